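# Independent brute-force oracles. These deliberately share no code with the
# package: ranks are computed from first principles, crossings by root
# bracketing on the density difference, exact binomial bounds by bisection on
# the binomial CDF.

midrank <- function(x) {
  # average position of each value among the sorted pooled sample
  vapply(x, function(v) mean(which(sort(x) == v)), numeric(1))
}

oracle_kruskal_h <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- midrank(x)
  sizes <- vapply(groups, length, integer(1))
  idx <- rep(seq_along(groups), sizes)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, sum)^2 / sizes) - 3 * (N + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (correction == 0) 0 else h / correction
}

oracle_dunn_z <- function(groups, i, j) {
  x <- unlist(groups)
  N <- length(x)
  r <- midrank(x)
  sizes <- vapply(groups, length, integer(1))
  idx <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, idx, mean)
  ties <- table(x)
  v <- (N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))) *
    (1 / sizes[i] + 1 / sizes[j])
  if (v == 0) 0 else unname((rbar[[i]] - rbar[[j]]) / sqrt(v))
}

oracle_auc_counting <- function(pos, neg) {
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

oracle_spearman <- function(x, y) {
  rx <- midrank(x); ry <- midrank(y)
  stats::cor(rx, ry)
}

# Crossings of two (optionally weighted) normal densities by sign-change
# bracketing of the log-density difference on a fine grid, refined by uniroot.
oracle_crossings <- function(w1, m1, s1, w2, m2, s2, step = 1e-4,
                             window = NULL) {
  f <- function(x) {
    (log(w1) + stats::dnorm(x, m1, s1, log = TRUE)) -
      (log(w2) + stats::dnorm(x, m2, s2, log = TRUE))
  }
  lo <- if (is.null(window)) min(m1 - 8 * s1, m2 - 8 * s2) else window[1]
  hi <- if (is.null(window)) max(m1 + 8 * s1, m2 + 8 * s2) else window[2]
  grid <- seq(lo, hi, by = step * (hi - lo))
  fv <- f(grid)
  flips <- which(sign(fv[-1]) * sign(fv[-length(fv)]) < 0)
  sort(vapply(flips, function(i) {
    stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root
  }, numeric(1)))
}

# Exact binomial interval bounds by bisection on the binomial CDF (percent).
oracle_clopper_pearson <- function(x, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  bisect <- function(g) {
    lo <- 0; hi <- 1
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (g(mid)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else bisect(function(p) stats::pbinom(x - 1, n, p) > 1 - alpha / 2)
  upper <- if (x == n) 1 else bisect(function(p) stats::pbinom(x, n, p) >= alpha / 2)
  c(lo = 100 * lower, hi = 100 * upper)
}

# Exhaustive least-squares monotone fit: enumerate all partitions of 1..n
# into consecutive blocks, fit block means, keep the monotone ones, take the
# minimum-SSE solution. Feasible for n <= 8.
oracle_isotonic <- function(y, increasing = TRUE) {
  n <- length(y)
  best <- NULL; best_sse <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    means <- numeric(0); fit <- numeric(n)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      means <- c(means, mean(y[idx]))
      fit[idx] <- mean(y[idx])
    }
    mono <- if (increasing) all(diff(means) >= 0) else all(diff(means) <= 0)
    if (!mono) next
    sse <- sum((y - fit)^2)
    if (sse < best_sse) { best_sse <- sse; best <- fit }
  }
  best
}

make_mixture <- function(weights, means, sds) {
  structure(list(k = length(means), weights = weights, means = means,
                 sds = sds, loglik = NA_real_, n = NA_integer_,
                 converged = TRUE, iterations = 0L),
            class = "ev_mixture")
}

describe_rule <- function() classification_rule(c(0.77, 1.27), c(13.87, 56.18),
                                                cohort = "DESCRIBE-2")

# the window a grid-scan oracle can certify; crossings outside it sit in
# regions where both densities underflow any plotted curve
oracle_window <- function(m1, s1, m2, s2) {
  c(min(m1 - 8 * s1, m2 - 8 * s2), max(m1 + 8 * s1, m2 + 8 * s2))
}
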