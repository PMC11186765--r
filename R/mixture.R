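#' Fit a univariate Gaussian mixture by expectation-maximization
#'
#' Standard univariate EM with several seeded initializations (one
#' quantile-based start plus random restarts); the best log-likelihood wins.
#' Component standard deviations are floored at `data range * 1e-3` to
#' prevent collapse onto single observations. The log-likelihood is checked
#' to be nondecreasing on every iteration; a decrease beyond floating-point
#' slack aborts the fit.
#'
#' Components are returned sorted by mean, which makes derived quantities
#' (cut-offs in particular) invariant to label switching.
#'
#' @param values Finite numeric vector, `length(values) >= 5 * k`.
#' @param k Number of components (>= 1).
#' @param seed Integer seed controlling the random restarts.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum EM iterations per start.
#' @param n_starts Number of initializations.
#' @return An object of class `ev_mixture`: `k`, `weights`, `means`, `sds`,
#'   `loglik`, `n`, `converged`, `iterations`.
#' @export
em_fit <- function(values, k, seed = 1, tol = 1e-8, max_iter = 500, n_starts = 5) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop_invalid("values must be finite")
  n <- length(values)
  if (k < 1) stop_invalid("k must be >= 1")
  if (n < 5 * k) stop_invalid("need at least 5k observations (n = %d, k = %d)", n, k)
  rng <- diff(range(values))
  if (rng == 0 && k > 1) stop_invalid("all values identical: cannot fit k > 1 components")
  sd_floor <- max(rng * 1e-3, 1e-8)

  if (k == 1) {
    mu <- mean(values)
    sigma <- max(stats::sd(values), sd_floor)
    if (n == 1 || is.na(sigma)) sigma <- sd_floor
    ll <- sum(stats::dnorm(values, mu, sigma, log = TRUE))
    return(structure(list(k = 1L, weights = 1, means = mu, sds = sigma,
                          loglik = ll, n = n, converged = TRUE, iterations = 0L),
                     class = "ev_mixture"))
  }

  loglik_matrix <- function(w, mu, sigma) {
    # n x k matrix of log(w_j * phi(x; mu_j, sigma_j)), built column-block-wise
    lm <- matrix(0, n, k)
    for (j in seq_len(k)) {
      lm[, j] <- log(w[j]) + stats::dnorm(values, mu[j], sigma[j], log = TRUE)
    }
    lm
  }
  run_em <- function(w, mu, sigma) {
    ll_old <- -Inf
    iter <- 0L
    converged <- FALSE
    repeat {
      iter <- iter + 1L
      lm <- loglik_matrix(w, mu, sigma)
      mx <- lm[, 1]
      for (j in seq_len(k)[-1]) mx <- pmax(mx, lm[, j])
      lse <- mx + log(rowSums(exp(lm - mx)))
      ll <- sum(lse)
      if (ll < ll_old - 1e-6 * max(1, abs(ll_old))) {
        stop_invalid("EM log-likelihood decreased (%.6g -> %.6g)", ll_old, ll)
      }
      if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
      if (iter >= max_iter) break
      ll_old <- ll
      resp <- exp(lm - lse)               # E step: posterior responsibilities
      nk <- pmax(colSums(resp), 1e-12)
      w <- nk / n                         # M step
      mu <- colSums(resp * values) / nk
      sigma <- pmax(sqrt(colSums(resp * (matrix(values, n, k) -
                                           matrix(mu, n, k, byrow = TRUE))^2) / nk),
                    sd_floor)
    }
    list(w = w, mu = mu, sigma = sigma, loglik = ll, iterations = iter,
         converged = converged)
  }

  starts <- with_seed(seed, {
    qs <- stats::quantile(values, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    s0 <- list(list(w = rep(1 / k, k), mu = qs,
                    sd = rep(max(stats::sd(values) / k, sd_floor), k)))
    extra <- lapply(seq_len(max(0, n_starts - 1)), function(s) {
      list(w = rep(1 / k, k), mu = sort(sample(values, k)),
           sd = rep(max(stats::sd(values) / k, sd_floor), k))
    })
    c(s0, extra)
  })

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(run_em(st$w, st$mu, pmax(st$sd, sd_floor)), error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) stop_invalid("EM failed for every initialization")
  ord <- order(best$mu)
  structure(list(k = as.integer(k), weights = best$w[ord], means = best$mu[ord],
                 sds = best$sigma[ord], loglik = best$loglik, n = n,
                 converged = best$converged, iterations = best$iterations),
            class = "ev_mixture")
}

#' @export
print.ev_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture: k = %d, n = %d, logLik = %.3f (%s, %d iter)\n",
              x$k, x$n, x$loglik, if (x$converged) "converged" else "not converged",
              x$iterations))
  print(data.frame(weight = x$weights, mean = x$means, sd = x$sds))
  invisible(x)
}

# Sample from a fitted mixture (parametric bootstrap draws).
rmixture <- function(n, model) {
  cid <- sample.int(model$k, n, replace = TRUE, prob = model$weights)
  stats::rnorm(n, model$means[cid], model$sds[cid])
}

#' Select the number of mixture components by parametric bootstrap
#'
#' Sequential bootstrap likelihood-ratio tests of k versus k + 1 components:
#' both models are fitted, the observed statistic `2 (ll_{k+1} - ll_k)` is
#' compared with its distribution over `n_boot` datasets simulated from the
#' k-component fit (both models refitted on each), and the procedure stops at
#' the first non-rejection at level `alpha`. EM failures on a bootstrap
#' replicate are redrawn (bounded retries). Deterministic under a fixed seed.
#'
#' @inheritParams em_fit
#' @param k_max Largest number of components considered (>= 1).
#' @param n_boot Bootstrap replicates per test (>= 20).
#' @param alpha Test level.
#' @param n_starts_boot Initializations per bootstrap refit (kept small for
#'   speed).
#' @return List with the selected `k` and a data frame `tests`
#'   (`k`, `lrt`, `p`).
#' @export
boot_comp <- function(values, k_max = 3, n_boot = 100, alpha = 0.05, seed = 1,
                      n_starts = 5, n_starts_boot = 1, max_iter = 150, tol = 1e-6) {
  if (k_max < 1) stop_invalid("k_max must be >= 1")
  if (k_max == 1) return(list(k = 1L, tests = data.frame(k = integer(), lrt = numeric(), p = numeric())))
  if (n_boot < 20) stop_invalid("n_boot must be >= 20")

  tests <- list()
  k_sel <- 1L
  for (k in seq_len(k_max - 1)) {
    seed_k <- derive_seed(seed, paste0("bootcomp-k", k))
    fit0 <- em_fit(values, k, seed = seed_k, n_starts = n_starts, max_iter = max_iter,
                   tol = tol)
    fit1 <- em_fit(values, k + 1, seed = seed_k + 1L, n_starts = n_starts,
                   max_iter = max_iter, tol = tol)
    lrt_obs <- max(0, 2 * (fit1$loglik - fit0$loglik))
    lrt_boot <- with_seed(seed_k + 2L, {
      vapply(seq_len(n_boot), function(b) {
        for (attempt in 1:5) {
          x_b <- rmixture(length(values), fit0)
          stat <- tryCatch({
            b0 <- em_fit(x_b, k, seed = seed_k + 10L + b, n_starts = n_starts_boot,
                         max_iter = max_iter, tol = tol)
            b1 <- em_fit(x_b, k + 1, seed = seed_k + 11L + b, n_starts = n_starts_boot,
                         max_iter = max_iter, tol = tol)
            max(0, 2 * (b1$loglik - b0$loglik))
          }, error = function(e) NA_real_)
          if (!is.na(stat)) return(stat)
        }
        stop_invalid("bootstrap replicate failed repeatedly at k = %d", k)
      }, numeric(1))
    })
    p <- mean(lrt_boot >= lrt_obs)
    tests[[k]] <- data.frame(k = k, lrt = lrt_obs, p = p)
    if (p > alpha) { k_sel <- k; break }
    k_sel <- k + 1L
  }
  list(k = as.integer(k_sel), tests = do.call(rbind, tests))
}

#' Crossing points of two mixture component densities
#'
#' Solves `w_i phi(x; mu_i, sd_i) = w_j phi(x; mu_j, sd_j)` (weighted; the
#' equal-posterior Bayes boundary) or the unweighted `phi_i = phi_j`. The
#' log-density difference is quadratic in x when the standard deviations
#' differ (0, 1 or 2 real roots) and linear when they are equal; every root
#' is verified by a sign change of the log-density difference around it.
#' Identical components have no isolated crossing: an empty result flagged
#' via the `"identical"` attribute.
#'
#' @param model An `ev_mixture`.
#' @param i,j Component indices (components are sorted by mean).
#' @param weighted Include the mixing weights (default TRUE).
#' @return Sorted numeric vector of crossings, with attribute `identical`.
#' @export
density_crossings <- function(model, i, j, weighted = TRUE) {
  stopifnot(inherits(model, "ev_mixture"))
  if (i == j || i < 1 || j < 1 || i > model$k || j > model$k) {
    stop_invalid("component indices must be distinct and within the model")
  }
  mu_i <- model$means[i]; mu_j <- model$means[j]
  s_i <- model$sds[i]; s_j <- model$sds[j]
  w_i <- if (weighted) model$weights[i] else 1
  w_j <- if (weighted) model$weights[j] else 1

  if (mu_i == mu_j && s_i == s_j && w_i == w_j) {
    out <- numeric(0)
    attr(out, "identical") <- TRUE
    return(out)
  }
  # f(x) = log(w_i phi_i) - log(w_j phi_j) = a x^2 + b x + c
  a <- 1 / (2 * s_j^2) - 1 / (2 * s_i^2)
  b <- mu_i / s_i^2 - mu_j / s_j^2
  cc <- mu_j^2 / (2 * s_j^2) - mu_i^2 / (2 * s_i^2) + log(w_i / w_j) + log(s_j / s_i)
  roots <- if (abs(a) < 1e-300) {
    if (b == 0) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0)
    else if (disc == 0) -b / (2 * a)
    else sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  }
  f <- function(x) {
    (log(w_i) + stats::dnorm(x, mu_i, s_i, log = TRUE)) -
      (log(w_j) + stats::dnorm(x, mu_j, s_j, log = TRUE))
  }
  h <- max(1e-8, 1e-6 * max(s_i, s_j))
  verified <- roots[vapply(roots, function(r) {
    sign(f(r - h)) * sign(f(r + h)) <= 0
  }, logical(1))]
  out <- sort(verified)
  attr(out, "identical") <- FALSE
  out
}

#' Derive the two data-driven cut-offs from a three-component mixture
#'
#' The lower cut-off is the crossing of the low-mean and middle component
#' densities inside `(mu_1, mu_2)`, the upper cut-off the crossing of the
#' middle and high-mean components inside `(mu_2, mu_3)`. If several
#' crossings fall inside an interval, the one where the lower-mean component
#' dominates immediately to its left is chosen. Missing crossings raise an
#' error carrying the model diagnostics.
#'
#' @param model An `ev_mixture` with `k = 3` and strictly ordered means.
#' @param marker Marker name recorded in the result.
#' @param cohort Cohort name recorded in the result.
#' @param weighted Use weighted (Bayes-boundary) crossings; both variants
#'   are recorded in the result metadata.
#' @return An object of class `ev_cutoffs`: `marker`, `cohort`, `lower`,
#'   `upper`, `weighted`, `model`.
#' @export
derive_cutoffs <- function(model, marker = "marker", cohort = "cohort",
                           weighted = TRUE) {
  stopifnot(inherits(model, "ev_mixture"))
  if (model$k != 3) stop_invalid("cut-off derivation requires k = 3 (got k = %d)", model$k)
  if (any(diff(model$means) <= 0)) stop_invalid("component means must be strictly ordered")

  pick <- function(i, j) {
    cr <- density_crossings(model, i, j, weighted = weighted)
    cr <- cr[cr > model$means[i] & cr < model$means[j]]
    if (length(cr) == 0) {
      stop_invalid(paste0("no density crossing between components %d and %d inside ",
                          "(%.4g, %.4g); weights = %s, sds = %s"),
                   i, j, model$means[i], model$means[j],
                   paste(signif(model$weights, 3), collapse = "/"),
                   paste(signif(model$sds, 3), collapse = "/"))
    }
    if (length(cr) > 1) {
      f <- function(x) {
        (log(if (weighted) model$weights[i] else 1) +
           stats::dnorm(x, model$means[i], model$sds[i], log = TRUE)) -
          (log(if (weighted) model$weights[j] else 1) +
             stats::dnorm(x, model$means[j], model$sds[j], log = TRUE))
      }
      h <- 1e-6 * diff(range(model$means))
      dominated <- vapply(cr, function(r) f(r - h) > 0, logical(1))
      cr <- if (any(dominated)) cr[dominated][1] else cr[1]
    }
    cr
  }
  lower <- pick(1, 2)
  upper <- pick(2, 3)
  structure(list(marker = marker, cohort = cohort,
                 lower = lower, upper = upper, weighted = weighted,
                 model = model),
            class = "ev_cutoffs")
}

#' @export
print.ev_cutoffs <- function(x, ...) {
  cat(sprintf("%s cut-offs (%s, %s crossings): lower = %.4g, upper = %.4g\n",
              x$marker, x$cohort, if (x$weighted) "weighted" else "unweighted",
              x$lower, x$upper))
  invisible(x)
}

#' Fit marker cut-offs on a cohort table
#'
#' The full cut-off stage as applied per marker: pool the cohort's values,
#' exclude genetically or neuropathologically confirmed cases (they are
#' reserved for testing the cut-offs), select the number of components by
#' [boot_comp()], fit the mixture and derive the two density-crossing
#' cut-offs. The number of components is forced to 3 for derivation; if the
#' bootstrap selects a different k a warning records the discrepancy.
#'
#' @param table Cohort table.
#' @param marker Column name (`"tau_ratio"` or `"tdp43"`).
#' @param seed Integer seed.
#' @param exclude_confirmed Drop rows with a known pathology label before
#'   fitting (default TRUE).
#' @param run_boot Run the bootstrap component-number selection (default
#'   TRUE); skipping it saves time when k is imposed anyway.
#' @param n_boot,alpha,k_max Passed to [boot_comp()].
#' @param log_scale Fit the mixture on log-transformed values (default FALSE:
#'   raw marker scale); recorded in the result.
#' @param ... Passed to [em_fit()].
#' @return An `ev_cutoffs` object with `boot` (selection result or NULL) and
#'   `log_scale` attached; cut-offs are reported on the raw marker scale.
#' @export
cutoffs_from_cohort <- function(table, marker, seed = 1, exclude_confirmed = TRUE,
                                run_boot = TRUE, n_boot = 100, alpha = 0.05,
                                k_max = 3, log_scale = FALSE, ...) {
  if (!marker %in% names(table)) stop_invalid("unknown marker column: %s", marker)
  rows <- if (exclude_confirmed) table$pathology %in% c(NA, "unknown") else rep(TRUE, nrow(table))
  values <- table[[marker]][rows]
  values <- values[is.finite(values)]
  if (log_scale) values <- log(values)

  boot <- NULL
  if (run_boot) {
    boot <- boot_comp(values, k_max = k_max, n_boot = n_boot, alpha = alpha,
                      seed = derive_seed(seed, paste0("boot-", marker)))
    if (boot$k != 3) {
      warning(sprintf("bootstrap selected k = %d for %s; forcing k = 3 for cut-off derivation",
                      boot$k, marker), call. = FALSE)
    }
  }
  model <- em_fit(values, k = 3, seed = derive_seed(seed, paste0("em-", marker)), ...)
  cuts <- derive_cutoffs(model, marker = marker,
                         cohort = table$cohort[1] %||% "cohort")
  if (log_scale) {
    cuts$lower <- exp(cuts$lower)
    cuts$upper <- exp(cuts$upper)
  }
  cuts$boot <- boot
  cuts$log_scale <- log_scale
  cuts
}
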