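#' Median and interquartile range
#'
#' Quartiles follow the linear-interpolation convention (`stats::quantile`
#' type 7), fixed and documented because printed IQRs rarely disclose the
#' convention used. Missing values are dropped.
#'
#' @param values Numeric vector with at least one finite value.
#' @return Named numeric vector `(median, q1, q3)`.
#' @export
median_iqr <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop_invalid("no finite values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], q1 = q[1], q3 = q[3])
}

#' Kruskal-Wallis rank test across diagnostic groups
#'
#' Midranks for ties and the tie-corrected H statistic
#' (`H / (1 - sum(t^3 - t) / (N^3 - N))`), with the p-value from a
#' chi-square on k-1 degrees of freedom; computed by `stats::kruskal.test`.
#' All values identical across groups gives H = 0, p = 1 rather than an
#' error.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups).
#' @return List with `h`, `df` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop_invalid("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 1)) stop_invalid("every group needs >= 1 value")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (length(unique(x)) == 1L) {
    return(list(h = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(x, g)
  list(h = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Dunn's pairwise post-hoc comparisons after Kruskal-Wallis
#'
#' For each pair (i, j) of groups,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/n_i + 1/n_j))`
#' on the pooled midranks, with two-sided normal p-values adjusted over all
#' k(k-1)/2 comparisons. Bonferroni (capped at 1) is the default family-wise
#' correction, matching common statistics-package behaviour; Holm is
#' available.
#'
#' @param groups Named (or unnamed) list of numeric vectors, one per group.
#' @param adjust `"bonferroni"` (default), `"holm"` or `"none"`.
#' @return List with `h`, `df`, `p_global` and a data frame `pairwise`
#'   holding `group_a`, `group_b`, `z`, `p_raw`, `p_adjusted`.
#' @export
dunn_pairwise <- function(groups, adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  if (!is.list(groups) || length(groups) < 2) stop_invalid("need >= 2 groups")
  kw <- kruskal_wallis(groups)
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  if (is.null(names(groups))) names(groups) <- nm
  sizes <- vapply(groups, length, integer(1))
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x)                       # midranks
  g <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term

  pairs <- utils::combn(length(groups), 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1, m]; j <- pairs[2, m]
    se <- sqrt(var_base * (1 / sizes[i] + 1 / sizes[j]))
    z[m] <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
    p_raw[m] <- 2 * stats::pnorm(-abs(z[m]))
  }
  p_adj <- stats::p.adjust(p_raw, method = adjust)
  list(h = kw$h, df = kw$df, p_global = kw$p,
       pairwise = data.frame(group_a = nm[pairs[1, ]], group_b = nm[pairs[2, ]],
                             z = z, p_raw = p_raw, p_adjusted = p_adj,
                             stringsAsFactors = FALSE))
}

#' Spearman correlation matrix with pairwise-complete deletion
#'
#' Rank correlation on midranks with two-sided p-values from the
#' t-approximation (`stats::cor.test`, `exact = FALSE`). Variable pairs with
#' fewer than three complete observations are flagged missing (`NA`), never
#' fabricated.
#'
#' @param table Data frame (e.g. a cohort table).
#' @param variables Character vector of numeric column names.
#' @param within Optional diagnosis label; rows are filtered to
#'   `table$diagnosis == within` first.
#' @return List of matrices `r`, `p`, `n` plus `variables`.
#' @export
spearman_matrix <- function(table, variables, within = NULL) {
  if (!is.null(within)) table <- table[table$diagnosis == within, , drop = FALSE]
  missing_vars <- setdiff(variables, names(table))
  if (length(missing_vars)) stop_invalid("unknown variables: %s", paste(missing_vars, collapse = ", "))
  k <- length(variables)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  n <- matrix(0L, k, k, dimnames = list(variables, variables))
  for (i in seq_len(k)) {
    for (j in i:k) {
      xi <- table[[variables[i]]]
      xj <- table[[variables[j]]]
      ok <- is.finite(xi) & is.finite(xj)
      n[i, j] <- n[j, i] <- sum(ok)
      if (i == j) { r[i, j] <- 1; p[i, j] <- NA_real_; next }
      if (sum(ok) < 3) next
      ct <- suppressWarnings(stats::cor.test(xi[ok], xj[ok], method = "spearman", exact = FALSE))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(variables = variables, r = r, p = p, n = n)
}

#' Least-squares monotone trend fit
#'
#' Isotonic regression by pool-adjacent-violators on the x-sorted data
#' (`stats::isoreg`; decreasing fits via negation), used to display monotone
#' marker-severity associations. `direction = "auto"` picks the direction
#' with the smaller residual sum of squares.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @param direction `"increasing"`, `"decreasing"` or `"auto"`.
#' @return List with `x`, `fitted` (aligned to the original order of `x`),
#'   `direction` and `rss`.
#' @export
monotone_fit <- function(x, y, direction = c("increasing", "decreasing", "auto")) {
  direction <- match.arg(direction)
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  if (length(x) < 2) stop_invalid("need >= 2 points")
  fit_one <- function(dir) {
    ord <- order(x)
    ys <- if (dir == "increasing") y[ord] else -y[ord]
    iso <- stats::isoreg(ys)$yf
    fitted_sorted <- if (dir == "increasing") iso else -iso
    fitted <- numeric(length(y))
    fitted[ord] <- fitted_sorted
    list(x = x, fitted = fitted, direction = dir, rss = sum((y - fitted)^2))
  }
  if (direction != "auto") return(fit_one(direction))
  inc <- fit_one("increasing"); dec <- fit_one("decreasing")
  if (inc$rss <= dec$rss) inc else dec
}
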