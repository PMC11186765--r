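#' Exact (Clopper-Pearson) binomial confidence interval, in percent
#'
#' Two-sided exact interval from beta quantiles:
#' `lo = qbeta(alpha/2, x, n - x + 1)` (0 when x = 0) and
#' `hi = qbeta(1 - alpha/2, x + 1, n - x)` (1 when x = n), returned in
#' percent. This is the interval behind every printed sensitivity and
#' specificity bound the pipeline reproduces.
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials (>= 1).
#' @param conf_level Confidence level in (0, 1).
#' @return Named numeric vector `c(lo, hi)` in percent.
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  stopifnot(n >= 1, conf_level > 0, conf_level < 1)
  if (x < 0 || x > n) stop_invalid("x must be in [0, n] (x = %s, n = %s)", x, n)
  alpha <- 1 - conf_level
  lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lo = 100 * lo, hi = 100 * hi)
}

#' Build the two-marker classification rule
#'
#' The two tau-ratio cut-offs and two TDP-43 cut-offs partition the marker
#' plane into a 3 x 3 grid of putative molecular-pathology labels. The
#' default label map follows the published reading of the grid: a low tau
#' ratio flags PSP/GGT-type 4R tauopathy, a high tau ratio flags
#' FTLD-tau (MAPT-like), a mid-range ratio with at least mildly elevated
#' TDP-43 flags TDP-43 pathology (with a severity sub-flag above the upper
#' TDP-43 cut-off), and everything else is control-like.
#'
#' @param tau_cutoffs,tdp_cutoffs `ev_cutoffs` objects or plain
#'   `c(lower, upper)` numeric vectors.
#' @param cohort Provenance string.
#' @return An object of class `ev_rule`.
#' @export
classification_rule <- function(tau_cutoffs, tdp_cutoffs, cohort = "cohort") {
  as_pair <- function(x, nm) {
    if (inherits(x, "ev_cutoffs")) x <- c(x$lower, x$upper)
    if (!is.numeric(x) || length(x) != 2 || x[1] >= x[2]) {
      stop_invalid("%s must be c(lower, upper) with lower < upper", nm)
    }
    unname(x)
  }
  structure(list(tau = as_pair(tau_cutoffs, "tau_cutoffs"),
                 tdp = as_pair(tdp_cutoffs, "tdp_cutoffs"),
                 cohort = cohort),
            class = "ev_rule")
}

#' @export
print.ev_rule <- function(x, ...) {
  cat(sprintf("Classification rule (%s): tau ratio %.4g / %.4g, TDP-43 %.4g / %.4g pg/ml\n",
              x$cohort, x$tau[1], x$tau[2], x$tdp[1], x$tdp[2]))
  invisible(x)
}

#' Classify one subject on the two-marker grid
#'
#' Tau-ratio labels take precedence; a tau label combined with elevated
#' TDP-43 is reported with a conflict flag rather than silently resolved
#' (the published grids show essentially empty conflict regions, so no
#' precedence claim is warranted).
#'
#' @param tau_ratio,tdp43 Marker values; a missing marker yields
#'   `"unclassifiable"`.
#' @param rule An `ev_rule`.
#' @return List with `label`, `tdp_high` (severity sub-flag) and `conflict`.
#' @export
classify_subject <- function(tau_ratio, tdp43, rule) {
  stopifnot(inherits(rule, "ev_rule"))
  if (!is.finite(tau_ratio) || !is.finite(tdp43)) {
    return(list(label = "unclassifiable", tdp_high = NA, conflict = NA))
  }
  tdp_elevated <- tdp43 > rule$tdp[1]
  tdp_high <- tdp43 > rule$tdp[2]
  if (tau_ratio < rule$tau[1]) {
    list(label = "PSP/GGT-type tauopathy-like", tdp_high = tdp_high,
         conflict = tdp_elevated)
  } else if (tau_ratio > rule$tau[2]) {
    list(label = "FTLD-tau (MAPT-like)", tdp_high = tdp_high,
         conflict = tdp_elevated)
  } else if (tdp_elevated) {
    list(label = "TDP-43-positive", tdp_high = tdp_high, conflict = FALSE)
  } else {
    list(label = "control-like", tdp_high = FALSE, conflict = FALSE)
  }
}

#' Classify every row of a cohort table
#'
#' @param table Cohort table with `tau_ratio` and `tdp43` columns.
#' @param rule An `ev_rule`.
#' @return The table with `ev_class`, `ev_tdp_high` and `ev_conflict`
#'   columns appended.
#' @export
classify_table <- function(table, rule) {
  res <- lapply(seq_len(nrow(table)), function(i) {
    classify_subject(table$tau_ratio[i], table$tdp43[i], rule)
  })
  table$ev_class <- vapply(res, `[[`, character(1), "label")
  table$ev_tdp_high <- vapply(res, function(r) isTRUE(r$tdp_high), logical(1))
  table$ev_conflict <- vapply(res, function(r) isTRUE(r$conflict), logical(1))
  table
}

#' Sensitivity and specificity with exact binomial confidence intervals
#'
#' Confusion counts of a binary prediction against a binary truth, with
#' sensitivity `100 tp / (tp + fn)` and specificity `100 tn / (tn + fp)` and
#' their Clopper-Pearson intervals. A truth vector without positives (or
#' negatives) flags the corresponding estimate as undefined instead of
#' erroring.
#'
#' @param predictions,truth Logical vectors of equal length.
#' @param conf_level CI level.
#' @return An object of class `ev_performance`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity` (each a list with `estimate`, `ci_low`,
#'   `ci_high`, in percent, or NA when undefined) and `conf_level`.
#' @export
diagnostic_performance <- function(predictions, truth, conf_level = 0.95) {
  stopifnot(length(predictions) == length(truth))
  predictions <- as.logical(predictions)
  truth <- as.logical(truth)
  ok <- !is.na(predictions) & !is.na(truth)
  predictions <- predictions[ok]; truth <- truth[ok]
  tp <- sum(predictions & truth)
  fp <- sum(predictions & !truth)
  tn <- sum(!predictions & !truth)
  fn <- sum(!predictions & truth)
  prop <- function(x, n) {
    if (n == 0) return(list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
    ci <- clopper_pearson(x, n, conf_level)
    list(estimate = 100 * x / n, ci_low = unname(ci[1]), ci_high = unname(ci[2]))
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = prop(tp, tp + fn),
                 specificity = prop(tn, tn + fp),
                 conf_level = conf_level),
            class = "ev_performance")
}

#' @export
print.ev_performance <- function(x, ...) {
  fmt <- function(p, nm) {
    if (is.na(p$estimate)) sprintf("%s: undefined", nm)
    else sprintf("%s: %.2f%% [%.2f-%.2f]", nm, p$estimate, p$ci_low, p$ci_high)
  }
  cat(sprintf("tp=%d fp=%d tn=%d fn=%d | %s; %s (%.0f%% CI)\n",
              x$tp, x$fp, x$tn, x$fn,
              fmt(x$sensitivity, "sensitivity"), fmt(x$specificity, "specificity"),
              100 * x$conf_level))
  invisible(x)
}

#' Score a classification rule against confirmed-pathology truth
#'
#' `truth_spec` makes both sides of the comparison explicit: which rows
#' count as true positives and which rows form the negative denominator
#' (the published denominators vary between "all other confirmed cases" and
#' "all other subjects", so nothing is hard-coded).
#'
#' @param table A classified or raw cohort table.
#' @param rule An `ev_rule` applied to the table.
#' @param truth_spec List with `positive` (function of the table returning a
#'   logical truth vector), `predicted` (function of the classified table
#'   returning the logical prediction vector) and optional `subset`
#'   (function returning the rows to score).
#' @param conf_level CI level.
#' @return An `ev_performance`.
#' @export
evaluate_rule <- function(table, rule, truth_spec, conf_level = 0.95) {
  ct <- classify_table(table, rule)
  attr(ct, "ev_rule") <- rule   # lets truth specs predict from the rule under test
  keep <- if (is.null(truth_spec$subset)) rep(TRUE, nrow(ct)) else truth_spec$subset(ct)
  rl <- attr(ct, "ev_rule")
  ct <- ct[keep, , drop = FALSE]
  attr(ct, "ev_rule") <- rl
  truth <- truth_spec$positive(ct)
  pred <- truth_spec$predicted(ct)
  diagnostic_performance(pred, truth, conf_level)
}

#' Apply one cohort's cut-off rule to another cohort
#'
#' Classifies cohort B with cohort A's rule, scores it against B's truth
#' labels, and (when B's own rule is supplied) reports the native
#' performance side by side — the cross-cohort transferability check.
#'
#' @param rule_from An `ev_rule` derived on cohort A.
#' @param table_b Cohort B table carrying the truth labels named by
#'   `truth_spec`.
#' @param truth_spec As in [evaluate_rule()].
#' @param native_rule Optional `ev_rule` derived on cohort B itself.
#' @param conf_level CI level.
#' @return List with `transferred` (`ev_performance`) and `native`
#'   (`ev_performance` or NULL).
#' @export
transfer_cutoffs <- function(rule_from, table_b, truth_spec, native_rule = NULL,
                             conf_level = 0.95) {
  needed <- c("tau_ratio", "tdp43", "pathology")
  missing_cols <- setdiff(needed, names(table_b))
  if (length(missing_cols)) {
    stop_invalid("cohort table lacks columns: %s", paste(missing_cols, collapse = ", "))
  }
  list(transferred = evaluate_rule(table_b, rule_from, truth_spec, conf_level),
       native = if (is.null(native_rule)) NULL else
         evaluate_rule(table_b, native_rule, truth_spec, conf_level))
}

#' Canonical truth specifications
#'
#' Helpers constructing the `truth_spec` lists used in the published
#' performance claims: TDP-43 pathology detection among confirmed cases via
#' the lower TDP-43 cut-off, and PSP discrimination via the lower tau-ratio
#' cut-off.
#'
#' @param among `"confirmed"` restricts the denominator to
#'   pathology-confirmed rows; `"all"` uses the whole cohort.
#' @param rule Optional `ev_rule` fixing the predictions; by default the
#'   predictions come from whichever rule [evaluate_rule()] is scoring, so
#'   the same truth spec can score a native and a transferred rule.
#' @name truth_specs
#' @export
truth_spec_tdp <- function(rule = NULL, among = c("confirmed", "all")) {
  among <- match.arg(among)
  list(
    subset = if (among == "confirmed") function(ct) !ct$pathology %in% c(NA, "unknown") else NULL,
    positive = function(ct) ct$pathology == "TDP-43",
    predicted = function(ct) {
      r <- rule %||% attr(ct, "ev_rule")
      ct$tdp43 > r$tdp[1]
    }
  )
}

#' @rdname truth_specs
#' @export
truth_spec_psp <- function(rule = NULL) {
  list(
    subset = NULL,
    positive = function(ct) ct$diagnosis == "PSP",
    predicted = function(ct) {
      r <- rule %||% attr(ct, "ev_rule")
      ct$tau_ratio < r$tau[1]
    }
  )
}
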