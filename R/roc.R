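#' ROC curve and AUC by the Mann-Whitney statistic
#'
#' `AUC = (#\{pos > neg\} + 0.5 #\{pos = neg\}) / (n_pos * n_neg)` after
#' orientation, computed through midranks so ties get half credit. The
#' staircase is built from the distinct observed thresholds with infinite
#' sentinels; the Hanley-McNeil standard error and the normal-approximation
#' confidence interval (clipped to \[0, 1\]) are attached.
#'
#' @param pos,neg Numeric marker scores of the positive and negative group.
#' @param orientation `"higher_is_positive"`, `"lower_is_positive"` or
#'   `"auto"` (flip so that AUC >= 0.5, recording the flip).
#' @param conf_level Confidence level for the AUC interval.
#' @return An object of class `ev_roc`: list with `auc`, `se`, `ci_low`,
#'   `ci_high`, `n_pos`, `n_neg`, `orientation`, `flipped`, `q1`, `q2`,
#'   `points` (fpr/tpr staircase) and the raw scores.
#' @export
auc_mann_whitney <- function(pos, neg,
                             orientation = c("higher_is_positive", "lower_is_positive", "auto"),
                             conf_level = 0.95) {
  orientation <- match.arg(orientation)
  pos <- pos[is.finite(pos)]; neg <- neg[is.finite(neg)]
  if (length(pos) < 1 || length(neg) < 1) stop_invalid("both groups must be non-empty")

  auc_raw <- function(p, n) {
    r <- rank(c(p, n))
    (sum(r[seq_along(p)]) - length(p) * (length(p) + 1) / 2) / (length(p) * length(n))
  }
  a <- auc_raw(pos, neg)
  flipped <- FALSE
  if (orientation == "lower_is_positive") {
    pos <- -pos; neg <- -neg; a <- auc_raw(pos, neg)
  } else if (orientation == "auto" && a < 0.5) {
    pos <- -pos; neg <- -neg; a <- auc_raw(pos, neg)
    flipped <- TRUE
    orientation <- "lower_is_positive"
  } else if (orientation == "auto") {
    orientation <- "higher_is_positive"
  }

  thr <- c(Inf, sort(unique(c(pos, neg)), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  se <- hanley_mcneil_se(a, length(pos), length(neg))
  ci <- auc_ci_normal(a, se, conf_level)
  structure(list(auc = a, se = se, ci_low = ci[1], ci_high = ci[2],
                 n_pos = length(pos), n_neg = length(neg),
                 orientation = orientation, flipped = flipped,
                 q1 = a / (2 - a), q2 = 2 * a^2 / (1 + a),
                 points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 scores_pos = pos, scores_neg = neg,
                 conf_level = conf_level),
            class = "ev_roc")
}

#' Hanley-McNeil standard error of an AUC
#'
#' Closed form
#' `se = sqrt((A(1-A) + (n1-1)(Q1-A^2) + (n2-1)(Q2-A^2)) / (n1 n2))` with
#' `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`.
#'
#' @param auc Area under the curve in \[0, 1\].
#' @param n_pos,n_neg Group sizes (>= 1).
#' @export
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  stopifnot(auc >= 0, auc <= 1, n_pos >= 1, n_neg >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) + (n_neg - 1) * (q2 - auc^2)) /
         (n_pos * n_neg))
}

auc_ci_normal <- function(auc, se, level) {
  if (level <= 0 || level >= 1) stop_invalid("conf level must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(max(0, auc - z * se), min(1, auc + z * se))
}

#' Normal-approximation confidence interval for an AUC
#'
#' `A +/- z * se`, clipped to \[0, 1\] (the normal approximation overflows
#' near a perfect AUC).
#'
#' @param roc An `ev_roc` object.
#' @param level Confidence level in (0, 1).
#' @return `c(ci_low, ci_high)`.
#' @export
auc_confidence_interval <- function(roc, level = 0.95) {
  stopifnot(inherits(roc, "ev_roc"))
  auc_ci_normal(roc$auc, roc$se, level)
}

# DeLong placement values: for each positive score, the fraction of negatives
# it beats (ties half credit), and vice versa.
placements <- function(pos, neg) {
  v10 <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)), numeric(1))
  v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' Compare two AUCs (Hanley-McNeil z framework)
#'
#' Unpaired: `z = (A1 - A2) / sqrt(se1^2 + se2^2)`. Paired (two markers on
#' the same subjects): the covariance of the two AUC estimates is estimated
#' from DeLong per-subject placement values and subtracted inside the square
#' root. Two-sided normal p-value.
#'
#' @param roc_a,roc_b `ev_roc` objects.
#' @param paired If `TRUE`, `roc_a` and `roc_b` must hold scores of the same
#'   subjects in the same order.
#' @return List with `z`, `p`, `auc_diff` and `se_diff`.
#' @export
compare_auc <- function(roc_a, roc_b, paired = FALSE) {
  stopifnot(inherits(roc_a, "ev_roc"), inherits(roc_b, "ev_roc"))
  d <- roc_a$auc - roc_b$auc
  if (!paired) {
    se <- sqrt(roc_a$se^2 + roc_b$se^2)
  } else {
    if (roc_a$n_pos != roc_b$n_pos || roc_a$n_neg != roc_b$n_neg) {
      stop_invalid("paired comparison needs both markers on the same subjects")
    }
    pa <- placements(roc_a$scores_pos, roc_a$scores_neg)
    pb <- placements(roc_b$scores_pos, roc_b$scores_neg)
    n1 <- roc_a$n_pos; n2 <- roc_a$n_neg
    cov_ab <- if (n1 > 1 && n2 > 1) {
      stats::cov(pa$v10, pb$v10) / n1 + stats::cov(pa$v01, pb$v01) / n2
    } else 0
    se <- sqrt(max(0, roc_a$se^2 + roc_b$se^2 - 2 * cov_ab))
  }
  z <- if (se == 0) 0 else d / se
  list(z = z, p = if (se == 0 && d == 0) 1 else 2 * stats::pnorm(-abs(z)),
       auc_diff = d, se_diff = se)
}

#' Prevalence-adjusted precision-recall curve
#'
#' Re-expresses an ROC staircase at a chosen population prevalence:
#' `PPV = rho TPR / (rho TPR + (1 - rho) FPR)` at every ROC point, with the
#' area under the precision-recall curve by the trapezoid rule over recall
#' and a seeded stratified bootstrap of the underlying scores for the CI.
#' A degenerate all-tie ROC yields the random-classifier baseline
#' `AUPRC = rho`, flagged.
#'
#' @param roc An `ev_roc` object (carries the raw scores).
#' @param prevalence Population prevalence in (0, 1).
#' @param n_boot Bootstrap replicates for the AUPRC CI (0 disables).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level CI level.
#' @return List with `prevalence`, `points` (recall/ppv), `auprc`, `ci_low`,
#'   `ci_high`, `degenerate`.
#' @export
pr_with_prevalence <- function(roc, prevalence, n_boot = 200, seed = 1,
                               conf_level = 0.95) {
  stopifnot(inherits(roc, "ev_roc"))
  if (prevalence <= 0 || prevalence >= 1) stop_invalid("prevalence must be in (0, 1)")

  curve_from <- function(pos, neg) {
    thr <- c(Inf, sort(unique(c(pos, neg)), decreasing = TRUE), -Inf)
    tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
    ppv <- ifelse(tpr + fpr == 0, 1,
                  prevalence * tpr / (prevalence * tpr + (1 - prevalence) * fpr))
    list(recall = tpr, ppv = ppv)
  }
  auprc_of <- function(cv) {
    ord <- order(cv$recall)
    rec <- cv$recall[ord]; ppv <- cv$ppv[ord]
    sum(diff(rec) * (utils::head(ppv, -1) + utils::tail(ppv, -1)) / 2)
  }
  degenerate <- length(unique(c(roc$scores_pos, roc$scores_neg))) == 1L
  cv <- curve_from(roc$scores_pos, roc$scores_neg)
  auprc <- if (degenerate) prevalence else auprc_of(cv)

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && !degenerate) {
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      p <- sample(roc$scores_pos, replace = TRUE)
      n <- sample(roc$scores_neg, replace = TRUE)
      auprc_of(curve_from(p, n))
    }, numeric(1)))
    alpha <- 1 - conf_level
    ci <- unname(stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), type = 7))
  }
  list(prevalence = prevalence,
       points = data.frame(recall = cv$recall, ppv = cv$ppv),
       auprc = auprc, ci_low = ci[1], ci_high = ci[2], degenerate = degenerate)
}
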