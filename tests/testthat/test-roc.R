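test_that("AUC equals exhaustive concordant-pair counting", {
  r <- auc_mann_whitney(c(2, 4), c(1, 3))
  expect_equal(r$auc, 0.75)
  expect_equal(auc_mann_whitney(c(5, 6), c(1, 2))$auc, 1)
  expect_equal(auc_mann_whitney(c(1, 2, 2), c(1, 2, 2))$auc, 0.5)

  set.seed(99)
  for (rep in 1:100) {
    pos <- sample(1:8, sample(2:10, 1), replace = TRUE)
    neg <- sample(1:8, sample(2:10, 1), replace = TRUE)
    expect_equal(auc_mann_whitney(pos, neg)$auc, oracle_auc_counting(pos, neg))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  pos <- rnorm(30, 1); neg <- rnorm(40)
  a <- auc_mann_whitney(pos, neg)$auc
  expect_equal(auc_mann_whitney(exp(pos), exp(neg))$auc, a)
  expect_equal(auc_mann_whitney(pos^3 + 2 * pos, neg^3 + 2 * neg)$auc, a)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  pos <- round(rnorm(25, 1), 1); neg <- round(rnorm(35), 1)
  ours <- auc_mann_whitney(pos, neg)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 25), rep(0, 35)), predictor = c(pos, neg),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("ROC staircase is a valid curve and orientation flips record", {
  r <- auc_mann_whitney(c(2, 4, 5), c(1, 3, 3))
  expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[1], 0)
  expect_equal(utils::tail(r$points$fpr, 1), 1)
  expect_equal(utils::tail(r$points$tpr, 1), 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))

  # lower-is-positive marker (tau ratio in PSP): auto flips and says so
  rf <- auc_mann_whitney(c(0.2, 0.3), c(0.9, 1.1), orientation = "auto")
  expect_true(rf$flipped)
  expect_equal(rf$auc, 1)
  expect_error(auc_mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Hanley-McNeil standard error matches its closed form", {
  expect_equal(hanley_mcneil_se(1, 5, 9), 0)
  expect_equal(hanley_mcneil_se(0.5, 1, 1), 0.5)
  # A = 0.5: Q1 = Q2 = 1/3, se = sqrt((0.25 + 18/12)/100)
  expect_equal(hanley_mcneil_se(0.5, 10, 10), sqrt(0.0175), tolerance = 1e-12)
  # monotone decreasing in both group sizes at fixed A
  for (a in c(0.6, 0.75, 0.9)) {
    se_seq <- vapply(c(5, 10, 20, 50, 100), function(n) hanley_mcneil_se(a, n, 30),
                     numeric(1))
    expect_true(all(diff(se_seq) < 0))
    se_seq2 <- vapply(c(5, 10, 50), function(n) hanley_mcneil_se(a, 30, n), numeric(1))
    expect_true(all(diff(se_seq2) < 0))
  }
})

test_that("AUC confidence intervals are normal-approximation with clipping", {
  r <- auc_mann_whitney(c(2, 4), c(1, 3))
  r$auc <- 0.5; r$se <- 0.1
  expect_equal(auc_confidence_interval(r, 0.95), c(0.304, 0.696), tolerance = 1e-3)
  r$auc <- 1; r$se <- 0
  expect_equal(auc_confidence_interval(r, 0.95), c(1, 1))
  r$auc <- 0.99; r$se <- 0.02
  expect_equal(auc_confidence_interval(r, 0.95)[2], 1)  # clipped
  expect_error(auc_confidence_interval(r, 1.5), "level")
})

test_that("AUC comparison: closed form, self-comparison, independence limit", {
  set.seed(3)
  pos <- rnorm(40, 1); neg <- rnorm(40)
  r <- auc_mann_whitney(pos, neg)
  self <- compare_auc(r, r, paired = TRUE)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)

  # z = (A1 - A2) / sqrt(se1^2 + se2^2), two-sided normal p
  ra <- r; ra$auc <- 0.9; ra$se <- 0.03
  rb <- r; rb$auc <- 0.7; rb$se <- 0.05
  un <- compare_auc(ra, rb, paired = FALSE)
  expect_equal(un$z, 3.430, tolerance = 1e-3)
  expect_equal(un$p, 6.0e-4, tolerance = 0.05)

  # independent markers on the same subjects: paired ~ unpaired
  set.seed(31)
  n1 <- 400; n2 <- 400
  m1p <- rnorm(n1, 0.8); m1n <- rnorm(n2)
  m2p <- rnorm(n1, 0.8); m2n <- rnorm(n2)
  r1 <- auc_mann_whitney(m1p, m1n); r2 <- auc_mann_whitney(m2p, m2n)
  expect_lt(abs(compare_auc(r1, r2, paired = TRUE)$se_diff -
                  compare_auc(r1, r2, paired = FALSE)$se_diff), 0.003)
})

test_that("prevalence-adjusted precision-recall behaves", {
  # PPV at (TPR 0.9, FPR 0.1) under 1% prevalence: scores engineered so the
  # staircase passes exactly through that operating point
  pos <- c(rep(2, 9), 0); neg <- c(rep(0, 9), 2)
  r <- auc_mann_whitney(pos, neg, orientation = "higher_is_positive")
  pr <- pr_with_prevalence(r, prevalence = 0.01, n_boot = 0)
  row <- which(abs(pr$points$recall - 0.9) < 1e-12)[1]
  expect_equal(pr$points$ppv[row], 0.009 / (0.009 + 0.099), tolerance = 1e-10)

  # perfect classifier: AUPRC 1 at any prevalence; FPR = 0 points have PPV 1
  rp <- auc_mann_whitney(c(3, 4), c(1, 2))
  prp <- pr_with_prevalence(rp, 0.05, n_boot = 0)
  expect_equal(prp$auprc, 1, tolerance = 1e-12)
  expect_true(all(prp$points$ppv[prp$points$recall > 0 &
                                   prp$points$recall <= 1][1] == 1))

  # degenerate all-tie scores: random-classifier baseline, flagged
  rd <- auc_mann_whitney(c(1, 1), c(1, 1))
  prd <- pr_with_prevalence(rd, 0.2, n_boot = 0)
  expect_true(prd$degenerate)
  expect_equal(prd$auprc, 0.2)

  # at the sample prevalence the curve reproduces empirical precision
  set.seed(8)
  pos <- rnorm(30, 1); neg <- rnorm(70)
  r2 <- auc_mann_whitney(pos, neg, orientation = "higher_is_positive")
  rho <- 30 / 100
  pr2 <- pr_with_prevalence(r2, rho, n_boot = 50, seed = 4)
  for (i in sample(nrow(pr2$points), 10)) {
    thr <- r2$points$threshold[i]
    tp <- sum(pos >= thr); fp <- sum(neg >= thr)
    if (tp + fp > 0) {
      expect_equal(pr2$points$ppv[i], tp / (tp + fp), tolerance = 1e-10)
    }
  }
  expect_true(pr2$ci_low <= pr2$auprc && pr2$auprc <= pr2$ci_high)
  expect_error(pr_with_prevalence(r2, 1.2), "prevalence")
})
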