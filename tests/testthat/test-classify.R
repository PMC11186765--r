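test_that("exact binomial intervals reproduce known bounds", {
  expect_equal(clopper_pearson(3, 3), c(lo = 29.24, hi = 100), tolerance = 5e-3)
  expect_equal(unname(clopper_pearson(0, 10)[1]), 0)
  expect_equal(unname(clopper_pearson(0, 10)[2]), 100 * (1 - 0.025^(1 / 10)),
               tolerance = 1e-10)
  expect_equal(unname(clopper_pearson(0, 10)[2]), 30.85, tolerance = 5e-3)
  # the published interval for an 88% sensitivity (76.13-95.67) corresponds
  # to 45/51, not to the 44/50 counts it accompanies; the exact interval for
  # 44/50 is [75.69, 95.47]
  expect_equal(clopper_pearson(44, 50), c(lo = 75.69, hi = 95.47), tolerance = 5e-3)
  expect_equal(clopper_pearson(45, 51), c(lo = 76.13, hi = 95.56), tolerance = 5e-3)
  expect_error(clopper_pearson(5, 3), "x must be")
})

test_that("exact intervals match the binomial-CDF bisection oracle", {
  # spot grid over the full n range the performance tables use
  set.seed(20)
  cases <- rbind(expand.grid(n = c(1, 2, 3, 7, 13, 27), x = 0:27),
                 data.frame(n = sample(30:200, 60, replace = TRUE), x = NA))
  cases <- cases[is.na(cases$x) | cases$x <= cases$n, ]
  cases$x[is.na(cases$x)] <- vapply(cases$n[is.na(cases$x)],
                                    function(n) sample(0:n, 1), numeric(1))
  for (r in seq_len(nrow(cases))) {
    got <- clopper_pearson(cases$x[r], cases$n[r])
    ref <- oracle_clopper_pearson(cases$x[r], cases$n[r])
    expect_equal(unname(got), unname(ref), tolerance = 0.005)
  }
})

test_that("exact interval coverage sits at the nominal level", {
  set.seed(77)
  p <- 0.9; n <- 50
  x <- rbinom(1e4, n, p)
  lo <- ifelse(x == 0, 0, qbeta(0.025, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(0.975, x + 1, n - x))
  # same draws scored through the package function on a subsample
  idx <- sample(1e4, 50)
  for (i in idx) {
    ci <- clopper_pearson(x[i], n)
    expect_equal(unname(ci), 100 * c(lo[i], hi[i]), tolerance = 1e-10)
  }
  coverage <- mean(lo <= p & p <= hi)
  # exact coverage at p = 0.9, n = 50 is 97.03% (sum of binomial mass over
  # the covering x); the simulation must sit at that value, above nominal
  exact <- sum(dbinom(which(qbeta(0.025, 0:n, n - 0:n + 1) <= p &
                              p <= ifelse(0:n == n, 1, qbeta(0.975, 0:n + 1, n - 0:n))) - 1,
                      n, p))
  expect_gte(coverage, 0.94)
  expect_lt(abs(coverage - exact), 0.01)
})

test_that("the two-marker grid assigns the published group medians correctly", {
  rule <- describe_rule()
  expect_equal(classify_subject(0.42, 2.85, rule)$label, "PSP/GGT-type tauopathy-like")
  expect_equal(classify_subject(3.96, 2.86, rule)$label, "FTLD-tau (MAPT-like)")
  tdp <- classify_subject(0.95, 63.95, rule)
  expect_equal(tdp$label, "TDP-43-positive")
  expect_true(tdp$tdp_high)
  expect_equal(classify_subject(0.99, 9.47, rule)$label, "control-like")
})

test_that("grid is complete, conflict-flagging and monotone in the TDP cut-off", {
  rule <- describe_rule()
  set.seed(10)
  labels <- c("PSP/GGT-type tauopathy-like", "FTLD-tau (MAPT-like)",
              "TDP-43-positive", "control-like")
  tau <- runif(500, 0, 5); tdp <- runif(500, 0, 120)
  got <- vapply(seq_len(500), function(i) classify_subject(tau[i], tdp[i], rule)$label,
                character(1))
  expect_true(all(got %in% labels))   # every finite pair gets exactly one label

  # conflicting cell: tau label wins but the conflict is flagged
  cf <- classify_subject(0.4, 30, rule)
  expect_equal(cf$label, "PSP/GGT-type tauopathy-like")
  expect_true(cf$conflict)
  expect_equal(classify_subject(NA, 30, rule)$label, "unclassifiable")

  # raising the lower TDP cut-off never increases TDP-positive calls
  counts <- vapply(c(5, 10, 13.87, 20, 40, 60), function(cut) {
    r <- classification_rule(c(0.77, 1.27), c(cut, 100))
    sum(vapply(seq_len(500), function(i)
      classify_subject(tau[i], tdp[i], r)$label == "TDP-43-positive", logical(1)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("diagnostic performance reproduces published confusion summaries", {
  perfect <- diagnostic_performance(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(perfect$sensitivity$estimate, 100)
  expect_equal(perfect$specificity$estimate, 100)

  # 44/50 detected, 13/13 true negatives
  pred <- c(rep(TRUE, 44), rep(FALSE, 6), rep(FALSE, 13))
  truth <- c(rep(TRUE, 50), rep(FALSE, 13))
  perf <- diagnostic_performance(pred, truth)
  expect_equal(perf$tp, 44); expect_equal(perf$fn, 6)
  expect_equal(perf$tn, 13); expect_equal(perf$fp, 0)
  expect_equal(perf$sensitivity$estimate, 88)
  expect_equal(perf$sensitivity$ci_low, 75.69, tolerance = 5e-3)
  expect_equal(perf$sensitivity$ci_high, 95.47, tolerance = 5e-3)
  expect_equal(perf$specificity$estimate, 100)
  expect_equal(perf$specificity$ci_low, 75.29, tolerance = 5e-3)

  # zero sensitivity: CI upper = 100 (1 - 0.025^(1/5))
  p0 <- diagnostic_performance(rep(FALSE, 10), c(rep(TRUE, 5), rep(FALSE, 5)))
  expect_equal(p0$sensitivity$estimate, 0)
  expect_equal(p0$sensitivity$ci_high, 100 * (1 - 0.025^(1 / 5)), tolerance = 1e-10)
  expect_equal(p0$sensitivity$ci_high, 52.18, tolerance = 5e-3)

  # no positives in truth: sensitivity undefined-flagged, not fabricated
  pu <- diagnostic_performance(c(TRUE, FALSE), c(FALSE, FALSE))
  expect_true(is.na(pu$sensitivity$estimate))
  expect_false(is.na(pu$specificity$estimate))
})

test_that("cut-off transfer: self-transfer is identity, cohorts are interchangeable", {
  sp <- sant_pau_spec()
  tab <- inject_pathology_labels(generate_cohort(sp, seed = 55), sp, seed = 56)

  native <- classification_rule(c(0.78, 1.28), c(17.85, 57.34), "SantPau")
  foreign <- classification_rule(c(0.77, 1.28), c(13.87, 56.18), "DESCRIBE-2")

  ts <- truth_spec_tdp(among = "confirmed")
  self <- transfer_cutoffs(native, tab, ts, native_rule = native)
  expect_identical(unclass(self$transferred), unclass(self$native))

  # discovery-cohort cut-offs on validation-like data: performance within a
  # few percentage points of the native rule
  both <- transfer_cutoffs(foreign, tab, truth_spec_tdp(among = "confirmed"),
                           native_rule = native)
  # score each rule with its own cut-offs
  native_perf <- evaluate_rule(tab, native, truth_spec_tdp(among = "confirmed"))
  expect_lt(abs(both$transferred$sensitivity$estimate -
                  native_perf$sensitivity$estimate), 10)
  expect_gt(both$transferred$sensitivity$estimate, 80)

  # degenerate rule: lower tau cut-off at 0 classifies nobody as PSP-like
  degen <- classification_rule(c(1e-9, 1.27), c(13.87, 56.18))
  psp_perf <- evaluate_rule(tab, degen, truth_spec_psp())
  expect_equal(psp_perf$sensitivity$estimate, 0)

  expect_error(transfer_cutoffs(native, tab[, c("subject_id", "tau_ratio")],
                                ts), "lacks columns")
})
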