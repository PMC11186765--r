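test_that("EM handles degenerate input and recovers planted parameters", {
  m0 <- em_fit(rep(3.2, 10), k = 1)
  expect_equal(m0$means, 3.2)
  expect_equal(m0$weights, 1)
  expect_lt(m0$sds, 1e-7)   # floored, not zero-collapsed
  expect_error(em_fit(rep(1, 20), k = 2), "identical")
  expect_error(em_fit(rnorm(8), k = 2), "5k")

  set.seed(2)
  x <- c(rnorm(500, -5, 0.5), rnorm(500, 5, 0.5))
  m <- em_fit(x, k = 2, seed = 9)
  expect_equal(m$means, c(-5, 5), tolerance = 0.15)
  expect_equal(m$weights, c(0.5, 0.5), tolerance = 0.05)
  expect_true(m$converged)
  expect_true(all(diff(m$means) > 0))  # sorted by mean
})

test_that("EM log-likelihood matches an established mixture fitter", {
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the calling frame
  set.seed(4)
  x <- c(rnorm(200, 0, 1), rnorm(150, 4, 0.7), rnorm(100, 9, 1.5))
  m <- em_fit(x, k = 3, seed = 2)
  mc <- mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  # same ML target: our best-of-starts should not be materially worse
  expect_gt(m$loglik, mc$loglik - 0.5)
  expect_equal(sort(m$means), sort(unname(mc$parameters$mean)), tolerance = 0.2)
})

test_that("bootstrap component selection picks the planted k", {
  set.seed(6)
  x1 <- rnorm(1000)
  b1 <- boot_comp(x1, k_max = 3, n_boot = 50, alpha = 0.05, seed = 3)
  expect_equal(b1$k, 1L)

  x3 <- c(rnorm(200, 0.4, 0.08), rnorm(200, 1.0, 0.1), rnorm(200, 2.5, 0.4))
  b3 <- boot_comp(x3, k_max = 3, n_boot = 50, alpha = 0.05, seed = 3)
  expect_equal(b3$k, 3L)

  expect_equal(boot_comp(x1, k_max = 1)$k, 1L)
  # deterministic under a fixed seed
  expect_identical(boot_comp(x1, k_max = 2, n_boot = 20, seed = 5),
                   boot_comp(x1, k_max = 2, n_boot = 20, seed = 5))
})

test_that("density crossings solve the closed form and verify sign changes", {
  # symmetric equal-sd pair: single crossing at the midpoint
  m <- make_mixture(c(0.5, 0.5), c(0, 2), c(1, 1))
  expect_equal(as.numeric(density_crossings(m, 1, 2)), 1)

  # weighted linear case: x = (9 + 2 ln 3) / 6
  m2 <- make_mixture(c(0.75, 0.25), c(0, 3), c(1, 1))
  expect_equal(as.numeric(density_crossings(m2, 1, 2, weighted = TRUE)),
               (9 + 2 * log(3)) / 6, tolerance = 1e-10)
  expect_equal(as.numeric(density_crossings(m2, 1, 2, weighted = TRUE)),
               1.86620, tolerance = 1e-5)

  # equal means, unequal sds: two symmetric crossings at +/- sqrt((8/3) ln 2)
  m3 <- make_mixture(c(0.5, 0.5), c(0, 0), c(1, 2))
  expect_equal(as.numeric(density_crossings(m3, 1, 2)),
               c(-1, 1) * sqrt(8 / 3 * log(2)), tolerance = 1e-10)

  # identical components: flagged, no isolated crossing
  m4 <- make_mixture(c(0.5, 0.5), c(1, 1), c(2, 2))
  cr <- density_crossings(m4, 1, 2)
  expect_length(cr, 0)
  expect_true(attr(cr, "identical"))
  expect_error(density_crossings(m4, 1, 1), "distinct")
})

test_that("crossings match the grid sign-scan oracle on random pairs", {
  set.seed(12)
  for (rep in 1:200) {
    w <- runif(2, 0.1, 0.9)
    mu <- sort(runif(2, -3, 3))
    s <- runif(2, 0.2, 2)
    m <- make_mixture(w / sum(w), mu, s)
    win <- oracle_window(mu[1], s[1], mu[2], s[2])
    ours <- as.numeric(density_crossings(m, 1, 2, weighted = TRUE))
    ours <- ours[ours >= win[1] & ours <= win[2]]
    ref <- oracle_crossings(m$weights[1], mu[1], s[1], m$weights[2], mu[2], s[2])
    expect_equal(length(ours), length(ref))
    if (length(ref)) expect_equal(ours, ref, tolerance = 1e-6)
  }
})

test_that("cut-off derivation picks the in-interval crossings", {
  # symmetric three-component model: cut-offs at -1 and 1 by symmetry
  sym <- make_mixture(rep(1 / 3, 3), c(-2, 0, 2), c(0.8, 0.8, 0.8))
  cs <- derive_cutoffs(sym, marker = "m", cohort = "c")
  expect_equal(cs$lower, -1, tolerance = 1e-12)
  expect_equal(cs$upper, 1, tolerance = 1e-12)

  # against the brute-force scan oracle
  mod <- make_mixture(rep(1 / 3, 3), c(0.45, 1.00, 2.30), c(0.10, 0.15, 0.60))
  cs2 <- derive_cutoffs(mod)
  o12 <- oracle_crossings(1 / 3, 0.45, 0.10, 1 / 3, 1.00, 0.15)
  o23 <- oracle_crossings(1 / 3, 1.00, 0.15, 1 / 3, 2.30, 0.60)
  expect_equal(cs2$lower, o12[o12 > 0.45 & o12 < 1.00][1], tolerance = 1e-6)
  expect_equal(cs2$upper, o23[o23 > 1.00 & o23 < 2.30][1], tolerance = 1e-6)

  expect_error(derive_cutoffs(make_mixture(c(0.5, 0.5), c(0, 1), c(1, 1))), "k = 3")
})

test_that("cut-offs are invariant to component label order and improve with n", {
  true_model <- make_mixture(c(0.3, 0.45, 0.25), c(0.45, 1.0, 2.3),
                             c(0.10, 0.15, 0.60))
  truth <- derive_cutoffs(true_model)

  sample_from <- function(n, seed) {
    set.seed(seed)
    cid <- sample.int(3, n, replace = TRUE, prob = true_model$weights)
    rnorm(n, true_model$means[cid], true_model$sds[cid])
  }
  err_at <- function(n, seed) {
    cs <- derive_cutoffs(em_fit(sample_from(n, seed), k = 3, seed = seed))
    abs(c(cs$lower - truth$lower, cs$upper - truth$upper))
  }
  e_small <- rowMeans(vapply(1:5, function(s) err_at(400, s), numeric(2)))
  e_big <- rowMeans(vapply(1:5, function(s) err_at(6400, s + 50), numeric(2)))
  expect_true(all(e_big < e_small))          # Monte-Carlo error shrinks with n
  expect_true(all(e_big < 0.1))

  # label-switching safety: different seeded starts, same sorted components
  x <- sample_from(1000, 99)
  c1 <- derive_cutoffs(em_fit(x, 3, seed = 1, n_starts = 2))
  c2 <- derive_cutoffs(em_fit(x, 3, seed = 77, n_starts = 6))
  expect_equal(c1$lower, c2$lower, tolerance = 1e-4)
  expect_equal(c1$upper, c2$upper, tolerance = 1e-4)
})

test_that("cohort-level cut-off fitting excludes confirmed cases and records provenance", {
  spec <- describe_subcohort2_spec()
  tab <- inject_pathology_labels(generate_cohort(spec, seed = 31), spec, seed = 32)
  cf <- cutoffs_from_cohort(tab, "tau_ratio", seed = 3, run_boot = FALSE)
  expect_s3_class(cf, "ev_cutoffs")
  expect_equal(cf$model$n, sum(tab$pathology == "unknown"))
  expect_lt(cf$lower, cf$upper)
  expect_true(cf$lower > cf$model$means[1] && cf$lower < cf$model$means[2])
  expect_true(cf$upper > cf$model$means[2] && cf$upper < cf$model$means[3])
  expect_error(cutoffs_from_cohort(tab, "nonesuch"), "unknown marker")
})
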