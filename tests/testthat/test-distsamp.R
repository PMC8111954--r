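test_that("truncation keeps the right observations and reports w", {
  d <- truncate_distances(c(5, 20, 54), "fixed", 55)
  expect_equal(nrow(d), 3)
  expect_equal(attr(d, "removed_fraction"), 0)
  expect_equal(attr(d, "w"), 55)

  withr::with_seed(1, x <- runif(1000, 0, 100))
  dp <- truncate_distances(x, "percent", 0.10)
  expect_equal(nrow(dp), 900)
  expect_equal(attr(dp, "w"), sort(x)[900])   # order-statistics oracle
  expect_equal(attr(dp, "removed_fraction"), 0.1)

  expect_error(truncate_distances(x, "percent", 1.2), "< 1")
  expect_error(truncate_distances(x, "fixed", -5), "positive")
  expect_error(truncate_distances(c(-1, 3), "fixed", 55), "nonnegative")
})

test_that("detection function closed forms evaluate correctly", {
  hn <- detection_model("half_normal", sigma = 20, w = 55)
  hr <- detection_model("hazard_rate", sigma = 15, b = 2.5, w = 55)
  un <- detection_model("uniform", w = 55)
  # g(0) = 1 for every key
  expect_equal(detection_g(hn, 0), 1)
  expect_equal(detection_g(hr, 0), 1)
  expect_equal(detection_g(un, 0), 1)
  expect_equal(detection_g(hn, 20), exp(-0.5))
  expect_equal(detection_g(hr, 30), 1 - exp(-(30 / 15)^(-2.5)))
  expect_equal(detection_g(hr, 30), 0.1620, tolerance = 1e-3)
  expect_error(detection_g(hn, 60), "within")
})

test_that("the likelihood matches a hand-computed value on three distances", {
  x <- c(5, 10, 20)
  # oracle: sum log g - n log integral, integral by midpoint quadrature
  g <- g_hn(15)
  ll_oracle <- sum(log(g(x))) - 3 * log(riemann(g, 0, 55, n = 2e5))
  nll <- settdensity:::neg_loglik(log(15), x, 55, "half_normal", "none",
                                  integer(0))
  expect_equal(-nll, ll_oracle, tolerance = 1e-6)
})

test_that("ESW matches closed forms and a brute-force quadrature oracle", {
  expect_equal(esw(detection_model("uniform", w = 55)), 55)
  # half-normal, effectively untruncated: sigma * sqrt(pi / 2)
  expect_equal(esw(detection_model("half_normal", sigma = 20, w = 1000)),
               20 * sqrt(pi / 2), tolerance = 1e-6)
  m <- detection_model("hazard_rate", sigma = 15, b = 2.5, w = 55)
  expect_equal(esw(m), riemann(function(u) detection_g(m, u), 0, 55),
               tolerance = 1e-4)
})

test_that("fitting recovers a known half-normal scale and satisfies the AIC identity", {
  withr::with_seed(42, x <- sim_distances(2000, g_hn(15), 55))
  d <- truncate_distances(x, "fixed", 55)
  m <- fit_detection(d, key = "half_normal")
  td <- tidy(m)
  expect_equal(td$term, "sigma")
  expect_lt(abs(td$estimate - 15), 3 * td$std.error)
  expect_equal(m$AIC, -2 * m$logLik + 2 * m$npar, tolerance = 1e-9)
  expect_lte(esw(m), m$w)
  # ESW grows with sigma for a fixed key
  esws <- vapply(c(10, 15, 20, 30), function(s) {
    esw(detection_model("half_normal", sigma = s, w = 55))
  }, 0)
  expect_true(all(diff(esws) > 0))
})

test_that("adjustment terms only stay when they lower AIC and keep g monotone", {
  withr::with_seed(43, x <- sim_distances(600, g_hn(18), 55))
  d <- truncate_distances(x, "fixed", 55)
  plain <- fit_detection(d, key = "half_normal")
  adj <- fit_detection(d, key = "half_normal", adjustment = "cosine")
  expect_lte(adj$AIC, plain$AIC + 1e-9)
  grid <- seq(0, 55, length.out = 500)
  gv <- detection_g(adj, grid)
  expect_true(all(diff(gv) <= 1e-5))
  expect_equal(gv[1], 1)
})

test_that("CDS post-stratification equals independent per-stratum fits", {
  withr::with_seed(44, {
    xa <- sim_distances(300, g_hn(20), 55)
    xb <- sim_distances(300, g_hn(10), 55)
  })
  d <- tibble::tibble(distance_m = c(xa, xb),
                      habitat = rep(c("forest", "hedgerow"), each = 300))
  strat <- fit_detection(d, key = "half_normal", strata = "habitat", w = 55)
  fa <- fit_detection(tibble::tibble(distance_m = xa), key = "half_normal",
                      w = 55)
  fb <- fit_detection(tibble::tibble(distance_m = xb), key = "half_normal",
                      w = 55)
  expect_equal(strat$logLik, fa$logLik + fb$logLik, tolerance = 1e-8)
  expect_equal(strat$npar, fa$npar + fb$npar)
  expect_equal(strat$AIC, fa$AIC + fb$AIC, tolerance = 1e-8)
  e <- esw(strat)
  expect_equal(e$esw_m[e$stratum == "forest"], esw(fa))
  # the wider-detection stratum has the larger effective strip
  expect_gt(e$esw_m[e$stratum == "forest"],
            e$esw_m[e$stratum == "hedgerow"])
})

test_that("MCDS log-linear scale recovers a covariate effect", {
  withr::with_seed(45, {
    xa <- sim_distances(400, g_hn(20), 55)
    xb <- sim_distances(400, g_hn(10), 55)
  })
  d <- tibble::tibble(distance_m = c(xa, xb),
                      sit = rep(c("forested", "hedgerow"), each = 400))
  m <- fit_detection(d, key = "half_normal", scale_covariates = "sit",
                     w = 55)
  expect_equal(m$npar, 2)
  s_for <- m$sigma[1]
  s_hed <- m$sigma[401]
  expect_equal(s_for, 20, tolerance = 0.15)
  expect_equal(s_hed, 10, tolerance = 0.15)
  expect_gt(detection_g(m, 20, covariates = list(sit = "forested")),
            detection_g(m, 20, covariates = list(sit = "hedgerow")))
})

test_that("model selection minimizes AIC with deterministic tie-breaking", {
  m1 <- detection_model("half_normal", sigma = 15, w = 55)
  m2 <- detection_model("hazard_rate", sigma = 15, b = 2.5, w = 55)
  m1$AIC <- 856.66; m1$npar <- 1L; m1$n <- 100L
  m2$AIC <- 875.30; m2$npar <- 2L; m2$n <- 100L
  expect_identical(select_model(list(m2, m1)), m1)
  expect_identical(select_model(list(m2)), m2)
  # tie: fewer parameters wins
  m2$AIC <- 856.66
  expect_identical(select_model(list(m2, m1)), m1)
  # tie on both: simpler key wins
  m3 <- m2; m3$npar <- 1L
  expect_identical(select_model(list(m3, m1))$key, "half_normal")
  m4 <- m1; m4$n <- 90L
  expect_error(select_model(list(m1, m4)), "different data")
})

test_that("goodness of fit reproduces hand-computed chi-squared values", {
  # uniform key, 2 bins on [0, 55]: expected 50/50; observed 60/40
  un <- detection_model("uniform", w = 55)
  un$distances <- c(runif(60, 0, 27.5), runif(40, 27.5, 55))
  un$n <- 100L
  got <- gof_chi2(un, n_bins = 2)
  expect_equal(got$chi2, 4.0, tolerance = 1e-6)
  expect_equal(got$df, 1)
  # df formula: 6 bins, 1-parameter key (scale wide enough that no
  # right-tail bin drops below an expected count of 1)
  withr::with_seed(46, x <- sim_distances(400, g_hn(20), 55))
  m <- fit_detection(truncate_distances(x, "fixed", 55),
                     key = "half_normal")
  g6 <- gof_chi2(m, n_bins = 6)
  expect_equal(g6$df, 4)
  expect_gt(g6$p_value, 0.001)
  # perfectly matching counts give chi2 = 0, p = 1 (uniform, any split)
  un2 <- detection_model("uniform", w = 40)
  un2$distances <- rep(c(5, 15, 25, 35), each = 25)
  un2$n <- 100L
  g0 <- gof_chi2(un2, n_bins = 4)
  expect_equal(g0$chi2, 0)
  expect_equal(g0$p_value, 1)
})

test_that("stratum density follows the closed form", {
  expect_equal(stratum_density(20, 10, 20), 50)
  expect_equal(stratum_density(0, 10, 20), 0)
  expect_equal(stratum_density(100, 80, 10.7), 100 / (2 * 0.0107 * 80))
  expect_equal(stratum_density(100, 80, 10.7), 58.41, tolerance = 1e-3)
  expect_error(stratum_density(5, 0, 20), "effort")
  expect_error(stratum_density(5, 10, -1), "positive")
})

test_that("bootstrap CV matches exhaustive enumeration on a two-transect toy", {
  # counts {0, 4}, equal lengths: resampled totals {0, 4, 8} with
  # probabilities {1/4, 1/2, 1/4}; CV = sd/mean = sqrt(8)/4
  bt <- bootstrap_density(c(0, 4), c(1, 1), esw_m = 20, exhaustive = TRUE)
  expect_equal(bt$cv, sqrt(8) / 4, tolerance = 1e-12)
  expect_equal(length(unique(attr(bt, "boot"))), 3)
  # sampled bootstrap is seed-reproducible and converges to the same CV
  b1 <- bootstrap_density(c(0, 4), c(1, 1), 20, B = 5000, seed = 9)
  b2 <- bootstrap_density(c(0, 4), c(1, 1), 20, B = 5000, seed = 9)
  expect_identical(b1, b2)
  expect_equal(b1$cv, sqrt(8) / 4, tolerance = 0.05)
  # identical transects: no between-transect variance
  b0 <- bootstrap_density(c(3, 3, 3), c(1, 1, 1), 20, B = 99, seed = 1)
  expect_equal(b0$cv, 0)
  expect_warning(bootstrap_density(c(0, 0), c(1, 1), 20, exhaustive = TRUE),
                 "undefined")
})

test_that("suitable-habitat correction scales densities and CIs alike", {
  expect_equal(apply_suitable_fraction(12.80, 1), 12.80)
  expect_equal(apply_suitable_fraction(0, 0.4), 0)
  # consistency with the published site C row: 12.80 * f = 3.55
  f <- 3.55 / 12.80
  expect_equal(apply_suitable_fraction(12.80, f), 3.55, tolerance = 1e-9)
  expect_error(apply_suitable_fraction(5, 0), "0, 1")
  expect_error(apply_suitable_fraction(5, 1.4), "0, 1")
})

test_that("too few observations or distances beyond w are rejected", {
  expect_error(fit_detection(tibble::tibble(distance_m = c(1, 2, 3)),
                             key = "half_normal", w = 55),
               "min_n")
  expect_error(fit_detection(tibble::tibble(distance_m = c(10, 60)),
                             key = "half_normal", w = 55, min_n = 2),
               "truncation")
})
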