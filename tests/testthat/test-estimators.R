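test_that("Wald ratios reproduce single-SNP estimates", {
  panel <- ua_ms_snps()
  wr <- wald_ratio(panel$dataset)

  # the strongest urate SNP gives a null MS estimate with a tight CI
  lead <- wr[wr$rsid == "rs12498742", ]
  expect_equal(lead$or, 1.00, tolerance = 0.005)
  expect_equal(lead$or_ci_low, 0.90, tolerance = 0.005)
  expect_equal(lead$or_ci_high, 1.11, tolerance = 0.005)

  # rounded published inputs give ~4.33 for the strongest outlier
  out <- wr[wr$rsid == "rs653178", ]
  expect_equal(out$estimate, log(0.95) / (-0.035))
  expect_equal(out$estimate, 1.4654, tolerance = 1e-4)
  expect_equal(out$or, 4.33, tolerance = 0.005)

  # unit denominator: estimate and SE pass through
  ds <- make_ds(bx = 1, bo = 0.3, so = 0.05)
  one <- wald_ratio(ds)
  expect_equal(one$estimate, 0.3)
  expect_equal(one$se, 0.05)

  # second-order SE adds the exposure-error term
  ds2 <- make_ds(bx = 0.2, bo = 0.1, so = 0.05, sx = 0.02)
  expect_equal(wald_ratio(ds2, second_order = TRUE)$se,
               sqrt(0.05^2 / 0.2^2 + 0.1^2 * 0.02^2 / 0.2^4))

  expect_error(wald_ratio(make_ds(bx = c(0.1, 0), bo = c(0, 0),
                                  so = c(1, 1))), "snp0002")
})

test_that("IVW pools ratios by inverse variance", {
  # weights 100 and 300 on ratios 0.2 and 0.4 -> weighted mean 0.35
  ds <- make_ds(bx = c(10, sqrt(300)), bo = c(2, 0.4 * sqrt(300)),
                so = c(1, 1))
  expect_equal(mr_ivw(ds)$estimate, 0.35)

  # k = 1 reduction: fixed-effects IVW is the Wald ratio
  one <- subset_dataset(ua_ms_snps()$dataset, 1)
  ivw1 <- mr_ivw(one, "fixed")
  wr1 <- wald_ratio(one)
  expect_equal(ivw1$estimate, wr1$estimate)
  expect_equal(ivw1$se, wr1$se)
  expect_error(mr_ivw(one, "multiplicative_random"), "at least 2")

  # identical point estimates under both effects models; random se >= fixed
  for (seed in 1:10) {
    ds <- random_ds(seed)
    f <- mr_ivw(ds, "fixed"); r <- mr_ivw(ds, "multiplicative_random")
    expect_equal(f$estimate, r$estimate)
    expect_gte(r$se, f$se)
  }
})

test_that("IVW equals the zero-intercept weighted regression oracle", {
  for (seed in 1:25) {
    ds <- random_ds(seed)
    oracle <- lm(beta_outcome ~ 0 + beta_exposure, data = ds,
                 weights = 1 / ds$se_outcome^2)
    expect_equal(mr_ivw(ds)$estimate, unname(coef(oracle)),
                 tolerance = 1e-12)
  }
})

test_that("Egger regression recovers slope and intercept", {
  # collinear data: exact slope 0.5, intercept 0.01, zero residual scale
  bx <- c(0.1, 0.2, 0.3, 0.4)
  ds <- make_ds(bx = bx, bo = 0.01 + 0.5 * bx, so = c(0.02, 0.03, 0.01, 0.05))
  eg <- mr_egger(ds)
  expect_equal(eg$slope$estimate, 0.5)
  expect_equal(eg$intercept$estimate, 0.01)
  expect_equal(eg$residual_scale, 0, tolerance = 1e-7)

  # directional pleiotropy with InSIDE holding: slope and intercept are
  # recovered within 2 SE at low noise
  sim <- simulate_two_sample(theta = 0.1, k = 50, pleiotropy = "directional",
                             pleiotropy_mean = 0.02, pleiotropy_sd = 0.005,
                             se_exposure = 0.002, se_outcome = 0.005,
                             seed = 401)
  eg2 <- mr_egger(sim_to_ds(sim))
  expect_lt(abs(eg2$slope$estimate - 0.1), 2 * eg2$slope$se)
  expect_lt(abs(eg2$intercept$estimate - 0.02), 2 * eg2$intercept$se)

  expect_error(mr_egger(make_ds(bx = c(1, 1), bo = c(0, 0), so = c(1, 1))),
               "at least 3")
})

test_that("Egger agrees with IVW on pleiotropy-free data", {
  agree <- 0
  for (seed in 1:500) {
    sim <- simulate_two_sample(theta = 0.1, k = 18, pleiotropy = "none",
                               seed = 5000 + seed)
    ds <- sim_to_ds(sim)
    eg <- mr_egger(ds)$slope
    iv <- mr_ivw(ds)
    if (abs(eg$estimate - iv$estimate) <
        2 * sqrt(eg$se^2 + iv$se^2)) agree <- agree + 1
  }
  expect_gte(agree / 500, 0.95)
})

test_that("weighted median interpolates cumulative weights at 0.5", {
  # equal weighting, odd k: the plain middle ratio
  ds <- make_ds(bx = c(1, 1, 1), bo = c(0.1, 0.5, 0.2), so = c(1, 2, 3))
  wm <- mr_weighted_median(ds, weighting = "equal", n_boot = 200, seed = 1)
  expect_equal(wm$estimate, 0.2)

  # ratios {0, 0, 1} with weights {10, 10, 1}: interpolation stays at 0
  ds2 <- make_ds(bx = c(sqrt(10), sqrt(10), 1), bo = c(0, 0, 1),
                 so = c(1, 1, 1))
  expect_equal(mr_weighted_median(ds2, n_boot = 200, seed = 1)$estimate, 0)

  expect_warning(mr_weighted_median(ds, n_boot = 50, seed = 1), "n_boot")
  expect_error(mr_weighted_median(ds), "seed")
  expect_error(mr_weighted_median(subset_dataset(ds, 1:2), seed = 1),
               "at least 3")
})

test_that("mode-based estimator follows the largest ratio cluster", {
  # degenerate cluster: all ratios equal
  ds <- make_ds(bx = c(1, 2, 4), bo = c(0.3, 0.6, 1.2), so = c(1, 1, 1))
  md <- mr_mode(ds, n_boot = 200, seed = 1)
  expect_equal(md$estimate, 0.3)
  expect_equal(md$se, 1 / sqrt(sum(c(1, 4, 16))))  # IVW fixed SE

  # 7 ratios near 0 vs 3 near 0.5, equal kernel weights: mode near 0
  set.seed(42)
  r <- c(rnorm(7, 0, 0.01), rnorm(3, 0.5, 0.01))
  ds2 <- make_ds(bx = rep(1, 10), bo = r, so = rep(1, 10))
  md2 <- mr_mode(ds2, weighted = FALSE, n_boot = 200, seed = 2)
  expect_lt(abs(md2$estimate), 0.1)

  expect_error(mr_mode(ds), "seed")
})

test_that("estimates are invariant under permutation and sign-equivariant", {
  ds <- random_ds(99, k = 10)
  perm <- subset_dataset(ds, sample(seq_len(nrow(ds))))
  for (fun in list(
    function(d) mr_ivw(d)$estimate,
    function(d) mr_egger(d)$slope$estimate,
    function(d) unlist(mr_weighted_median(d, n_boot = 200, seed = 7)[
      c("estimate", "se")]),
    function(d) unlist(mr_mode(d, n_boot = 200, seed = 7)[
      c("estimate", "se")])))
    expect_equal(fun(perm), fun(ds))

  # negating both exposure and outcome leaves estimates unchanged;
  # negating only the outcome negates them
  flip_both <- make_ds(bx = -ds$beta_exposure, bo = -ds$beta_outcome,
                       so = ds$se_outcome, sx = ds$se_exposure,
                       rsid = ds$rsid)
  flip_out <- make_ds(bx = ds$beta_exposure, bo = -ds$beta_outcome,
                      so = ds$se_outcome, sx = ds$se_exposure,
                      rsid = ds$rsid)
  expect_equal(mr_ivw(flip_both)$estimate, mr_ivw(ds)$estimate)
  expect_equal(mr_ivw(flip_out)$estimate, -mr_ivw(ds)$estimate)
  expect_equal(mr_egger(flip_both)$slope$estimate,
               mr_egger(ds)$slope$estimate)
  expect_equal(mr_weighted_median(flip_both, n_boot = 200, seed = 3)$estimate,
               mr_weighted_median(ds, n_boot = 200, seed = 3)$estimate)
  expect_equal(mr_weighted_median(flip_out, n_boot = 200, seed = 3)$estimate,
               -mr_weighted_median(ds, n_boot = 200, seed = 3)$estimate)
})

test_that("mr_fit collects all methods with working S3 methods", {
  ds <- ua_ms_snps()$dataset
  fit <- mr_fit(ds, n_boot = 200, seed = 11)
  expect_s3_class(fit, "mr_fit")
  expect_equal(nrow(fit$results), 5)
  expect_setequal(fit$results$method,
                  c("ivw_fixed", "ivw_random", "egger", "weighted_median",
                    "mode_based"))
  expect_equal(unname(coef(fit)["ivw_random"]), mr_ivw(ds)$estimate)
  ci <- confint(fit)
  expect_equal(ci["ivw_random", 1], mr_ivw(ds)$ci_low)
  expect_output(print(summary(fit)), "Egger intercept")
  expect_error(mr_fit(ds), "seed")

  # bootstrap seed makes results exactly reproducible
  fit2 <- mr_fit(ds, n_boot = 200, seed = 11)
  expect_identical(fit$results, fit2$results)
})
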