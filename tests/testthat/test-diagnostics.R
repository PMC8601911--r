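test_that("parametric-bootstrap GOF behaves on well-specified data and rejects bad input", {
  sim <- make_sim_data(150, c(intercept = 1, grassland = 0.8),
                       c(intercept = 0.5, jdate = -0.3),
                       offset_area_km2 = 1, cov_seed = 21, count_seed = 22)
  spec <- removal_model_spec(abund = "grassland", det = "jdate",
                             offset_area_km2 = 1)
  fit <- fit_removal(sim$counts, sim$covariates, spec)
  g <- gof_parametric_bootstrap(fit, nboot = 30, seed = 5)
  expect_gte(g$p_value, 0)
  expect_lte(g$p_value, 1)
  expect_gt(g$chat, 0.5)
  expect_lt(g$chat, 2)
  # deterministic given seed
  g2 <- gof_parametric_bootstrap(fit, nboot = 30, seed = 5)
  expect_identical(g$chisq_boot, g2$chisq_boot)
  expect_error(gof_parametric_bootstrap(fit, nboot = 0), "positive")
})

test_that("holdout cross-validation approaches the Poisson noise floor", {
  sim <- make_sim_data(2000, c(intercept = 1), c(intercept = 0.5),
                       offset_area_km2 = 1, cov_seed = 31, count_seed = 32)
  spec <- removal_model_spec(abund = character(0), det = character(0),
                             offset_area_km2 = 1)
  cv <- crossval_holdout(sim$counts, sim$covariates, spec, seed = 7)
  expect_true(cv$converged)
  # held-out totals are Poisson, so RMSE^2 should approach the mean
  # expected total (variance = mean); generous simulation tolerance
  etot <- exp(1) * (1 - (1 - plogis(0.5))^5)
  expect_lt(abs(cv$rmse^2 - etot) / etot, 0.2)
  expect_lt(cv$mae, cv$rmse)
  # deterministic given seed
  cv2 <- crossval_holdout(sim$counts, sim$covariates, spec, seed = 7)
  expect_identical(cv$rmse, cv2$rmse)
  expect_error(crossval_holdout(sim$counts, sim$covariates, spec,
                                holdout_frac = 0), "holdout_frac")
})

test_that("rank AUC separates informative models from null ones", {
  # degenerate check of the rank statistic itself
  expect_equal(grasslandRTR:::auc_rank(c(0.9, 0.8, 0.2, 0.1),
                                       c(1, 1, 0, 0)), 1)
  expect_equal(grasslandRTR:::auc_rank(c(0.1, 0.2, 0.8, 0.9),
                                       c(1, 1, 0, 0)), 0)

  # strong covariate effect (lambda spans orders of magnitude): high AUC
  sims <- make_sim_data(600, c(intercept = 0, grassland = 3),
                        c(intercept = 0.5), offset_area_km2 = 1,
                        cov_seed = 41, count_seed = 42)
  spec <- removal_model_spec(abund = "grassland", det = character(0),
                             offset_area_km2 = 1)
  a <- auc_holdout(sims$counts, sims$covariates, spec, reps = 5, seed = 3)
  expect_gt(a$mean_auc, 0.9)
  expect_true(a$acceptable)

  # covariate-free truth scored by a covariate-only model: AUC near 0.5
  simn <- make_sim_data(2000, c(intercept = 0.3), c(intercept = 0.5),
                        offset_area_km2 = 1, cov_seed = 43, count_seed = 44)
  simn$covariates$grassland <- grasslandRTR:::with_seed(45, rnorm(2000))
  an <- auc_holdout(simn$counts, simn$covariates, spec, reps = 10, seed = 4)
  expect_lt(abs(an$mean_auc - 0.5), 0.05)
})

test_that("Spearman's rho tracks observed-predicted agreement", {
  sim <- make_sim_data(1000, c(intercept = 1, grassland = 1),
                       c(intercept = 0.5), offset_area_km2 = 1,
                       cov_seed = 51, count_seed = 52)
  spec <- removal_model_spec(abund = "grassland", det = character(0),
                             offset_area_km2 = 1)
  fit <- fit_removal(sim$counts, sim$covariates, spec)
  rs <- spearman_obs_pred(fit)
  expect_gt(rs$rho, 0.3)
  # intercept-only model: constant predictions, rho undefined
  spec0 <- removal_model_spec(abund = character(0), det = character(0),
                              offset_area_km2 = 1)
  fit0 <- fit_removal(sim$counts, sim$covariates, spec0)
  rs0 <- spearman_obs_pred(fit0)
  expect_true(is.na(rs0$rho))
  expect_match(rs0$note, "constant")
})

test_that("Moran correlogram keeps permuted residuals inside the null envelope", {
  n <- 150
  sim <- make_sim_data(n, c(intercept = 1.5), c(intercept = 0.5),
                       offset_area_km2 = 1, cov_seed = 61, count_seed = 62)
  sites <- grasslandRTR:::with_seed(63, data.frame(
    site_id = seq_len(n), x = runif(n, 0, 40000), y = runif(n, 0, 40000)))
  spec <- removal_model_spec(abund = character(0), det = character(0),
                             offset_area_km2 = 1)
  fit <- fit_removal(sim$counts, sim$covariates, spec)
  mor <- residual_moran_correlogram(fit, sites, max_dist = 30000,
                                    n_bins = 10, nboot = 200, seed = 9)
  filled <- !is.na(mor$bins$I)
  expect_gte(mean(mor$bins$in_envelope[filled]), 0.9)
  # iid residuals: no residual autocorrelation declared
  expect_true(mor$no_autocorrelation ||
                sum(!mor$bins$in_envelope) <= 1)
  # deterministic given seed
  mor2 <- residual_moran_correlogram(fit, sites, max_dist = 30000,
                                     n_bins = 10, nboot = 200, seed = 9)
  expect_identical(mor$bins, mor2$bins)
})
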