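test_that("removal cell probabilities follow the geometric decay and sum to one", {
  expect_equal(unname(removal_cell_probs(1, 5)), c(1, 0, 0, 0, 0, 0))
  expect_equal(unname(removal_cell_probs(0.5, 5)),
               c(0.5, 0.25, 0.125, 0.0625, 0.03125, 0.03125))
  expect_equal(unname(removal_cell_probs(0.3, 5)),
               c(0.3, 0.21, 0.147, 0.1029, 0.07203, 0.16807))
  for (p in seq(0, 1, by = 0.05)) {
    cp <- removal_cell_probs(p, 5)
    expect_equal(sum(cp), 1)
    expect_equal(unname(cp[1:5]), p * (1 - p)^(0:4))
  }
  expect_error(removal_cell_probs(1.2, 5), "domain")
  expect_error(removal_cell_probs(-0.1, 5), "domain")
})

test_that("marginal likelihood matches the latent-N oracle and the offset identity", {
  spec <- removal_model_spec(abund = character(0), det = character(0))
  A <- spec$offset_area_km2
  cnt <- data.frame(site_id = 1, y1 = 1, y2 = 1, y3 = 0, y4 = 0, y5 = 0)
  cov <- data.frame(row.names = 1)
  # closed form vs explicit truncated latent-N sum
  par <- c(log(2 / A), qlogis(0.5))
  expect_lt(abs(removal_negloglik(par, cnt, cov, spec) -
                oracle_removal_nll(2, 0.5, c(1, 1, 0, 0, 0))), 1e-8)
  # empty site at p = 1: contribution is exactly lambda*A
  cnt0 <- data.frame(site_id = 1, y1 = 0, y2 = 0, y3 = 0, y4 = 0, y5 = 0)
  lamA <- 3.7
  expect_equal(removal_negloglik(c(log(lamA / A), 40), cnt0, cov, spec), lamA)
  # offset identity: (lambda, A) -> (lambda/2, 2A) leaves likelihood unchanged
  spec2 <- removal_model_spec(abund = character(0), det = character(0),
                              offset_area_km2 = 2 * A)
  expect_equal(removal_negloglik(par, cnt, cov, spec),
               removal_negloglik(c(par[1] - log(2), par[2]), cnt, cov, spec2))
})

test_that("maximum-likelihood fit satisfies the intercept stationarity identity", {
  # for intercept-only abundance and detection, the MLE solves
  # mean(T) = A * lambda-hat * (1 - (1 - p-hat)^J)
  sim <- make_sim_data(400, c(intercept = 3), c(intercept = 0.3),
                       offset_area_km2 = 1, cov_seed = 8, count_seed = 9)
  spec <- removal_model_spec(abund = character(0), det = character(0),
                             offset_area_km2 = 1)
  fit <- fit_removal(sim$counts, sim$covariates, spec)
  expect_true(fit$converged)
  lam <- exp(fit$beta_abund[["intercept"]])
  p <- plogis(fit$beta_det[["intercept"]])
  expect_equal(lam * (1 - (1 - p)^5), mean(sim$counts$total),
               tolerance = 1e-6)
})

test_that("fitting recovers known coefficients on simulated data", {
  truth_a <- c(intercept = 1.2, grassland = 0.8)
  truth_d <- c(intercept = 0.4, jdate = -0.3)
  spec <- removal_model_spec(abund = "grassland", det = "jdate")
  ests <- t(vapply(1:10, function(r) {
    sim <- make_sim_data(300, truth_a, truth_d, cov_seed = 100 + r,
                         count_seed = 200 + r)
    fit <- fit_removal(sim$counts, sim$covariates, spec)
    expect_true(fit$converged)
    c(fit$beta_abund, fit$beta_det)
  }, numeric(4)))
  truth <- c(truth_a, truth_d)
  emp_se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  expect_true(all(abs(colMeans(ests) - truth) <= 3 * emp_se))
  # too few sites for the parameter count
  sim <- make_sim_data(4, truth_a, truth_d)
  expect_error(fit_removal(sim$counts, sim$covariates, spec), "few sites")
})

test_that("overdispersion adjustment floors c-hat at one and scales errors by its root", {
  sim <- make_sim_data(200, c(intercept = 2), c(intercept = 0.3),
                       cov_seed = 3, count_seed = 4)
  spec <- removal_model_spec(abund = character(0), det = character(0))
  fit <- fit_removal(sim$counts, sim$covariates, spec)
  base_se <- fit$se
  f1 <- overdispersion_adjust(fit, 0.7)
  expect_equal(f1$chat, 1)
  expect_equal(f1$se, base_se)
  f4 <- overdispersion_adjust(fit, 4)
  expect_equal(f4$se, 2 * base_se)
  expect_equal(f4$beta_abund, fit$beta_abund)  # point estimates unchanged
  fid <- overdispersion_adjust(fit, 1)
  expect_equal(fid$se, base_se)
  expect_error(overdispersion_adjust(fit, -2), "domain")
})

test_that("density prediction applies joint coefficient shifts on the log link", {
  fake <- structure(list(
    beta_abund = c(intercept = 0),
    beta_det = c(intercept = 0),
    se = c(abund.intercept = 0.5, det.intercept = 0.1),
    spec = removal_model_spec(abund = character(0), det = character(0)),
    chat = 1
  ), class = "removal_fit")
  pred <- predict_expected_density(fake, data.frame(row.names = 1))
  expect_equal(pred$point, 1)
  expect_equal(pred$minus, exp(-0.98))
  expect_equal(pred$plus, exp(0.98))
  # zero standard errors: all three layers identical
  fake$se[] <- 0
  pr0 <- predict_expected_density(fake, data.frame(row.names = 1))
  expect_equal(pr0$minus, pr0$point)
  expect_equal(pr0$plus, pr0$point)
  # prediction at the covariate means is exp(intercept)
  fake2 <- fake
  fake2$beta_abund <- c(intercept = 1.3, grassland = 0.7)
  fake2$se <- c(abund.intercept = 0, abund.grassland = 0, det.intercept = 0)
  pr <- predict_expected_density(fake2, data.frame(grassland = 0))
  expect_equal(pr$point, exp(1.3))
  expect_error(predict_expected_density(fake2, data.frame(urban = 1)),
               "missing covariates")
})

test_that("effect sizes are exact log-link ratios", {
  fake <- structure(list(
    beta_abund = c(intercept = 0.5, grassland = 0.3, urban = 0),
    beta_det = c(intercept = 0),
    se = c(abund.intercept = 0.1, abund.grassland = 0.05, abund.urban = 0.2,
           det.intercept = 0.1),
    spec = removal_model_spec(abund = c("grassland", "urban"),
                              det = character(0)),
    chat = 1
  ), class = "removal_fit")
  es <- covariate_effect_size(fake, "grassland")
  expect_equal(es$ratio, exp(0.3))
  expect_equal(es$ratio, 1.3499, tolerance = 1e-4)
  expect_equal(es$density_at_mean, exp(0.5))
  es0 <- covariate_effect_size(fake, "urban")
  expect_equal(es0$ratio, 1)
  expect_equal(es0$absolute, 0)
  expect_error(covariate_effect_size(fake, "precip"), "unknown")
})
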