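test_that("land-cover generation hits target fractions and is deterministic", {
  # degenerate mixture: everything grassland
  cfg1 <- landscape_config(extent = c(40, 40),
                           class_fractions = c(grassland = 1, agriculture = 0,
                                               forest = 0, urban = 0),
                           seed = 3)
  lc1 <- generate_landcover(cfg1)
  expect_true(all(lc1$values == 1L))

  # determinism: same config, two calls, bit-identical
  cfg2 <- landscape_config(extent = c(80, 80), seed = 11)
  expect_identical(generate_landcover(cfg2), generate_landcover(cfg2))

  # realized proportions approach targets across seeds
  fr <- c(grassland = 0.3, agriculture = 0.3, forest = 0.3, urban = 0.1)
  for (s in 1:5) {
    cfg <- landscape_config(extent = c(300, 300), class_fractions = fr,
                            seed = s)
    lc <- generate_landcover(cfg)
    realized <- tabulate(lc$values, 4) / length(lc$values)
    expect_true(all(abs(realized - fr) <= 0.02))
  }

  # invalid fractions rejected
  expect_error(landscape_config(class_fractions = c(grassland = 0.5,
                                                    agriculture = 0.5,
                                                    forest = 0.5,
                                                    urban = -0.5)),
               "class_fractions")
  expect_error(landscape_config(fine_cellsize = 300, coarse_cellsize = 1000),
               "divide")
})

test_that("climate surfaces are finite, smooth and deterministic", {
  cfg <- landscape_config(extent = c(100, 100), seed = 5)
  cl <- generate_climate(cfg)
  expect_true(all(is.finite(cl$tmax$values)))
  expect_true(all(is.finite(cl$precip$values)))
  expect_identical(cl, generate_climate(cfg))
  # the configured west-east trend shows in cell means
  expect_gt(mean(cl$tmax$values[, 90:100]), mean(cl$tmax$values[, 1:10]))
})

test_that("conservation network nests GBCAs, keeps them disjoint, and sits in suitable grassland", {
  cfg <- landscape_config(extent = c(300, 300), autocorrelation_range = 2000,
                          seed = 7)
  lc <- generate_landcover(cfg)
  net <- generate_conservation_network(cfg, lc, n_focal = 1L,
                                       gbcas_per_focal = 3L,
                                       focal_area_km2 = 80, gbca_area_km2 = 5)
  gcov <- grid_cell_covariates(lc, coarse_cellsize = 1000)
  nr <- max(gcov$row)
  unsuit <- matrix(FALSE, nr, max(gcov$col))
  unsuit[cbind(gcov$row, gcov$col)] <- (gcov$forest + gcov$urban) >= 0.5
  fl <- net$landscapes[[1]]
  focal_keys <- grasslandRTR:::cell_key(fl$footprint$cells, nr)
  gbca_keys <- lapply(fl$gbcas, function(g)
    grasslandRTR:::cell_key(g$cells, nr))
  # nesting: every GBCA cell inside its focal landscape
  for (k in gbca_keys) expect_true(all(k %in% focal_keys))
  # pairwise disjoint GBCAs
  expect_equal(length(unlist(gbca_keys)), length(unique(unlist(gbca_keys))))
  # unsuitable-habitat fraction <= 0.20 for every footprint
  expect_lte(mean(unsuit[fl$footprint$cells]), 0.20)
  for (g in fl$gbcas) expect_lte(mean(unsuit[g$cells]), 0.20)
  # realized area within 5% of request
  expect_lt(abs(fl$footprint$area_km2 - 80) / 80, 0.05)
  # infeasible request errors with the constraint named
  expect_error(generate_conservation_network(cfg, lc, n_focal = 2L,
                                             focal_area_km2 = 1e5),
               "exceed")
})

test_that("survey sites respect spacing, dates and determinism; infeasible packing errors", {
  cfg <- landscape_config(extent = c(100, 100), seed = 13)  # 10 x 10 km
  sites <- generate_survey_sites(cfg, n_sites = 60)
  d <- as.matrix(dist(cbind(sites$x, sites$y)))
  diag(d) <- Inf
  expect_gt(min(d), 400)
  expect_true(all(sites$jdate >= 140 & sites$jdate <= 190))
  expect_identical(sites, generate_survey_sites(cfg, n_sites = 60))
  # far beyond the packing bound: immediate error
  small <- landscape_config(extent = c(10, 10), seed = 13)  # 1 x 1 km
  expect_error(generate_survey_sites(small, n_sites = 100), "infeasible")
})

test_that("simulated removal counts follow the Poisson x removal process", {
  # p = 1: every detected individual falls in the first interval
  sim1 <- make_sim_data(200, c(intercept = 3), c(intercept = 20),
                        cov_seed = 1, count_seed = 5)
  ymat <- as.matrix(sim1$counts[paste0("y", 1:5)])
  expect_true(all(ymat[, 2:5] == 0))
  expect_gt(sum(ymat[, 1]), 0)

  # vanishing density: all-zero counts
  sim0 <- make_sim_data(200, c(intercept = -30), c(intercept = 0),
                        count_seed = 6)
  expect_true(all(sim0$counts$total == 0))

  # Monte-Carlo mean vs closed form: lamA = 2, p = 0.5, J = 5
  # E[total] = 2 * (1 - 0.5^5) = 1.9375
  n <- 10000
  simm <- make_sim_data(n, c(intercept = log(2)), c(intercept = 0),
                        offset_area_km2 = 1, count_seed = 7)
  tot <- simm$counts$total
  mc_se <- sd(tot) / sqrt(n)
  expect_lt(abs(mean(tot) - 1.9375), 3 * mc_se)

  # conservation: interval counts sum to the detected total
  expect_equal(rowSums(simm$counts[paste0("y", 1:5)]), simm$counts$total)

  # interval fractions match the truncated geometric p(1-p)^(j-1)/(1-(1-p)^J)
  ym <- as.matrix(simm$counts[paste0("y", 1:5)])
  frac <- colSums(ym) / sum(ym)
  expected <- 0.5^(1:5) / (1 - 0.5^5)
  se <- sqrt(expected * (1 - expected) / sum(ym))
  expect_true(all(abs(frac - expected) <= 3 * se))

  # non-finite linear predictor is an error
  bad <- data.frame(grassland = c(1, Inf))
  expect_error(simulate_point_counts(
    data.frame(site_id = 1:2), bad,
    true_parameters(c(intercept = 0, grassland = 1), c(intercept = 0)),
    seed = 1), "non-finite")
})
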