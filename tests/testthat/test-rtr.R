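test_that("suitability mask implements the 50% unsuitable-cover rule", {
  g <- data.frame(row = c(1, 1, 2, 2), col = c(1, 2, 1, 2),
                  grassland = c(0.4, 0.51, 1, 0.5),
                  agriculture = 0,
                  forest = c(0.4, 0.49, 0, 0.2),
                  urban = c(0.2, 0, 0, 0.3))
  mask <- build_suitability_mask(g)
  expect_false(mask$suitable[1, 1])  # forest 0.4 + urban 0.2 = 0.6 >= 0.5
  expect_true(mask$suitable[1, 2])   # 0.49 < 0.5
  expect_true(mask$suitable[2, 1])   # all grassland
  expect_false(mask$suitable[2, 2])  # exactly 0.5 triggers the rule
  expect_error(build_suitability_mask(data.frame(row = 1, col = 1)),
               "forest")
})

test_that("identity and quarter-turn poses preserve footprints exactly", {
  gd <- c(40, 40)
  fp <- make_blob_footprint(gd, 30, seed = 2)
  src <- grasslandRTR:::rtr_source(fp, gd)
  reg <- grasslandRTR:::rtr_region(full_grid_footprint(gd), gd)
  # identity pose: translation equal to the source centroid, no rotation
  placed <- grasslandRTR:::rtr_try_pose(
    src, reg, gd, pose = list(theta = 0, tx = src$centroid[1],
                              ty = src$centroid[2]))
  expect_equal(placed[order(placed[, 1], placed[, 2]), , drop = FALSE],
               unname(fp$cells), ignore_attr = TRUE)
  # quarter-turn of a square footprint: identical cell count
  sq <- footprint(as.matrix(expand.grid(10:15, 10:15)))
  ssq <- grasslandRTR:::rtr_source(sq, gd)
  placed90 <- grasslandRTR:::rtr_try_pose(
    ssq, reg, gd, pose = list(theta = pi / 2, tx = ssq$centroid[1],
                              ty = ssq$centroid[2]))
  expect_equal(nrow(placed90), nrow(sq$cells))
})

test_that("random poses preserve cell count within the rasterization tolerance", {
  gd <- c(120, 120)
  fp <- make_blob_footprint(gd, 150, seed = 6)
  region <- full_grid_footprint(gd)
  grasslandRTR:::with_seed(10, {
    for (i in 1:200) {
      rep <- rtr_place_footprint(fp, region, gd)
      expect_lte(abs(nrow(rep$cells) - 150), 0.05 * 150)
    }
  })
  # a footprint larger than its region cannot be placed
  tiny <- footprint(cbind(1:2, 1:2))
  expect_error(rtr_place_footprint(fp, tiny, gd), "cannot fit")
})

test_that("ensembles place disjointly or fail loudly", {
  gd <- c(80, 80)
  fps <- lapply(1:3, function(i) make_blob_footprint(gd, 12, seed = 20 + i,
                                                     name = paste0("g", i)))
  region <- full_grid_footprint(gd)
  grasslandRTR:::with_seed(30, {
    for (i in 1:20) {
      pe <- place_ensemble(fps, region, gd)
      keys <- unlist(lapply(pe, function(f)
        grasslandRTR:::cell_key(f$cells, gd[1])))
      expect_equal(length(keys), length(unique(keys)))
    }
  })
  # combined area exceeding the region is rejected up front
  big <- lapply(1:2, function(i) make_blob_footprint(c(300, 300), 600,
                                                     seed = 40 + i))
  small_region <- footprint(as.matrix(expand.grid(1:30, 1:30)))
  expect_error(place_ensemble(big, small_region, c(300, 300)), "exceeds")
})

test_that("null distributions respect constraints and degenerate correctly", {
  gd <- c(60, 60)
  fp <- make_blob_footprint(gd, 20, seed = 3)
  region <- full_grid_footprint(gd)
  mask <- make_open_mask(gd)
  # uniform surface: every replicate mean equals the constant
  sfu <- density_surface(matrix(3.3, gd[1], gd[2]))
  nd <- generate_null_distribution(fp, region, sfu, mask, n = 50, seed = 4)
  expect_equal(nd$values, rep(3.3, 50))
  # fully suitable landscape with unsuit_frac 0: zero rejections
  nd0 <- generate_null_distribution(fp, region, sfu, mask, n = 50,
                                    unsuit_frac = 0, seed = 4)
  expect_equal(nd0$rejected_unsuitable, 0)
  # determinism: identical seed, identical distribution
  sfr <- density_surface(grasslandRTR:::with_seed(5,
    matrix(runif(gd[1] * gd[2]), gd[1], gd[2])))
  n1 <- generate_null_distribution(fp, region, sfr, mask, n = 100, seed = 8)
  n2 <- generate_null_distribution(fp, region, sfr, mask, n = 100, seed = 8)
  expect_identical(n1$values, n2$values)
  # high-density quadrant: null mean approximates the spatial average of
  # replicate placements (computed over several runs vs direct average)
  m <- matrix(1, gd[1], gd[2]); m[1:30, 1:30] <- 10
  sfq <- density_surface(m)
  runs <- vapply(1:5, function(s)
    mean(generate_null_distribution(fp, region, sfq, mask, n = 200,
                                    seed = s)$values), 0)
  mc_se <- sd(runs) / sqrt(5)
  # placements are uniform over the grid (all suitable), so the long-run
  # replicate mean approaches the overall spatial mean
  expect_lt(abs(mean(runs) - mean(m)), max(3 * mc_se, 0.15))
})

test_that("representation test flags only baselines above the 90th percentile", {
  null <- 1:100
  r <- representation_test(1000, null)
  expect_true(r$flagged)
  expect_equal(r$baseline_quantile, 1)
  rmed <- representation_test(stats::median(null), null)
  expect_false(rmed$flagged)
  expect_error(representation_test(1, numeric(0)), "empty")
})

test_that("scenarios flag constructed hotspots and nothing on uniform surfaces", {
  gd <- c(70, 70)
  net <- make_rect_network(gd, list(c(5, 5), c(5, 50), c(50, 50)))
  mask <- make_open_mask(gd)
  # species concentrated inside FL-1 only
  m <- matrix(1, gd[1], gd[2])
  fl1 <- net$landscapes[[1]]$footprint
  m[fl1$cells] <- 10
  surfaces <- list(conc = density_surface(m, species = "conc"),
                   unif = density_surface(matrix(2, gd[1], gd[2]),
                                          species = "unif"))
  sc <- run_scenario("focal_vs_state", net, surfaces, mask,
                     n_replicates = 200, seed = 12)
  res <- sc$results
  expect_true(res$flagged[res$species == "conc" & res$area == "FL-1"])
  expect_false(any(res$flagged[res$species == "conc" & res$area != "FL-1"]))
  # uniform species never flagged
  expect_false(any(res$flagged[res$species == "unif"]))
  # representation count equals the number of flagged species per area
  for (a in sc$counts$area)
    expect_equal(sc$counts$n_represented[sc$counts$area == a],
                 sum(res$flagged[res$area == a]))
  expect_error(run_scenario("bogus", net, surfaces, mask), "unknown")
})
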