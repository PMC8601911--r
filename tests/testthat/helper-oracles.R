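# Shared oracles and fixture builders (all fixtures generated in code).

# Independent brute-force oracle for the removal marginal likelihood: the
# explicit truncated sum over the latent site abundance N of
# Poisson(N; lamA) x Multinomial(y, N - T missed; removal cell probs).
oracle_removal_nll <- function(lamA, p, y, K = 500) {
  J <- length(y)
  Tt <- sum(y)
  pi <- c(p * (1 - p)^(0:(J - 1)), (1 - p)^J)
  lps <- vapply(Tt:K, function(N) {
    cells <- c(y, N - Tt)
    dpois(N, lamA, log = TRUE) + lgamma(N + 1) - sum(lgamma(cells + 1)) +
      sum(ifelse(cells > 0, cells * log(pi), 0))
  }, 0)
  m <- max(lps)
  -(m + log(sum(exp(lps - m))))
}

# Exhaustive minimum-set oracle: smallest subset of values whose sum
# reaches target_frac of the total (checked by subset size, ascending).
oracle_minimum_set_size <- function(values, target_frac) {
  need <- target_frac * sum(values)
  n <- length(values)
  for (k in seq_len(n)) {
    sums <- combn(values, k, FUN = sum)
    if (any(sums >= need - 1e-12)) return(k)
  }
  n
}

# iid-covariate fixture for model tests
make_sim_data <- function(n, beta_abund, beta_det, offset_area_km2 = pi * 0.1^2,
                          cov_seed = 1L, count_seed = 2L, J = 5L) {
  cov <- grasslandRTR:::with_seed(cov_seed, {
    vars <- setdiff(unique(c(names(beta_abund), names(beta_det))), "intercept")
    df <- as.data.frame(matrix(nrow = n, ncol = 0))
    for (v in vars) df[[v]] <- rnorm(n)
    df
  })
  tp <- true_parameters(beta_abund, beta_det, J = J)
  counts <- simulate_point_counts(data.frame(site_id = seq_len(n)), cov, tp,
                                  offset_area_km2 = offset_area_km2,
                                  seed = count_seed)
  list(counts = counts, covariates = cov, params = tp)
}

# Negative-binomial site abundance with removal detection: overdispersed
# relative to the Poisson N-mixture model.
make_negbin_counts <- function(cov, beta_abund, beta_det, size = 0.5,
                               seed = 1L, J = 5L, offset_area_km2 = 1) {
  n <- nrow(cov)
  Xa <- grasslandRTR:::coef_design(beta_abund, cov, n)
  Xd <- grasslandRTR:::coef_design(beta_det, cov, n)
  grasslandRTR:::with_seed(seed, {
    mu <- exp(drop(Xa %*% beta_abund)) * offset_area_km2
    N <- rnbinom(n, mu = mu, size = size)
    p <- plogis(drop(Xd %*% beta_det))
    y <- matrix(0L, n, J)
    for (i in seq_len(n)) {
      if (N[i] == 0L) next
      pr <- c(p[i] * (1 - p[i])^(0:(J - 1)), (1 - p[i])^J)
      y[i, ] <- rmultinom(1, N[i], pr)[seq_len(J), 1]
    }
    out <- data.frame(site_id = seq_len(n), y)
    names(out) <- c("site_id", paste0("y", seq_len(J)))
    out$total <- rowSums(y)
    out
  })
}

# all-suitable mask on a grid
make_open_mask <- function(grid_dim) {
  structure(list(suitable = matrix(TRUE, grid_dim[1], grid_dim[2]),
                 cell_threshold = 0.5),
            class = "suitability_mask")
}

# compact random blob footprint
make_blob_footprint <- function(grid_dim, n_cells, seed = 1L,
                                name = "blob") {
  grasslandRTR:::with_seed(seed, {
    start <- c(grid_dim[1] %/% 2, grid_dim[2] %/% 2)
    footprint(grasslandRTR:::grow_blob(start, n_cells,
                                       matrix(TRUE, grid_dim[1], grid_dim[2])),
              name = name)
  })
}

# hand-built network for scenario tests: focal landscapes as rectangles
# with small rectangular GBCAs inside
make_rect_network <- function(grid_dim, focal_origins, focal_size = c(12, 12),
                              gbca_size = c(3, 3), gbcas_per_focal = 2L) {
  landscapes <- lapply(seq_along(focal_origins), function(i) {
    o <- focal_origins[[i]]
    rows <- o[1]:(o[1] + focal_size[1] - 1L)
    cols <- o[2]:(o[2] + focal_size[2] - 1L)
    fp <- footprint(as.matrix(expand.grid(rows, cols)),
                    name = sprintf("FL-%d", i))
    gbcas <- lapply(seq_len(gbcas_per_focal), function(g) {
      r0 <- o[1] + 1L + (g - 1L) * (gbca_size[1] + 1L)
      c0 <- o[2] + 1L
      footprint(as.matrix(expand.grid(r0:(r0 + gbca_size[1] - 1L),
                                      c0:(c0 + gbca_size[2] - 1L))),
                name = sprintf("FL-%d/GBCA-%d", i, g))
    })
    list(name = fp$name, footprint = fp, gbcas = gbcas)
  })
  structure(list(landscapes = landscapes, grid_dim = grid_dim),
            class = "conservation_network")
}
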