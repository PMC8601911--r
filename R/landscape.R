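#' Configuration for a synthetic grassland landscape
#'
#' Bundles everything needed to generate a reproducible study landscape: a
#' fine-resolution categorical land-cover mosaic (grassland / agriculture /
#' forest / urban), smooth climate surfaces, and the geometry linking the
#' fine grid to the 1-km2 analysis grid.
#'
#' @param extent integer `c(rows, cols)` of fine-resolution cells.
#' @param fine_cellsize fine cell edge (m); must divide `coarse_cellsize`.
#' @param coarse_cellsize analysis cell edge (m), default 1000 (1-km2 cells).
#' @param class_fractions named numeric: target landscape fractions of
#'   grassland, agriculture, forest and urban cover; must sum to 1.
#' @param autocorrelation_range spatial correlation range of the land-cover
#'   mosaic (m); larger values give larger patches.
#' @param climate_params list with elements `tmax` and `precip`, each a list
#'   `mean` (surface mean; degrees C / mm), `trend` (`c(per-km east, per-km
#'   north)` linear gradient) and `noise_sd` (sd of the smooth noise field).
#' @param seed integer master seed; all generators derive child streams
#'   from it.
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(extent = c(600L, 600L),
                             fine_cellsize = 100,
                             coarse_cellsize = 1000,
                             class_fractions = c(grassland = 0.30,
                                                 agriculture = 0.40,
                                                 forest = 0.22,
                                                 urban = 0.08),
                             autocorrelation_range = 1500,
                             climate_params = list(
                               tmax = list(mean = 27, trend = c(0.03, -0.02),
                                           noise_sd = 0.6),
                               precip = list(mean = 310, trend = c(-0.3, 0.4),
                                             noise_sd = 8)
                             ),
                             seed = 1L) {
  extent <- as.integer(extent)
  if (length(extent) != 2L || any(extent <= 0L))
    stop("invalid configuration: `extent` must be two positive integers")
  if (!all(LANDCOVER_CLASSES %in% names(class_fractions)))
    stop("invalid configuration: class_fractions must name ",
         paste(LANDCOVER_CLASSES, collapse = ", "))
  class_fractions <- class_fractions[LANDCOVER_CLASSES]
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-9)
    stop("invalid configuration: class_fractions must be >= 0 and sum to 1")
  if (coarse_cellsize %% fine_cellsize != 0)
    stop("invalid configuration: fine_cellsize must divide coarse_cellsize")
  if (autocorrelation_range <= 0)
    stop("invalid configuration: autocorrelation_range must be positive")
  structure(
    list(extent = extent, fine_cellsize = fine_cellsize,
         coarse_cellsize = coarse_cellsize,
         class_fractions = class_fractions,
         autocorrelation_range = autocorrelation_range,
         climate_params = climate_params, seed = as.integer(seed)),
    class = "landscape_config"
  )
}

# Circular 1-D convolution down the columns of a matrix; falls back to an
# explicit circulant product when the kernel is as long as the series
# (stats::filter cannot handle that case).
filter_cols_circular <- function(m, k) {
  n <- nrow(m)
  if (length(k) < n) return(stats::filter(m, k, circular = TRUE))
  hw <- (length(k) - 1L) / 2L
  W <- matrix(0, n, n)
  for (o in -hw:hw) {
    idx <- ((seq_len(n) - 1L + o) %% n) + 1L
    W[cbind(seq_len(n), idx)] <- W[cbind(seq_len(n), idx)] + k[o + hw + 1L]
  }
  W %*% m
}

# Separable Gaussian smoothing with circular (torus) boundary; sigma in cells.
smooth_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  hw <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-hw, hw), sd = sigma)
  k <- k / sum(k)
  m <- filter_cols_circular(m, k)           # down columns
  m <- t(filter_cols_circular(t(m), k))     # across rows
  matrix(as.numeric(m), nrow = nrow(m))
}

#' Generate a spatially autocorrelated land-cover mosaic
#'
#' Thresholds a Gaussian-smoothed noise field at the quantiles of the target
#' class fractions, producing a patchy four-class mosaic whose realized
#' proportions match `class_fractions` up to grid discreteness.  Pure
#' function of the configuration (seeded child stream), so identical
#' configurations give bit-identical rasters.
#'
#' @param config a [landscape_config()].
#' @return A categorical `grid_raster` with levels grassland, agriculture,
#'   forest, urban.
#' @export
generate_landcover <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$extent[1]; nc <- config$extent[2]
  sigma <- config$autocorrelation_range / config$fine_cellsize / 2
  with_seed(child_seed(config$seed, "landcover"), {
    field <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
    # rank-based thresholding: realized class counts exact up to rounding
    r <- rank(field, ties.method = "first")
    ncells <- nr * nc
    counts <- diff(c(0L, round(cumsum(config$class_fractions) * ncells)))
    codes <- rep.int(1:4, counts)[r]
    grid_raster(matrix(as.integer(codes), nr, nc),
                origin = c(0, nr * config$fine_cellsize),
                cellsize = config$fine_cellsize,
                levels = LANDCOVER_CLASSES)
  })
}

#' Generate smooth climate surfaces
#'
#' Maximum temperature (degrees C) and total precipitation (mm) as a linear
#' spatial trend plus a Gaussian-smoothed noise field, on the fine grid.
#'
#' @param config a [landscape_config()].
#' @return A list with `grid_raster` elements `tmax` and `precip`.
#' @export
generate_climate <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$extent[1]; nc <- config$extent[2]
  sigma <- config$autocorrelation_range / config$fine_cellsize
  xkm <- (matrix(rep(seq_len(nc), each = nr), nr, nc) - 0.5) *
    config$fine_cellsize / 1000
  ykm <- (nr - matrix(rep(seq_len(nr), times = nc), nr, nc) + 0.5) *
    config$fine_cellsize / 1000
  one <- function(par, stream) {
    with_seed(child_seed(config$seed, stream), {
      noise <- smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
      noise <- noise / max(stats::sd(noise), 1e-12) * par$noise_sd
      par$mean + par$trend[1] * (xkm - mean(xkm)) +
        par$trend[2] * (ykm - mean(ykm)) + noise
    })
  }
  org <- c(0, nr * config$fine_cellsize)
  list(
    tmax = grid_raster(one(config$climate_params$tmax, "climate-tmax"),
                       origin = org, cellsize = config$fine_cellsize),
    precip = grid_raster(one(config$climate_params$precip, "climate-precip"),
                         origin = org, cellsize = config$fine_cellsize)
  )
}

# ---- footprints -----------------------------------------------------------

#' Conservation-area footprint on the 1-km2 analysis grid
#'
#' @param cells two-column integer matrix of (row, col) coarse-grid cells.
#' @param name footprint name.
#' @param cellsize_km coarse cell edge in km (default 1).
#' @return An object of class `footprint` with derived `area_km2`.
#' @export
footprint <- function(cells, name = "area", cellsize_km = 1) {
  cells <- matrix(as.integer(cells), ncol = 2,
                  dimnames = list(NULL, c("row", "col")))
  if (nrow(cells) == 0L) stop("footprint must be nonempty")
  cells <- unique(cells)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  structure(list(cells = cells, name = name, cellsize_km = cellsize_km,
                 area_km2 = nrow(cells) * cellsize_km^2),
            class = "footprint")
}

#' @export
print.footprint <- function(x, ...) {
  cat(sprintf("footprint '%s': %d cells (%.1f km2)\n",
              x$name, nrow(x$cells), x$area_km2))
  invisible(x)
}

# cells as single integer keys for fast set operations
cell_key <- function(cells, nrow_grid) {
  (as.integer(cells[, 2]) - 1L) * as.integer(nrow_grid) +
    as.integer(cells[, 1])
}

# Grow a contiguous blob of n cells from a start cell, preferring compact
# growth; `allowed` is a logical matrix of admissible cells and `weight`
# an optional matrix biasing growth (e.g. towards grass-rich cells).
grow_blob <- function(start, n, allowed, weight = NULL) {
  nr <- nrow(allowed); nc <- ncol(allowed)
  inblob <- matrix(FALSE, nr, nc)
  inblob[start[1], start[2]] <- TRUE
  cells <- matrix(start, ncol = 2)
  nbr_count <- matrix(0L, nr, nc)
  bump <- function(r, c) {
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc)
        nbr_count[rr, cc] <<- nbr_count[rr, cc] + 1L
    }
  }
  bump(start[1], start[2])
  while (nrow(cells) < n) {
    cand <- which(nbr_count > 0L & !inblob & allowed)
    if (length(cand) == 0L) return(NULL)
    w <- as.numeric(nbr_count[cand])^2
    if (!is.null(weight)) w <- w * weight[cand]
    pick <- cand[sample.int(length(cand), 1L, prob = w)]
    r <- ((pick - 1L) %% nr) + 1L; c <- ((pick - 1L) %/% nr) + 1L
    inblob[r, c] <- TRUE
    cells <- rbind(cells, c(r, c))
    bump(r, c)
  }
  cells
}

#' Generate a nested conservation-area network
#'
#' Places `n_focal` Focal Landscape footprints in grass-rich regions of the
#' coarse analysis grid, each containing `gbcas_per_focal` pairwise-disjoint
#' GBCA (Grassland Bird Conservation Area) footprints.  Every footprint is a
#' contiguous blob of 1-km2 cells whose fraction of unsuitable cover (cells
#' with forest + urban proportion >= 0.5) is at most `max_unsuitable`.
#'
#' @param config a [landscape_config()].
#' @param landcover categorical `grid_raster` from [generate_landcover()].
#' @param n_focal number of Focal Landscapes.
#' @param gbcas_per_focal number of GBCAs nested in each Focal Landscape.
#' @param focal_area_km2,gbca_area_km2 requested footprint areas (km2).
#' @param max_unsuitable maximum unsuitable-cover fraction per footprint.
#' @param max_attempts placement attempts before failing.
#' @param n_candidates admissible candidate blobs generated per footprint;
#'   the grass-richest candidate is kept (emulating expert designation of
#'   priority areas in the highest-grassland regions).
#' @return A `conservation_network`: list of Focal Landscapes, each a list
#'   with `name`, `footprint` and `gbcas` (list of `footprint`s).
#' @export
generate_conservation_network <- function(config, landcover,
                                          n_focal = 3L,
                                          gbcas_per_focal = 3L,
                                          focal_area_km2 = 150,
                                          gbca_area_km2 = 12,
                                          max_unsuitable = 0.20,
                                          max_attempts = 2000L,
                                          n_candidates = 25L) {
  gc_cov <- grid_cell_covariates(landcover, climate = NULL,
                                 coarse_cellsize = config$coarse_cellsize)
  nr <- max(gc_cov$row); nc <- max(gc_cov$col)
  grass <- matrix(0, nr, nc); unsuit <- matrix(FALSE, nr, nc)
  grass[cbind(gc_cov$row, gc_cov$col)] <- gc_cov$grassland
  unsuit[cbind(gc_cov$row, gc_cov$col)] <-
    (gc_cov$forest + gc_cov$urban) >= 0.5
  n_focal_cells <- round(focal_area_km2)
  n_gbca_cells <- round(gbca_area_km2)
  if (n_focal * n_focal_cells > nr * nc)
    stop("network generation failed: requested focal areas exceed extent")
  grass_rank <- rank(-grass, ties.method = "first")
  rich <- which(grass_rank <= max(n_focal * n_focal_cells,
                                  0.15 * nr * nc))
  gweight <- (grass + 0.25)^2  # mild bias towards grass-rich cells
  with_seed(child_seed(config$seed, "network"), {
    taken <- matrix(FALSE, nr, nc)
    network <- vector("list", n_focal)
    for (i in seq_len(n_focal)) {
      # emulate expert designation: among admissible candidate blobs seeded
      # in grass-rich cells, keep the one with the highest mean grassland
      fp <- NULL
      best_grass <- -Inf
      found <- 0L
      for (att in seq_len(max_attempts)) {
        start_idx <- rich[sample.int(length(rich), 1L)]
        sr <- ((start_idx - 1L) %% nr) + 1L
        sc <- ((start_idx - 1L) %/% nr) + 1L
        if (taken[sr, sc]) next
        cells <- grow_blob(c(sr, sc), n_focal_cells, !taken, gweight)
        if (is.null(cells)) next
        if (mean(unsuit[cells]) > max_unsuitable) next
        found <- found + 1L
        if (mean(grass[cells]) > best_grass) {
          best_grass <- mean(grass[cells])
          fp <- footprint(cells, name = sprintf("FL-%d", i))
        }
        if (found >= n_candidates) break
      }
      if (is.null(fp))
        stop("network generation failed: could not place Focal Landscape ",
             i, " satisfying the <=", max_unsuitable,
             " unsuitable-fraction constraint in ", max_attempts, " attempts")
      taken[fp$cells] <- TRUE
      infocal <- matrix(FALSE, nr, nc); infocal[fp$cells] <- TRUE
      gbcas <- vector("list", gbcas_per_focal)
      gtaken <- matrix(FALSE, nr, nc)
      for (g in seq_len(gbcas_per_focal)) {
        gfp <- NULL
        best_grass <- -Inf
        found <- 0L
        for (att in seq_len(max_attempts)) {
          free <- which(infocal & !gtaken)
          if (length(free) == 0L) break
          w <- (grass[free] + 0.05)^2
          start_idx <- free[sample.int(length(free), 1L, prob = w)]
          sr <- ((start_idx - 1L) %% nr) + 1L
          sc <- ((start_idx - 1L) %/% nr) + 1L
          cells <- grow_blob(c(sr, sc), n_gbca_cells, infocal & !gtaken,
                             gweight)
          if (is.null(cells)) next
          if (mean(unsuit[cells]) > max_unsuitable) next
          found <- found + 1L
          if (mean(grass[cells]) > best_grass) {
            best_grass <- mean(grass[cells])
            gfp <- footprint(cells, name = sprintf("FL-%d/GBCA-%d", i, g))
          }
          if (found >= n_candidates) break
        }
        if (is.null(gfp))
          stop("network generation failed: could not place GBCA ", g,
               " inside Focal Landscape ", i,
               " (disjointness / unsuitable-fraction constraints)")
        gtaken[gfp$cells] <- TRUE
        gbcas[[g]] <- gfp
      }
      network[[i]] <- list(name = fp$name, footprint = fp, gbcas = gbcas)
    }
    structure(list(landscapes = network, grid_dim = c(nr, nc)),
              class = "conservation_network")
  })
}

#' @export
print.conservation_network <- function(x, ...) {
  cat(sprintf("conservation_network: %d Focal Landscapes on a %d x %d km grid\n",
              length(x$landscapes), x$grid_dim[1], x$grid_dim[2]))
  for (fl in x$landscapes)
    cat(sprintf("  %s: %.0f km2, %d GBCAs (%.0f km2 total)\n", fl$name,
                fl$footprint$area_km2, length(fl$gbcas),
                sum(vapply(fl$gbcas, function(g) g$area_km2, 0))))
  invisible(x)
}

#' Generate point-count survey sites
#'
#' Uniform random site locations with a hard >400-m minimum spacing
#' (rejection sampling) and survey dates uniform over a season window.
#'
#' @param config a [landscape_config()].
#' @param n_sites number of sites.
#' @param min_dist minimum pairwise distance (m), default 400.
#' @param season integer `c(first, last)` day-of-year window for surveys.
#' @param max_attempts rejection-sampling budget.
#' @return data.frame with columns `site_id`, `x`, `y` (m), `jdate`.
#' @export
generate_survey_sites <- function(config, n_sites, min_dist = 400,
                                  season = c(140L, 190L),
                                  max_attempts = 100000L) {
  W <- config$extent[2] * config$fine_cellsize
  H <- config$extent[1] * config$fine_cellsize
  # hexagonal packing upper bound on how many points fit at this spacing
  n_max <- floor((W / min_dist + 1) * (H / (min_dist * sqrt(3) / 2) + 1))
  if (n_sites > n_max)
    stop("site generation infeasible: ", n_sites, " sites cannot satisfy >",
         min_dist, " m spacing in a ", W, " x ", H, " m extent")
  with_seed(child_seed(config$seed, "sites"), {
    xs <- numeric(n_sites); ys <- numeric(n_sites); k <- 0L
    for (att in seq_len(max_attempts)) {
      px <- stats::runif(1, 0, W); py <- stats::runif(1, 0, H)
      if (k > 0L) {
        d2 <- (xs[seq_len(k)] - px)^2 + (ys[seq_len(k)] - py)^2
        if (min(d2) <= min_dist^2) next
      }
      k <- k + 1L
      xs[k] <- px; ys[k] <- py
      if (k == n_sites) break
    }
    if (k < n_sites)
      stop("site generation failed: spacing constraint unmet after ",
           max_attempts, " attempts (placed ", k, " of ", n_sites, ")")
    data.frame(site_id = seq_len(n_sites), x = xs, y = ys,
               jdate = sample(seq(season[1], season[2]), n_sites,
                              replace = TRUE))
  })
}

#' True model parameters for simulation
#'
#' Per-species generating parameters: abundance coefficients on the log
#' link (intercept gives density per km2 at covariate means) and detection
#' coefficients on the logit link (per-interval detection probability).
#'
#' @param beta_abund named numeric; must include `intercept`, other names
#'   are standardized covariates.
#' @param beta_det named numeric; must include `intercept`, typically also
#'   `jdate`.
#' @param J number of removal intervals (2-min bins), default 5.
#' @return An object of class `true_parameters`.
#' @export
true_parameters <- function(beta_abund, beta_det = c(intercept = 0), J = 5L) {
  stopifnot("intercept" %in% names(beta_abund),
            "intercept" %in% names(beta_det),
            all(is.finite(beta_abund)), all(is.finite(beta_det)), J >= 1L)
  structure(list(beta_abund = beta_abund, beta_det = beta_det,
                 J = as.integer(J)),
            class = "true_parameters")
}

# design matrix for named coefficients from a covariate data.frame
coef_design <- function(beta, covariates, n) {
  vars <- setdiff(names(beta), "intercept")
  missing <- setdiff(vars, names(covariates))
  if (length(missing) > 0L)
    stop("missing covariates: ", paste(missing, collapse = ", "))
  X <- cbind(intercept = rep(1, n))
  for (v in vars) X <- cbind(X, covariates[[v]])
  colnames(X) <- c("intercept", vars)
  X
}

#' Simulate removal point counts
#'
#' Site abundance is Poisson with mean `lambda_i * A` where
#' `log lambda_i = x_i' beta_abund` (density per km2) and `A` is the
#' effective sampled area; each individual is first detected in interval
#' `j` with probability `p_i (1-p_i)^(j-1)` or never detected with
#' probability `(1-p_i)^J`, where `logit p_i = w_i' beta_det`.
#'
#' @param sites data.frame from [generate_survey_sites()].
#' @param site_covariates data.frame of standardized covariates (one row per
#'   site), covering all names in the parameters.
#' @param params a [true_parameters()] object.
#' @param offset_area_km2 effective sampled area A (km2); default the area
#'   of a 100-m-radius circle.
#' @param seed integer seed (default derived from nothing: supply one for
#'   reproducibility).
#' @return data.frame of class `removal_counts`: `site_id`, `y1..yJ`,
#'   `total`, plus attributes `J` and `offset_area_km2`.
#' @export
simulate_point_counts <- function(sites, site_covariates, params,
                                  offset_area_km2 = pi * 0.1^2,
                                  seed = 1L) {
  stopifnot(inherits(params, "true_parameters"), offset_area_km2 > 0)
  n <- nrow(sites)
  Xa <- coef_design(params$beta_abund, site_covariates, n)
  Xd <- coef_design(params$beta_det, site_covariates, n)
  eta <- drop(Xa %*% params$beta_abund)
  zeta <- drop(Xd %*% params$beta_det)
  if (any(!is.finite(eta)) || any(!is.finite(zeta)))
    stop("simulation error: non-finite linear predictor")
  J <- params$J
  with_seed(seed, {
    lambda <- exp(eta)
    N <- stats::rpois(n, lambda * offset_area_km2)
    p <- stats::plogis(zeta)
    y <- matrix(0L, n, J)
    for (i in seq_len(n)) {
      if (N[i] == 0L) next
      probs <- c(p[i] * (1 - p[i])^(seq_len(J) - 1), (1 - p[i])^J)
      draw <- stats::rmultinom(1, N[i], probs)
      y[i, ] <- draw[seq_len(J), 1]
    }
    out <- data.frame(site_id = sites$site_id, y)
    names(out) <- c("site_id", paste0("y", seq_len(J)))
    out$total <- rowSums(y)
    attr(out, "J") <- J
    attr(out, "offset_area_km2") <- offset_area_km2
    class(out) <- c("removal_counts", "data.frame")
    out
  })
}
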