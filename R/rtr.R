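# Constrained random translation-rotation (RTR) null model: replicate
# conservation areas with the same size and shape as the originals are
# placed at uniform random rotations and translations within a sampling
# region, constrained to suitable grassland, to build spatial null
# distributions of mean density.

#' Suitability mask for grassland bird conservation
#'
#' A 1-km2 cell is unsuitable when its total unsuitable land cover
#' (forest + urban proportions) is at least `cell_threshold` (default
#' 50%); all other cells are suitable.
#'
#' @param grid data.frame from [grid_cell_covariates()] (raw, not
#'   standardized: needs `forest` and `urban` proportions per cell).
#' @param cell_threshold unsuitable-cover threshold, default 0.50.
#' @return An object of class `suitability_mask`: logical matrix
#'   `suitable` plus the threshold.
#' @export
build_suitability_mask <- function(grid, cell_threshold = 0.50) {
  if (!all(c("row", "col", "forest", "urban") %in% names(grid)))
    stop("grid covariates must include forest and urban proportions")
  nr <- max(grid$row); nc <- max(grid$col)
  m <- matrix(NA, nr, nc)
  m[cbind(grid$row, grid$col)] <-
    (grid$forest + grid$urban) < cell_threshold
  structure(list(suitable = m, cell_threshold = cell_threshold),
            class = "suitability_mask")
}

#' @export
print.suitability_mask <- function(x, ...) {
  cat(sprintf("suitability_mask: %d x %d cells, %.1f%% suitable (forest+urban < %.0f%% rule)\n",
              nrow(x$suitable), ncol(x$suitable),
              100 * mean(x$suitable, na.rm = TRUE),
              100 * x$cell_threshold))
  invisible(x)
}

#' Footprint covering a whole analysis grid
#'
#' Convenience region for statewide-scale randomizations.
#'
#' @param grid_dim integer `c(rows, cols)` of the coarse grid.
#' @return A `footprint` containing every cell.
#' @export
full_grid_footprint <- function(grid_dim) {
  footprint(cbind(rep(seq_len(grid_dim[1]), times = grid_dim[2]),
                  rep(seq_len(grid_dim[2]), each = grid_dim[1])),
            name = "statewide")
}

# Precomputed geometry for repeated placements of one footprint.
rtr_source <- function(fp, grid_dim) {
  ctr <- cbind(fp$cells[, 2] - 0.5, fp$cells[, 1] - 0.5)  # (x, y) cell units
  lookup <- matrix(FALSE, grid_dim[1], grid_dim[2])
  lookup[fp$cells] <- TRUE
  list(centers = ctr, centroid = colMeans(ctr), n = nrow(ctr),
       lookup = lookup, name = fp$name)
}

rtr_region <- function(region, grid_dim) {
  lookup <- matrix(FALSE, grid_dim[1], grid_dim[2])
  lookup[region$cells] <- TRUE
  list(lookup = lookup,
       xr = range(region$cells[, 2]) + c(-1, 0),
       yr = range(region$cells[, 1]) + c(-1, 0),
       n = nrow(region$cells))
}

# One pose attempt: returns placed cell matrix or NULL.  Rotation angle
# uniform on (0, 2pi) about the source centroid; translation uniform over
# the region bounding box; the placed footprint is rasterized by
# cell-centre containment (a grid cell belongs to the replicate when its
# centre, mapped back through the inverse pose, lands inside a source
# cell).  Poses whose replicate leaves the region or whose rasterized
# cell count drifts more than `tol` from the source are rejected.
rtr_try_pose <- function(src, reg, grid_dim, tol = 0.05, pose = NULL) {
  if (is.null(pose)) {
    theta <- stats::runif(1, 0, 2 * pi)
    tx <- stats::runif(1, reg$xr[1], reg$xr[2])
    ty <- stats::runif(1, reg$yr[1], reg$yr[2])
  } else {
    theta <- pose$theta; tx <- pose$tx; ty <- pose$ty
  }
  co <- cos(theta); si <- sin(theta)
  rel <- sweep(src$centers, 2, src$centroid)
  px <- rel[, 1] * co - rel[, 2] * si + tx
  py <- rel[, 1] * si + rel[, 2] * co + ty
  rows <- max(1L, floor(min(py) - 0.5) + 1L):min(grid_dim[1], floor(max(py) + 0.5) + 1L)
  cols <- max(1L, floor(min(px) - 0.5) + 1L):min(grid_dim[2], floor(max(px) + 0.5) + 1L)
  if (length(rows) == 0L || length(cols) == 0L) return(NULL)
  cc <- rep(cols, each = length(rows))
  rr <- rep(rows, times = length(cols))
  # inverse pose of candidate cell centres
  dx <- (cc - 0.5) - tx
  dy <- (rr - 0.5) - ty
  qx <- dx * co + dy * si + src$centroid[1]
  qy <- -dx * si + dy * co + src$centroid[2]
  sc <- floor(qx) + 1L
  sr <- floor(qy) + 1L
  ok <- sr >= 1L & sr <= grid_dim[1] & sc >= 1L & sc <= grid_dim[2]
  ok[ok] <- src$lookup[cbind(sr[ok], sc[ok])]
  if (!any(ok)) return(NULL)
  placed <- cbind(rr[ok], cc[ok])
  if (abs(nrow(placed) - src$n) > tol * src$n) return(NULL)
  # no clipping: every transformed source centre must stay inside the grid,
  # and every rasterized replicate cell inside the region
  if (any(px < 0 | px > grid_dim[2] | py < 0 | py > grid_dim[1]))
    return(NULL)
  if (!all(reg$lookup[placed])) return(NULL)
  attr(placed, "theta") <- theta
  attr(placed, "translation") <- c(tx, ty)
  placed
}

#' Place one shape-preserving replicate footprint
#'
#' Draws random translation-rotation poses until the replicate lies
#' entirely within the region with a rasterized cell count within 5% of
#' the source footprint.
#'
#' @param fp source `footprint`.
#' @param region sampling-region `footprint` (e.g.
#'   [full_grid_footprint()] or a Focal Landscape).
#' @param grid_dim integer `c(rows, cols)` of the coarse grid.
#' @param max_attempts pose attempts before failing.
#' @param tol rasterization cell-count tolerance (fraction).
#' @return A `footprint` with attributes `theta` (radians) and
#'   `translation` (cell units).
#' @export
rtr_place_footprint <- function(fp, region, grid_dim,
                                max_attempts = 1000L, tol = 0.05) {
  src <- rtr_source(fp, grid_dim)
  reg <- rtr_region(region, grid_dim)
  if (src$n > reg$n)
    stop("placement error: footprint '", fp$name,
         "' cannot fit inside the region")
  for (att in seq_len(max_attempts)) {
    placed <- rtr_try_pose(src, reg, grid_dim, tol)
    if (!is.null(placed)) {
      out <- footprint(placed, name = paste0(fp$name, ".replicate"))
      attr(out, "theta") <- attr(placed, "theta")
      attr(out, "translation") <- attr(placed, "translation")
      return(out)
    }
  }
  stop("placement error: no valid pose for footprint '", fp$name,
       "' within the region after ", max_attempts, " attempts")
}

#' Place an ensemble of disjoint replicate footprints
#'
#' Members are placed sequentially; a member overlapping an already-placed
#' member is redrawn, so accepted ensembles have pairwise-disjoint cell
#' sets (GBCA replicates within an ensemble are not allowed to overlap).
#'
#' @param footprints list of source `footprint`s.
#' @param region sampling-region `footprint`.
#' @param grid_dim coarse grid dimensions.
#' @param max_attempts per-member pose attempts.
#' @param tol rasterization tolerance.
#' @return list of placed `footprint`s.
#' @export
place_ensemble <- function(footprints, region, grid_dim,
                           max_attempts = 1000L, tol = 0.05) {
  reg <- rtr_region(region, grid_dim)
  if (sum(vapply(footprints, function(f) nrow(f$cells), 0L)) > reg$n)
    stop("placement error: combined ensemble area exceeds the region")
  occupied <- matrix(FALSE, grid_dim[1], grid_dim[2])
  out <- vector("list", length(footprints))
  for (k in seq_along(footprints)) {
    src <- rtr_source(footprints[[k]], grid_dim)
    done <- FALSE
    for (att in seq_len(max_attempts)) {
      placed <- rtr_try_pose(src, reg, grid_dim, tol)
      if (is.null(placed)) next
      if (any(occupied[placed])) next
      occupied[placed] <- TRUE
      fpk <- footprint(placed, name = paste0(src$name, ".replicate"))
      attr(fpk, "theta") <- attr(placed, "theta")
      out[[k]] <- fpk
      done <- TRUE
      break
    }
    if (!done)
      stop("placement error: could not place ensemble member '",
           src$name, "' disjointly after ", max_attempts, " attempts")
  }
  out
}

# Shared placement engine: n accepted replicate cell sets of a target
# (single footprint or ensemble), subject to the unsuitable-fraction rule.
# Returns cell sets so several species' surfaces can reuse one set of
# placements.
generate_null_placements <- function(target, region, mask, n = 1000L,
                                     unsuit_frac = 0.20, seed = 1L,
                                     max_attempts = 1000L,
                                     global_cap = 1e6, tol = 0.05) {
  grid_dim <- dim(mask$suitable)
  single <- inherits(target, "footprint")
  members <- if (single) list(target) else target
  srcs <- lapply(members, rtr_source, grid_dim = grid_dim)
  reg <- rtr_region(region, grid_dim)
  unsuitable <- !mask$suitable
  placements <- vector("list", n)
  accepted <- 0L
  rejected_unsuitable <- 0L
  attempts <- 0L
  with_seed(seed, {
    while (accepted < n) {
      attempts <- attempts + 1L
      if (attempts > global_cap)
        stop("randomization failed: global attempt cap (", global_cap,
             ") reached with ", accepted, " of ", n,
             " replicates accepted; the unsuitable-fraction or region ",
             "constraint admits too few placements")
      occupied <- NULL
      cells <- NULL
      ok <- TRUE
      for (src in srcs) {
        placed <- NULL
        for (att in seq_len(max_attempts)) {
          cand <- rtr_try_pose(src, reg, grid_dim, tol)
          if (is.null(cand)) next
          if (!is.null(occupied) && any(occupied[cand])) next
          placed <- cand
          break
        }
        if (is.null(placed)) { ok <- FALSE; break }
        if (length(srcs) > 1L) {
          if (is.null(occupied))
            occupied <- matrix(FALSE, grid_dim[1], grid_dim[2])
          occupied[placed] <- TRUE
        }
        cells <- rbind(cells, placed)
      }
      if (!ok)
        stop("randomization failed: could not place a replicate of '",
             srcs[[1]]$name, "' after ", max_attempts, " pose attempts")
      if (mean(unsuitable[cells], na.rm = TRUE) > unsuit_frac) {
        rejected_unsuitable <- rejected_unsuitable + 1L
        next
      }
      accepted <- accepted + 1L
      placements[[accepted]] <- cells
    }
  })
  list(placements = placements, n = n,
       rejected_unsuitable = rejected_unsuitable,
       attempts = attempts, seed = seed)
}

#' Null distribution of replicate-area mean densities
#'
#' Repeatedly places a shape-preserving replicate of the target (a single
#' footprint, or an ensemble placed disjointly), discards replicates with
#' more than `unsuit_frac` unsuitable habitat, and records the mean
#' surface density over the accepted replicate's cells (no boundary
#' buffer) until `n` replicates are accepted.
#'
#' @param target a `footprint` or list of `footprint`s (ensemble).
#' @param region sampling-region `footprint`.
#' @param surface a `density_surface`.
#' @param mask a `suitability_mask` on the same grid.
#' @param n number of accepted replicates, default 1000.
#' @param unsuit_frac maximum unsuitable fraction per replicate, default
#'   0.20.
#' @param seed integer seed; identical inputs and seed give identical
#'   distributions.
#' @param layer surface layer.
#' @param max_attempts per-member pose attempts; a global cap of 1e6
#'   placement attempts guards against infeasible constraints.
#' @return list of class `null_distribution`: `values` (length `n`),
#'   `rejected_unsuitable`, `attempts`, `seed`, `layer`.
#' @export
generate_null_distribution <- function(target, region, surface, mask,
                                       n = 1000L, unsuit_frac = 0.20,
                                       seed = 1L, layer = "point",
                                       max_attempts = 1000L) {
  pl <- generate_null_placements(target, region, mask, n = n,
                                 unsuit_frac = unsuit_frac, seed = seed,
                                 max_attempts = max_attempts)
  m <- surface_layer(surface, layer)
  vals <- vapply(pl$placements, function(cells)
    mean(m[cells], na.rm = TRUE), 0)
  structure(list(values = vals, n = n,
                 rejected_unsuitable = pl$rejected_unsuitable,
                 attempts = pl$attempts, seed = seed, layer = layer),
            class = "null_distribution")
}

#' One-sided representation test against an RTR null distribution
#'
#' A conservation area represents a species when its baseline density is
#' strictly greater than the empirical 90th percentile of the replicate
#' null distribution (the baseline falls within the top 10% of the null).
#'
#' @param baseline baseline mean density of the real conservation area.
#' @param null a `null_distribution` or numeric vector of replicate
#'   means.
#' @param quantile one-sided percentile rule, default 0.90.
#' @return list of class `representation_result`: `baseline`,
#'   `null_quantile` (the 90th-percentile value), `flagged`,
#'   `baseline_quantile` (empirical quantile of the baseline within the
#'   null).
#' @export
representation_test <- function(baseline, null, quantile = 0.90) {
  vals <- if (inherits(null, "null_distribution")) null$values else null
  if (length(vals) == 0L) stop("empty null distribution")
  q <- stats::quantile(vals, probs = quantile, names = FALSE)
  structure(list(baseline = baseline, null_quantile = q,
                 flagged = baseline > q,
                 baseline_quantile = mean(vals < baseline)),
            class = "representation_result")
}

#' @export
print.representation_result <- function(x, ...) {
  cat(sprintf("representation test: baseline %.4f vs null 90th pct %.4f -> %s (baseline at null quantile %.3f)\n",
              x$baseline, x$null_quantile,
              if (x$flagged) "REPRESENTED" else "not represented",
              x$baseline_quantile))
  invisible(x)
}
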