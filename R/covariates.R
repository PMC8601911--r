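#' Land-cover proportions and climate in site buffers
#'
#' For each survey site, computes the proportion of the four land-cover
#' classes and the mean of each climate surface over the fine cells whose
#' centres lie within `radius_m` of the site (buffers are clipped at the
#' raster edge).  Because the fine grid is fully labelled, the four
#' proportions sum to 1 at every site.
#'
#' @param sites data.frame with `site_id`, `x`, `y` (m), and optionally
#'   `jdate` (carried through).
#' @param landcover categorical `grid_raster`.
#' @param climate list with `grid_raster` elements `tmax` and `precip` on
#'   the same grid, or NULL to skip climate.
#' @param radius_m buffer radius (m), default 100 (the territory-scale
#'   buffer used for survey covariates).
#' @return data.frame: `site_id`, class proportions, `tmax`, `precip`, and
#'   `jdate` if present in `sites`.
#' @export
site_buffer_covariates <- function(sites, landcover, climate = NULL,
                                   radius_m = 100) {
  nr <- nrow(landcover$values); nc <- ncol(landcover$values)
  s <- landcover$cellsize
  out <- matrix(0, nrow(sites), 4,
                dimnames = list(NULL, LANDCOVER_CLASSES))
  tmax <- precip <- rep(NA_real_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    px <- sites$x[i]; py <- sites$y[i]
    cc <- coord_to_cell(landcover, px, py)
    if (is.na(cc$row[1]))
      stop("covariate extraction error: site ", sites$site_id[i],
           " lies outside the raster extent")
    halo <- ceiling(radius_m / s) + 1L
    rows <- max(1L, cc$row - halo):min(nr, cc$row + halo)
    cols <- max(1L, cc$col - halo):min(nc, cc$col + halo)
    ctr <- expand.grid(row = rows, col = cols)
    xy <- cell_centers(landcover, ctr$row, ctr$col)
    inside <- (xy$x - px)^2 + (xy$y - py)^2 <= radius_m^2
    sel <- cbind(ctr$row[inside], ctr$col[inside])
    if (nrow(sel) == 0L)
      stop("covariate extraction error: empty buffer for site ",
           sites$site_id[i])
    tab <- tabulate(landcover$values[sel], nbins = 4L)
    out[i, ] <- tab / sum(tab)
    if (!is.null(climate)) {
      tmax[i] <- mean(climate$tmax$values[sel])
      precip[i] <- mean(climate$precip$values[sel])
    }
  }
  res <- data.frame(site_id = sites$site_id, out)
  if (!is.null(climate)) {
    res$tmax <- tmax
    res$precip <- precip
  }
  if ("jdate" %in% names(sites)) res$jdate <- sites$jdate
  res
}

#' Covariates on the 1-km2 analysis grid
#'
#' Aggregates the fine-resolution land cover (exact cell tallies) and
#' climate (means) to the coarse analysis grid.  The coarse grid must align
#' with the fine grid (cell-size ratio integer, extent an exact multiple).
#'
#' @param landcover categorical `grid_raster`.
#' @param climate list with `grid_raster` elements `tmax`, `precip` on the
#'   same grid as `landcover`, or NULL.
#' @param coarse_cellsize analysis cell edge (m), default 1000.
#' @return data.frame keyed by (`row`, `col`) with centroid coordinates
#'   `x`, `y` (m), the four class proportions, and `tmax`, `precip` when
#'   climate is supplied.
#' @export
grid_cell_covariates <- function(landcover, climate = NULL,
                                 coarse_cellsize = 1000) {
  s <- landcover$cellsize
  ratio <- coarse_cellsize / s
  nr <- nrow(landcover$values); nc <- ncol(landcover$values)
  if (ratio != round(ratio) || nr %% ratio != 0 || nc %% ratio != 0)
    stop("alignment error: coarse grid of ", coarse_cellsize,
         " m does not align with a ", nr, " x ", nc, " fine grid at ",
         s, " m resolution")
  ratio <- as.integer(ratio)
  nR <- nr %/% ratio; nC <- nc %/% ratio
  fr <- rep(seq_len(nr), times = nc)
  fc <- rep(seq_len(nc), each = nr)
  idx <- ((fc - 1L) %/% ratio) * nR + ((fr - 1L) %/% ratio) + 1L
  ncell <- ratio^2
  vals <- as.integer(landcover$values)
  props <- matrix(vapply(1:4, function(k)
    tabulate(idx[vals == k], nbins = nR * nC) / ncell, numeric(nR * nC)),
    ncol = 4, dimnames = list(NULL, LANDCOVER_CLASSES))
  res <- data.frame(
    row = rep(seq_len(nR), times = nC),
    col = rep(seq_len(nC), each = nR)
  )
  res$x <- landcover$origin[1] + (res$col - 0.5) * coarse_cellsize
  res$y <- landcover$origin[2] - (res$row - 0.5) * coarse_cellsize
  res <- cbind(res, props)
  if (!is.null(climate)) {
    res$tmax <- as.numeric(rowsum(as.vector(climate$tmax$values), idx)) / ncell
    res$precip <- as.numeric(rowsum(as.vector(climate$precip$values), idx)) / ncell
  }
  res
}

#' Standardize covariates, storing or reusing scaling parameters
#'
#' Fitting mode (`params = NULL`): centres and scales each column by its
#' mean and sample (n-1) standard deviation, returning the scaling so that
#' prediction-time covariates can be standardized identically.  Reuse mode:
#' applies the stored scaling.
#'
#' @param values data.frame of numeric covariates.
#' @param params a `scaling_params` object to reuse, or NULL to fit.
#' @param cols columns to standardize; default all numeric columns except
#'   `site_id`, `row`, `col`, `x`, `y`.
#' @return list with `values` (standardized data.frame) and `params`
#'   (`scaling_params`: per-covariate `mean`, `sd`, and the sd convention).
#' @export
standardize <- function(values, params = NULL, cols = NULL) {
  if (is.null(cols)) {
    cols <- setdiff(names(values)[vapply(values, is.numeric, TRUE)],
                    c("site_id", "row", "col", "x", "y"))
  }
  if (is.null(params)) {
    mu <- vapply(values[cols], mean, 0)
    sigma <- vapply(values[cols], stats::sd, 0)  # sample (n-1) convention
    zero <- cols[sigma == 0 | !is.finite(sigma)]
    if (length(zero) > 0L)
      stop("zero-variance covariate(s): ", paste(zero, collapse = ", "))
    params <- structure(list(mean = mu, sd = sigma, sd_type = "sample (n-1)"),
                        class = "scaling_params")
  } else {
    stopifnot(inherits(params, "scaling_params"))
    missing <- setdiff(cols, names(params$mean))
    if (length(missing) > 0L)
      stop("no stored scaling for covariate(s): ",
           paste(missing, collapse = ", "))
  }
  out <- values
  for (v in cols) out[[v]] <- (values[[v]] - params$mean[[v]]) / params$sd[[v]]
  list(values = out, params = params)
}

#' Pairwise collinearity report
#'
#' Pearson correlations between all covariate pairs, flagging any pair with
#' `|r|` at or above the threshold (0.7 by convention for these models).
#'
#' @param covariates data.frame of numeric covariates (>= 3 rows).
#' @param threshold absolute-correlation flag threshold.
#' @return data.frame with columns `var1`, `var2`, `r`, `flagged`.
#' @export
collinearity_check <- function(covariates, threshold = 0.7) {
  num <- covariates[vapply(covariates, is.numeric, TRUE)]
  num <- num[setdiff(names(num), c("site_id", "row", "col", "x", "y"))]
  if (nrow(num) < 3L) stop("collinearity check needs >= 3 records")
  sds <- vapply(num, stats::sd, 0)
  if (any(sds == 0))
    stop("zero-variance covariate(s): ",
         paste(names(num)[sds == 0], collapse = ", "))
  r <- stats::cor(num)
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  data.frame(
    var1 = colnames(r)[pairs[, 1]],
    var2 = colnames(r)[pairs[, 2]],
    r = r[pairs],
    flagged = abs(r[pairs]) >= threshold
  )
}
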