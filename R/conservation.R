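# Conservation-area evaluation: baseline densities, percent-of-statewide-
# population coverage, and minimum-set optimal planning on the 1-km2 grid.

# Cells whose centre lies within `buffer_m` of a footprint (distance to the
# nearest footprint cell square, so buffer 0 returns the footprint itself).
dilate_footprint_cells <- function(fp, grid_dim, buffer_m = 0,
                                   cellsize_m = 1000) {
  if (buffer_m <= 0) return(fp$cells)
  nr <- grid_dim[1]; nc <- grid_dim[2]
  halo <- ceiling(buffer_m / cellsize_m + 0.5)
  half <- cellsize_m / 2
  inc <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(fp$cells))) {
    fr <- fp$cells[k, 1]; fc <- fp$cells[k, 2]
    rows <- max(1L, fr - halo):min(nr, fr + halo)
    cols <- max(1L, fc - halo):min(nc, fc + halo)
    dr <- pmax(0, (abs(rows - fr)) * cellsize_m - half)
    dc <- pmax(0, (abs(cols - fc)) * cellsize_m - half)
    hit <- outer(dr^2, dc^2, "+") <= buffer_m^2
    inc[rows, cols] <- inc[rows, cols] | hit
  }
  which(inc, arr.ind = TRUE)
}

#' Mean density inside a (buffered) conservation-area footprint
#'
#' The population baseline of a conservation area: the mean predicted
#' density over the 1-km2 cells whose centres fall within the footprint
#' dilated by `buffer_m` (default 500 m, so cells intersecting the
#' boundary are included).
#'
#' @param surface a `density_surface`.
#' @param fp a `footprint` on the same grid.
#' @param buffer_m boundary buffer in metres (0 disables dilation).
#' @param layer surface layer: `"point"`, `"minus"` or `"plus"`.
#' @return list: `mean_density` (per km2), `n_cells`, `cells`.
#' @export
baseline_density <- function(surface, fp, buffer_m = 500, layer = "point") {
  stopifnot(inherits(surface, "density_surface"), inherits(fp, "footprint"))
  m <- surface_layer(surface, layer)
  if (any(fp$cells[, 1] > nrow(m)) || any(fp$cells[, 2] > ncol(m)))
    stop("footprint extends outside the surface grid")
  cells <- dilate_footprint_cells(fp, dim(m), buffer_m,
                                  surface$cellsize_km * 1000)
  vals <- m[cells]
  if (all(is.na(vals))) stop("no surface cells under the buffered footprint")
  list(mean_density = mean(vals, na.rm = TRUE),
       n_cells = sum(!is.na(vals)), cells = cells)
}

#' Percent of the statewide population inside a set of footprints
#'
#' Population in a cell is density times cell area; the statewide
#' population is the sum over all cells.  Footprint overlap is counted
#' once (union semantics).  Reported for each surface layer and compared
#' against the 20% conservation target and the 10% IUCN
#' critically-endangered threshold.
#'
#' @param surface a `density_surface`.
#' @param footprints a `footprint` or list of `footprint`s.
#' @param targets thresholds (fractions) to compare against.
#' @return data.frame: `layer`, `percent`, plus logical columns
#'   `meets_<target>` per threshold.
#' @export
percent_statewide <- function(surface, footprints,
                              targets = c(0.20, 0.10)) {
  if (inherits(footprints, "footprint")) footprints <- list(footprints)
  nr <- nrow(surface$point)
  keys <- unique(unlist(lapply(footprints, function(f)
    cell_key(f$cells, nr))))
  cells <- cbind(((keys - 1L) %% nr) + 1L, ((keys - 1L) %/% nr) + 1L)
  out <- lapply(c("point", "minus", "plus"), function(ly) {
    m <- surface_layer(surface, ly)
    tot <- sum(m, na.rm = TRUE)
    if (tot == 0)
      return(data.frame(layer = ly, percent = NA_real_))
    data.frame(layer = ly,
               percent = 100 * sum(m[cells], na.rm = TRUE) / tot)
  })
  res <- do.call(rbind, out)
  for (tg in targets)
    res[[sprintf("meets_%g", 100 * tg)]] <- !is.na(res$percent) &
      res$percent >= 100 * tg
  res
}

#' Minimum set of grid cells reaching a population target
#'
#' The smallest set of 1-km2 cells whose summed predicted population
#' reaches `target_frac` of the statewide total: cells are sorted by
#' density descending (ties broken by row, then column) and accumulated
#' until the target is met.  For this objective greedy selection is
#' provably minimal.
#'
#' @param surface a `density_surface`.
#' @param target_frac population fraction in (0, 1], default 0.20.
#' @param layer surface layer.
#' @return list of class `minimum_set_result`: `cells` (row/col matrix in
#'   selection order), `n_cells`, `achieved_frac`, `target_frac`.
#' @export
minimum_set <- function(surface, target_frac = 0.20, layer = "point") {
  if (target_frac <= 0 || target_frac > 1)
    stop("target_frac must be in (0, 1]")
  m <- surface_layer(surface, layer)
  nr <- nrow(m)
  v <- as.vector(m)
  keep <- which(!is.na(v))
  v <- v[keep]
  tot <- sum(v)
  if (tot <= 0) stop("all-zero density surface: minimum set undefined")
  rows <- ((keep - 1L) %% nr) + 1L
  cols <- ((keep - 1L) %/% nr) + 1L
  ord <- order(-v, rows, cols)
  cs <- cumsum(v[ord])
  # relative epsilon absorbs cumsum round-off on near-tied surfaces
  k <- which(cs >= target_frac * tot * (1 - 1e-12))[1]
  sel <- ord[seq_len(k)]
  structure(list(
    cells = cbind(row = rows[sel], col = cols[sel]),
    n_cells = k,
    achieved_frac = cs[k] / tot,
    target_frac = target_frac
  ), class = "minimum_set_result")
}

#' @export
print.minimum_set_result <- function(x, ...) {
  cat(sprintf("minimum set: %d cells reach %.1f%% of the statewide population (target %.0f%%)\n",
              x$n_cells, 100 * x$achieved_frac, 100 * x$target_frac))
  invisible(x)
}

#' Write footprint cells to CSV
#'
#' @param fp a `footprint` or `conservation_network`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_footprint_csv <- function(fp, path) {
  if (inherits(fp, "conservation_network")) {
    rows <- list()
    for (fl in fp$landscapes) {
      rows[[length(rows) + 1L]] <-
        data.frame(name = fl$name, kind = "focal", fl$footprint$cells)
      for (g in fl$gbcas)
        rows[[length(rows) + 1L]] <-
          data.frame(name = g$name, kind = "gbca", g$cells)
    }
    df <- do.call(rbind, rows)
  } else {
    df <- data.frame(name = fp$name, kind = "footprint", fp$cells)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
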