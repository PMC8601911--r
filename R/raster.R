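#' Matrix-backed planar raster
#'
#' A minimal raster container: a numeric or integer matrix plus an origin and
#' a cell size in metres.  Coordinates are projected planar metres; the grid
#' is row-major with the origin at the upper-left corner, x increasing east
#' (with column index) and y increasing north (so y decreases with row
#' index).  Cell intervals are half-open: cell (r, c) covers
#' `[x0 + (c-1)s, x0 + c s) x (y0 - r s, y0 - (r-1) s]`.
#'
#' @param values matrix of cell values (integer class codes or numeric).
#' @param origin length-2 numeric `c(x0, y0)`: coordinates of the upper-left
#'   corner of cell (1, 1), metres.
#' @param cellsize cell edge length in metres.
#' @param levels optional character vector of class labels for categorical
#'   rasters; `values` then holds integer codes indexing `levels`.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, origin = c(0, 0), cellsize, levels = NULL) {
  stopifnot(is.matrix(values), length(origin) == 2L, is.finite(cellsize),
            cellsize > 0)
  structure(
    list(values = values, origin = as.numeric(origin),
         cellsize = as.numeric(cellsize), levels = levels),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("grid_raster: %d x %d cells, %g m resolution, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize,
              x$origin[1], x$origin[2]))
  if (!is.null(x$levels)) {
    tab <- table(factor(x$levels[x$values], levels = x$levels))
    cat("classes:", paste(sprintf("%s=%.3f", names(tab),
                                  as.numeric(tab) / length(x$values)),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Cell-centre coordinates of a raster
#'
#' @param x a `grid_raster`.
#' @param rows,cols integer vectors of equal length (recycled).
#' @return data.frame with columns `x`, `y` (metres).
#' @export
cell_centers <- function(x, rows, cols) {
  data.frame(
    x = x$origin[1] + (cols - 0.5) * x$cellsize,
    y = x$origin[2] - (rows - 0.5) * x$cellsize
  )
}

#' Map planar coordinates to raster cell indices
#'
#' Half-open cell convention; points on the right/bottom outer edge fall
#' outside.
#'
#' @param x a `grid_raster`.
#' @param px,py coordinate vectors (metres).
#' @return data.frame with integer columns `row`, `col`; NA outside extent.
#' @export
coord_to_cell <- function(x, px, py) {
  col <- floor((px - x$origin[1]) / x$cellsize) + 1L
  row <- floor((x$origin[2] - py) / x$cellsize) + 1L
  bad <- row < 1L | row > nrow(x$values) | col < 1L | col > ncol(x$values)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Write / read a raster as long-format CSV
#'
#' Plain-text storage: one row per cell (`row`, `col`, `value`), with grid
#' geometry in `#`-prefixed header comments.  Values round-trip exactly at
#' the printed precision of [base::format()] with 15 significant digits.
#'
#' @param x a `grid_raster`.
#' @param path file path.
#' @return `read_raster_csv` returns a `grid_raster`.
#' @export
write_raster_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nrow=%d ncol=%d cellsize=%.10g x0=%.10g y0=%.10g",
                     nrow(x$values), ncol(x$values), x$cellsize,
                     x$origin[1], x$origin[2]), con)
  if (!is.null(x$levels))
    writeLines(paste0("# levels=", paste(x$levels, collapse = ",")), con)
  df <- data.frame(
    row = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
    col = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
    value = format(as.vector(x$values), digits = 15, trim = TRUE,
                   scientific = FALSE)
  )
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  hdr <- readLines(path, n = 2L)
  hdr <- hdr[startsWith(hdr, "#")]
  m <- regmatches(hdr[1], gregexpr("[a-z0-9]+=[^ ]+", hdr[1]))[[1]]
  kv <- strsplit(m, "=", fixed = TRUE)
  geo <- stats::setNames(vapply(kv, function(p) p[2], ""),
                         vapply(kv, function(p) p[1], ""))
  levels <- NULL
  if (length(hdr) > 1L && grepl("levels=", hdr[2]))
    levels <- strsplit(sub("^# levels=", "", hdr[2]), ",")[[1]]
  df <- utils::read.csv(path, comment.char = "#")
  nr <- as.integer(geo[["nrow"]]); nc <- as.integer(geo[["ncol"]])
  vals <- matrix(NA_real_, nr, nc)
  vals[cbind(df$row, df$col)] <- df$value
  if (!is.null(levels)) storage.mode(vals) <- "integer"
  grid_raster(vals, origin = c(as.numeric(geo[["x0"]]), as.numeric(geo[["y0"]])),
              cellsize = as.numeric(geo[["cellsize"]]), levels = levels)
}

# Land-cover class labels used throughout; order fixes integer codes.
LANDCOVER_CLASSES <- c("grassland", "agriculture", "forest", "urban")
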