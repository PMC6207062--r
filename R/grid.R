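#' Regular geographic grid specification
#'
#' Describes a regular latitude/longitude grid with grid-cell (area)
#' registration on the WGS84 graticule: cells tile the graticule and values
#' represent cell areas, with cell centers offset half a cell from the grid
#' edges. Row 1 is the northernmost row, column 1 the westernmost column.
#'
#' @param rows,cols positive integer grid dimensions.
#' @param cell_size cell size in degrees. Pass exact expressions such as
#'   `1/120` so that the geotransform is reproduced bit-for-bit; display
#'   values like 0.0083 are rounded forms of these rationals.
#' @param xmin western edge longitude (degrees, default -180).
#' @param ymax northern edge latitude (degrees, default 90).
#' @return an object of class `kg_grid`.
#' @examples
#' kg_grid(360, 720, 1/2)          # the 0.5 degree global grid
#' kg_grid(21600, 43200, 1/120)    # the 1-km-class global grid
#' @export
kg_grid <- function(rows, cols, cell_size, xmin = -180, ymax = 90) {
  stopifnot(rows >= 1, cols >= 1, is.finite(cell_size), cell_size > 0)
  if (rows * cell_size > 180 + 1e-9 || cols * cell_size > 360 + 1e-9)
    stop("grid exceeds the globe: rows*cell_size must be <= 180 and cols*cell_size <= 360")
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         cell_size = as.numeric(cell_size),
         xmin = as.numeric(xmin), ymax = as.numeric(ymax)),
    class = "kg_grid")
}

#' @export
print.kg_grid <- function(x, ...) {
  cat(sprintf("<kg_grid> %d x %d @ %.6g deg, origin (%.6g W-edge, %.6g N-edge)\n",
              x$rows, x$cols, x$cell_size, x$xmin, x$ymax))
  invisible(x)
}

#' @rdname kg_grid
#' @param x object to test.
#' @export
is_kg_grid <- function(x) inherits(x, "kg_grid")

# exact-enough equality for grids that should share a geotransform
grids_identical <- function(a, b, tol = 1e-9) {
  a$rows == b$rows && a$cols == b$cols &&
    abs(a$cell_size - b$cell_size) < tol &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol
}

check_same_grid <- function(a, b, what = "grids") {
  if (!grids_identical(a, b))
    stop("incompatible ", what, ": grid specifications differ", call. = FALSE)
  invisible(TRUE)
}

#' Cell-center coordinates of a grid
#'
#' @param spec a [kg_grid()].
#' @return `grid_lats()`: latitudes of row centers (north to south);
#'   `grid_lons()`: longitudes of column centers (west to east).
#' @export
grid_lats <- function(spec) spec$ymax - (seq_len(spec$rows) - 0.5) * spec$cell_size

#' @rdname grid_lats
#' @export
grid_lons <- function(spec) spec$xmin + (seq_len(spec$cols) - 0.5) * spec$cell_size

#' Locate the grid cell containing a coordinate
#'
#' Cells are half-open intervals: a point exactly on a cell edge belongs to
#' the cell to the south-east of the edge. Points on the outermost south/east
#' edge of the grid are clamped into the last row/column.
#'
#' @param spec a [kg_grid()].
#' @param lat,lon coordinates in degrees (vectors of equal length).
#' @return a list with integer vectors `row` and `col`; NA where the point is
#'   outside the grid extent.
#' @export
grid_locate <- function(spec, lat, lon) {
  row <- floor((spec$ymax - lat) / spec$cell_size) + 1
  col <- floor((lon - spec$xmin) / spec$cell_size) + 1
  # south/east outer edge belongs to the last cell
  row[lat == spec$ymax - spec$rows * spec$cell_size] <- spec$rows
  col[lon == spec$xmin + spec$cols * spec$cell_size] <- spec$cols
  bad <- row < 1 | row > spec$rows | col < 1 | col > spec$cols
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Standard global grids of the published map resolutions
#'
#' The three resolutions at which maps are published: `"fine"` (1/120 degree,
#' about 1 km at the equator), `"medium"` (1/12 degree) and `"coarse"`
#' (1/2 degree), all global (90N-90S, 180W-180E).
#'
#' @param resolution one of `"fine"`, `"medium"`, `"coarse"`.
#' @return a [kg_grid()].
#' @examples
#' standard_grid("fine")    # 21600 x 43200
#' standard_grid("coarse")  # 360 x 720
#' @export
standard_grid <- function(resolution = c("fine", "medium", "coarse")) {
  resolution <- match.arg(resolution)
  switch(resolution,
    fine   = kg_grid(21600, 43200, 1/120),
    medium = kg_grid(2160, 4320, 1/12),
    coarse = kg_grid(360, 720, 1/2))
}

#' Monthly climatology stack on a grid
#'
#' A 12-band gridded climatology: `values[row, col, month]` with months in
#' calendar order (January = 1). Temperature is in degrees Celsius,
#' precipitation in mm/month. NA marks nodata cells.
#'
#' @param values numeric array `rows x cols x 12`.
#' @param spec the [kg_grid()] the stack lives on.
#' @param var `"temp"` or `"precip"`.
#' @return an object of class `kg_stack` (the array with `spec` and `var`
#'   attributes).
#' @export
kg_stack <- function(values, spec, var = c("temp", "precip")) {
  var <- match.arg(var)
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (dim(values)[1] != spec$rows || dim(values)[2] != spec$cols || dim(values)[3] != 12)
    stop("stack must be rows x cols x 12 matching the grid spec")
  if (var == "precip" && any(values < 0, na.rm = TRUE))
    stop("precipitation stack contains negative values")
  structure(values, spec = spec, var = var, class = c("kg_stack", "array"))
}

stack_spec <- function(x) attr(x, "spec")
stack_var  <- function(x) attr(x, "var")

#' @export
print.kg_stack <- function(x, ...) {
  s <- stack_spec(x)
  cat(sprintf("<kg_stack:%s> %d x %d x 12 @ %.6g deg; range [%.4g, %.4g]\n",
              stack_var(x), s$rows, s$cols, s$cell_size,
              suppressWarnings(min(x, na.rm = TRUE)),
              suppressWarnings(max(x, na.rm = TRUE))))
  invisible(x)
}

# Aggregate a fine matrix to a coarser nested grid by block mean (NA-aware).
# factor = coarse cell size / fine cell size, must be a whole number.
block_aggregate <- function(m, factor, fun = c("mean", "sum")) {
  fun <- match.arg(fun)
  nr <- nrow(m) %/% factor; nc <- ncol(m) %/% factor
  stopifnot(nr * factor == nrow(m), nc * factor == ncol(m))
  a <- array(m, dim = c(factor, nr, factor, nc))
  ok <- !is.na(a)
  a[!ok] <- 0
  collapse <- function(x) {   # sum over dims 1 and 3
    s1 <- colSums(x, dims = 1)                # (nr, factor, nc)
    colSums(aperm(s1, c(2, 1, 3)), dims = 1)  # (nr, nc)
  }
  s <- collapse(a)
  n <- collapse(ok + 0)
  out <- if (fun == "sum") s else s / n
  out[n == 0] <- NA_real_
  out
}
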