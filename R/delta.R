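#' Monthly gridded time series
#'
#' A per-month gridded series for one variable: `data[row, col, month, year]`
#' on a fixed grid, with `years` giving the calendar year of each slice.
#' This is the container for the coarse time-varying datasets used to
#' homogenize climatologies to a common period and to derive model anomalies.
#'
#' @param data numeric array `rows x cols x 12 x n_years`.
#' @param years integer vector of calendar years, one per slice.
#' @param spec the [kg_grid()].
#' @param var `"temp"` or `"precip"`.
#' @return an object of class `kg_series`.
#' @export
kg_series <- function(data, years, spec, var = c("temp", "precip")) {
  var <- match.arg(var)
  stopifnot(is.array(data), length(dim(data)) == 4)
  d <- dim(data)
  if (d[1] != spec$rows || d[2] != spec$cols || d[3] != 12 || d[4] != length(years))
    stop("series must be rows x cols x 12 x n_years matching spec and years")
  structure(list(data = data, years = as.integer(years), spec = spec, var = var),
            class = "kg_series")
}

#' @export
print.kg_series <- function(x, ...) {
  cat(sprintf("<kg_series:%s> %d x %d, years %d-%d (%d)\n", x$var,
              x$spec$rows, x$spec$cols, min(x$years), max(x$years),
              length(x$years)))
  invisible(x)
}

#' Period climatology of a gridded series
#'
#' Per-cell, per-month arithmetic mean over the years of the series that fall
#' inside the (inclusive) period. Cells that are nodata in every contributing
#' year stay nodata.
#'
#' @param series a [kg_series()].
#' @param period inclusive year range `c(first, last)`.
#' @return a [kg_stack()] of 12 monthly means.
#' @export
period_climatology <- function(series, period) {
  stopifnot(inherits(series, "kg_series"), length(period) == 2)
  keep <- series$years >= period[1] & series$years <= period[2]
  if (!any(keep))
    stop("empty period: the series has no years in ", period[1], "-", period[2])
  sub <- series$data[, , , keep, drop = FALSE]
  ok <- !is.na(sub)
  sub[!ok] <- 0
  s <- rowSums(sub, dims = 3)      # sum over years
  n <- rowSums(ok, dims = 3)
  out <- s / n
  out[n == 0] <- NA_real_
  kg_stack(out, series$spec, series$var)
}

#' Per-month climate-change field (offsets or factors)
#'
#' @param values numeric array `rows x cols x 12`.
#' @param spec the [kg_grid()].
#' @param mode `"offset"` (additive, temperature, degrees C) or `"factor"`
#'   (multiplicative, precipitation, dimensionless, non-negative).
#' @return an object of class `kg_change_field`.
#' @export
kg_change_field <- function(values, spec, mode = c("offset", "factor")) {
  mode <- match.arg(mode)
  stopifnot(is.array(values), length(dim(values)) == 3)
  d <- dim(values)
  if (d[1] != spec$rows || d[2] != spec$cols || d[3] != 12)
    stop("change field must be rows x cols x 12 matching the grid spec")
  if (mode == "factor" && any(values < 0, na.rm = TRUE))
    stop("multiplicative change factors must be non-negative")
  structure(values, spec = spec, mode = mode,
            class = c("kg_change_field", "array"))
}

field_mode <- function(x) attr(x, "mode")

#' Compute a climate-change field between two climatologies
#'
#' Additive mode (temperature): `target - source` per month and cell.
#' Multiplicative mode (precipitation): `target / max(source, epsilon)`,
#' capped at `cap`. The epsilon guard and the cap only matter for near-zero
#' baselines; over real climatologies change factors stay small (below about
#' 5). Cells masked in either input are masked in the result.
#'
#' @param target,source [kg_stack()]s on the same grid (the period to adjust
#'   toward, and the period the data currently represent).
#' @param mode `"offset"` or `"factor"`; defaults to the mode matching the
#'   stacks' variable (offset for temperature, factor for precipitation).
#' @param epsilon floor (mm/month) applied to the source in factor mode.
#' @param cap upper bound on change factors.
#' @return a [kg_change_field()].
#' @export
change_field <- function(target, source, mode = NULL, epsilon = 0.01, cap = 10) {
  stopifnot(inherits(target, "kg_stack"), inherits(source, "kg_stack"))
  spec <- stack_spec(target)
  check_same_grid(spec, stack_spec(source), "climatology stacks")
  if (is.null(mode))
    mode <- if (stack_var(target) == "temp") "offset" else "factor"
  if (mode == "offset") {
    vals <- unclass(target) - unclass(source)
  } else {
    vals <- unclass(target) / pmax(unclass(source), epsilon)
    vals <- pmin(vals, cap)
  }
  vals[is.na(unclass(target)) | is.na(unclass(source))] <- NA_real_
  attributes(vals) <- list(dim = dim(unclass(target)))
  kg_change_field(vals, spec, mode)
}

#' Resample a change field to a finer grid by bilinear interpolation
#'
#' Interpolates cell-center values among the four nearest coarse cell
#' centers. Fine centers outside the outermost coarse centers are clamped to
#' the edge (no extrapolation); when the coarse grid spans 360 degrees of
#' longitude the interpolation wraps across the antimeridian. Masked coarse
#' neighbors are dropped with weight renormalization; a fine cell whose four
#' neighbors are all masked is masked.
#'
#' @param field a [kg_change_field()] on a coarse grid.
#' @param fine the target [kg_grid()], nested within the coarse extent.
#' @return a [kg_change_field()] on `fine` with the same mode.
#' @export
bilinear_to_grid <- function(field, fine) {
  coarse <- attr(field, "spec")
  mode <- field_mode(field)
  tol <- 1e-9
  global_lon <- abs(coarse$cols * coarse$cell_size - 360) < tol

  c_xmax <- coarse$xmin + coarse$cols * coarse$cell_size
  c_ymin <- coarse$ymax - coarse$rows * coarse$cell_size
  f_xmax <- fine$xmin + fine$cols * fine$cell_size
  f_ymin <- fine$ymax - fine$rows * fine$cell_size
  if (fine$ymax > coarse$ymax + tol || f_ymin < c_ymin - tol ||
      (!global_lon && (fine$xmin < coarse$xmin - tol || f_xmax > c_xmax + tol)))
    stop("incompatible grids: fine grid is not nested within the coarse extent")

  lat_c <- grid_lats(coarse); lon_c <- grid_lons(coarse)
  lat_f <- grid_lats(fine);   lon_f <- grid_lons(fine)

  # latitude: descending; clamp outside the outermost centers
  i <- findInterval(-lat_f, -lat_c)
  i <- pmin(pmax(i, 1L), coarse$rows - 1L)
  t <- (lat_c[i] - lat_f) / coarse$cell_size
  t <- pmin(pmax(t, 0), 1)
  if (coarse$rows == 1L) { i <- rep(1L, length(lat_f)); t <- rep(0, length(lat_f)) }

  # longitude: optionally wrap across the seam
  if (global_lon) {
    lon_x <- c(lon_c, lon_c[1] + 360)
    lon_fw <- ifelse(lon_f < lon_c[1], lon_f + 360, lon_f)
    j <- findInterval(lon_fw, lon_x)
    j <- pmin(pmax(j, 1L), coarse$cols)   # col index into extended (wrap) axis
    u <- (lon_fw - lon_x[j]) / coarse$cell_size
    u <- pmin(pmax(u, 0), 1)
    jr <- ifelse(j == coarse$cols, 1L, j + 1L)  # right neighbor with wrap
  } else {
    j <- findInterval(lon_f, lon_c)
    j <- pmin(pmax(j, 1L), max(coarse$cols - 1L, 1L))
    u <- (lon_f - lon_c[j]) / coarse$cell_size
    u <- pmin(pmax(u, 0), 1)
    if (coarse$cols == 1L) u <- rep(0, length(lon_f))
    jr <- pmin(j + 1L, coarse$cols)
  }

  fr <- fine$rows; fc <- fine$cols
  I  <- matrix(i,  fr, fc);  Ib <- matrix(pmin(i + 1L, coarse$rows), fr, fc)
  J  <- matrix(j,  fr, fc, byrow = TRUE)
  Jr <- matrix(jr, fr, fc, byrow = TRUE)
  Tm <- matrix(t, fr, fc); Um <- matrix(u, fr, fc, byrow = TRUE)
  W11 <- (1 - Tm) * (1 - Um); W12 <- (1 - Tm) * Um
  W21 <- Tm * (1 - Um);       W22 <- Tm * Um

  nr <- coarse$rows
  id11 <- (J  - 1L) * nr + I;  id12 <- (Jr - 1L) * nr + I
  id21 <- (J  - 1L) * nr + Ib; id22 <- (Jr - 1L) * nr + Ib

  out <- array(NA_real_, dim = c(fr, fc, 12))
  for (m in 1:12) {
    V <- unclass(field)[, , m]
    v11 <- V[id11]; v12 <- V[id12]; v21 <- V[id21]; v22 <- V[id22]
    num <- W11 * ifelse(is.na(v11), 0, v11) + W12 * ifelse(is.na(v12), 0, v12) +
           W21 * ifelse(is.na(v21), 0, v21) + W22 * ifelse(is.na(v22), 0, v22)
    den <- W11 * (!is.na(v11)) + W12 * (!is.na(v12)) +
           W21 * (!is.na(v21)) + W22 * (!is.na(v22))
    slice <- num / den
    slice[den == 0] <- NA_real_
    out[, , m] <- slice
  }
  kg_change_field(out, fine, mode)
}

#' Apply a change field to a climatology
#'
#' Additive fields are added (temperature); multiplicative fields multiply
#' and any negative result is clipped to zero (precipitation). Nodata in
#' either input propagates.
#'
#' @param clim a [kg_stack()].
#' @param field a [kg_change_field()] on the same grid; its mode must match
#'   the stack's variable (offset for temperature, factor for precipitation).
#' @return the adjusted [kg_stack()].
#' @export
apply_change <- function(clim, field) {
  stopifnot(inherits(clim, "kg_stack"), inherits(field, "kg_change_field"))
  spec <- stack_spec(clim)
  check_same_grid(spec, attr(field, "spec"), "climatology and change field")
  mode <- field_mode(field)
  var <- stack_var(clim)
  if ((var == "temp") != (mode == "offset"))
    stop("mode/variable mismatch: offsets apply to temperature, factors to precipitation")
  vals <- if (mode == "offset") unclass(clim) + unclass(field)
          else pmax(unclass(clim) * unclass(field), 0)
  attributes(vals) <- list(dim = dim(unclass(clim)))
  kg_stack(vals, spec, var)
}

#' Homogenize a climatology to a target period
#'
#' Adjusts a high-resolution climatology representing `source_period` so that
#' it reflects `target_period`, using a coarse time-varying reference series:
#' the per-month change between the two period climatologies of the reference
#' is computed ([change_field()]), resampled to the fine grid
#' ([bilinear_to_grid()]) and applied ([apply_change()]). Temperature uses
#' additive offsets, precipitation multiplicative factors.
#'
#' @param clim fine-grid [kg_stack()] to adjust.
#' @param reference coarse [kg_series()] of the same variable.
#' @param source_period inclusive year range the climatology represents.
#' @param target_period inclusive year range to adjust to.
#' @param epsilon,cap guards for factor mode, see [change_field()].
#' @return the homogenized [kg_stack()].
#' @export
homogenize <- function(clim, reference, source_period, target_period,
                       epsilon = 0.01, cap = 10) {
  stopifnot(inherits(clim, "kg_stack"), inherits(reference, "kg_series"))
  if (stack_var(clim) != reference$var)
    stop("climatology and reference series are for different variables")
  tgt <- period_climatology(reference, target_period)
  src <- period_climatology(reference, source_period)
  cf <- change_field(tgt, src, epsilon = epsilon, cap = cap)
  cf_fine <- bilinear_to_grid(cf, stack_spec(clim))
  apply_change(clim, cf_fine)
}
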