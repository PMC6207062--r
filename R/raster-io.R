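# Lightweight GeoTIFF support: single-band, uncompressed, little-endian,
# uint8 (class/confidence maps) or float32 (climatology stacks), WGS84
# geographic referencing via the ModelPixelScale/ModelTiepoint tags and a
# GeoKey directory (GTModelType = geographic, GTRasterType = PixelIsArea,
# GeographicType = EPSG:4326), plus the GDAL_NODATA ascii tag. This covers
# exactly the product formats used here; it is not a general TIFF
# implementation.

TIFF_TYPE_ASCII  <- 2L
TIFF_TYPE_SHORT  <- 3L
TIFF_TYPE_LONG   <- 4L
TIFF_TYPE_DOUBLE <- 12L

uint32_le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
uint16_le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
double_le <- function(x) writeBin(as.numeric(x), raw(), size = 8, endian = "little")

write_geotiff_band <- function(values, spec, path, nodata = 0,
                               type = c("uint8", "float32")) {
  type <- match.arg(type)
  stopifnot(is.matrix(values))
  rows <- spec$rows; cols <- spec$cols
  # pixel data row-major (TIFF scanline order), single strip
  if (type == "uint8") {
    vals <- as.integer(values)
    vals[is.na(vals)] <- as.integer(nodata)
    if (any(vals < 0L | vals > 255L)) stop("uint8 raster values must lie in 0-255")
    pix <- as.raw(as.vector(t(matrix(vals, rows, cols))))
    bits <- 8L; fmt <- 1L
  } else {
    vals <- as.numeric(values)
    vals[is.na(vals)] <- as.numeric(nodata)
    pix <- writeBin(as.vector(t(matrix(vals, rows, cols))), raw(),
                    size = 4, endian = "little")
    bits <- 32L; fmt <- 3L
  }
  n_pix <- length(pix)
  data_off <- 8L
  ifd_off <- data_off + n_pix + (n_pix %% 2L)   # word-align the IFD

  scale  <- double_le(c(spec$cell_size, spec$cell_size, 0))
  tiept  <- double_le(c(0, 0, 0, spec$xmin, spec$ymax, 0))
  geokey <- uint16_le(c(1, 1, 0, 3,          # version, revision, n keys
                        1024, 0, 1, 2,       # model type: geographic
                        1025, 0, 1, 1,       # raster type: pixel-is-area
                        2048, 0, 1, 4326))   # geographic CRS: WGS84
  nodata_str <- c(charToRaw(format(nodata)), as.raw(0))
  n_entries <- 15L
  ifd_size <- 2L + n_entries * 12L + 4L
  aux_off <- ifd_off + ifd_size
  scale_off  <- aux_off
  tiept_off  <- scale_off + length(scale)
  geokey_off <- tiept_off + length(tiept)
  nodata_off <- geokey_off + length(geokey)

  entry <- function(tag, type, count, value_raw) {
    stopifnot(length(value_raw) <= 4)
    c(uint16_le(tag), uint16_le(type), uint32_le(count),
      value_raw, rep(as.raw(0), 4 - length(value_raw)))
  }
  short_val <- function(x) uint16_le(x)
  long_val  <- function(x) uint32_le(x)

  entries <- c(
    entry(256L, TIFF_TYPE_LONG, 1L, long_val(cols)),
    entry(257L, TIFF_TYPE_LONG, 1L, long_val(rows)),
    entry(258L, TIFF_TYPE_SHORT, 1L, short_val(bits)),
    entry(259L, TIFF_TYPE_SHORT, 1L, short_val(1L)),        # no compression
    entry(262L, TIFF_TYPE_SHORT, 1L, short_val(1L)),        # black is zero
    entry(273L, TIFF_TYPE_LONG, 1L, long_val(data_off)),    # strip offset
    entry(277L, TIFF_TYPE_SHORT, 1L, short_val(1L)),
    entry(278L, TIFF_TYPE_LONG, 1L, long_val(rows)),        # rows per strip
    entry(279L, TIFF_TYPE_LONG, 1L, long_val(n_pix)),
    entry(284L, TIFF_TYPE_SHORT, 1L, short_val(1L)),        # chunky
    entry(339L, TIFF_TYPE_SHORT, 1L, short_val(fmt)),       # unsigned/float
    entry(33550L, TIFF_TYPE_DOUBLE, 3L, long_val(scale_off)),
    entry(33922L, TIFF_TYPE_DOUBLE, 6L, long_val(tiept_off)),
    entry(34735L, TIFF_TYPE_SHORT, 16L, long_val(geokey_off)),
    entry(42113L, TIFF_TYPE_ASCII, length(nodata_str),
          if (length(nodata_str) <= 4) nodata_str else long_val(nodata_off)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), uint16_le(42L), uint32_le(ifd_off)), con)
  writeBin(pix, con)
  if (n_pix %% 2L) writeBin(raw(1), con)
  writeBin(c(uint16_le(n_entries), entries, uint32_le(0L)), con)
  writeBin(c(scale, tiept, geokey), con)
  if (length(nodata_str) > 4) writeBin(nodata_str, con)
  invisible(path)
}

read_geotiff_band <- function(path) {
  raw_all <- readBin(path, raw(), n = file.size(path))
  if (length(raw_all) < 8) stop("malformed TIFF: file too short")
  order <- rawToChar(raw_all[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big"
            else stop("malformed TIFF: bad byte-order mark")
  rd_int <- function(off, size, n = 1)
    readBin(raw_all[(off + 1):(off + size * n)], "integer",
            n = n, size = size, endian = endian, signed = size == 4)
  rd_dbl <- function(off, n)
    readBin(raw_all[(off + 1):(off + 8 * n)], "double",
            n = n, size = 8, endian = endian)
  if (rd_int(2, 2) != 42L) stop("malformed TIFF: bad magic number")
  ifd_off <- rd_int(4, 4)
  n_entries <- rd_int(ifd_off, 2)
  tags <- list()
  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)
  for (e in seq_len(n_entries)) {
    off <- ifd_off + 2L + (e - 1L) * 12L
    tag <- rd_int(off, 2); type <- rd_int(off + 2, 2); count <- rd_int(off + 4, 4)
    sz <- type_size[as.character(type)]
    if (is.na(sz)) next
    voff <- if (sz * count > 4) rd_int(off + 8, 4) else off + 8L
    val <- if (type == TIFF_TYPE_DOUBLE) rd_dbl(voff, count)
           else if (type == TIFF_TYPE_ASCII) {
             b <- raw_all[(voff + 1):(voff + count)]
             rawToChar(b[b != as.raw(0)])
           } else rd_int(voff, sz, count)
    tags[[as.character(tag)]] <- val
  }
  need <- function(tag) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) stop("malformed TIFF: missing tag ", tag)
    v
  }
  cols <- need(256); rows <- need(257)
  bits <- need(258)[1]; fmt <- (tags[["339"]] %||% 1L)[1]
  if ((tags[["277"]] %||% 1L) != 1L)
    stop("unsupported TIFF: only single-band rasters are handled")
  if (need(259) != 1L) stop("unsupported TIFF: compressed data")
  if (!((bits == 8L && fmt == 1L) || (bits == 32L && fmt == 3L)))
    stop("unsupported TIFF: only uint8 and float32 samples are handled")
  offsets <- need(273); counts <- need(279)
  pix <- raw(0)
  for (s in seq_along(offsets))
    pix <- c(pix, raw_all[(offsets[s] + 1):(offsets[s] + counts[s])])
  if (length(pix) != rows * cols * bits / 8)
    stop("malformed TIFF: pixel count mismatch")
  if (bits == 8L) {
    vals <- matrix(as.integer(pix), rows, cols, byrow = TRUE)
    type <- "uint8"
  } else {
    v <- readBin(pix, "double", n = rows * cols, size = 4, endian = endian)
    vals <- matrix(v, rows, cols, byrow = TRUE)
    type <- "float32"
    nd <- tags[["42113"]]
    if (!is.null(nd)) {
      ndv <- suppressWarnings(as.numeric(nd))
      if (is.finite(ndv)) vals[abs(vals - ndv) < 1e-6 * max(1, abs(ndv))] <- NA_real_
    }
  }

  scale <- tags[["33550"]]; tiept <- tags[["33922"]]
  if (is.null(scale) || is.null(tiept))
    stop("not a GeoTIFF: missing georeferencing tags")
  spec <- kg_grid(rows, cols, scale[1], xmin = tiept[4] - tiept[1] * scale[1],
                  ymax = tiept[5] + tiept[2] * scale[2])
  list(values = vals, spec = spec, type = type)
}

#' Write and read classification maps as GeoTIFF
#'
#' Class maps are stored as single-band unsigned 8-bit GeoTIFFs on the WGS84
#' graticule, codes 1-30 with nodata 0, so that `read_class_map(
#' write_class_map(x, path))` reproduces `x` exactly. Files containing codes
#' above 30 are rejected on read.
#'
#' @param grid a [kg_class_grid()].
#' @param path file path ending in `.tif`.
#' @return `write_class_map()`: the path, invisibly; `read_class_map()`: a
#'   [kg_class_grid()].
#' @export
write_class_map <- function(grid, path) {
  stopifnot(inherits(grid, "kg_class_grid"))
  write_geotiff_band(grid$codes, grid$spec, path, nodata = 0, type = "uint8")
  invisible(path)
}

#' @rdname write_class_map
#' @export
read_class_map <- function(path) {
  r <- read_geotiff_band(path)
  if (any(r$values > 30L))
    stop("invalid class map: values above 30 in ", path)
  kg_class_grid(r$values, r$spec)
}

#' Write and read confidence maps as GeoTIFF
#'
#' Confidence levels are rounded to the nearest whole percent for the 8-bit
#' format; nodata cells are stored as 0.
#'
#' @param grid a [kg_conf_grid()].
#' @param path file path.
#' @return `write_conf_map()`: the path, invisibly; `read_conf_map()`: a
#'   [kg_conf_grid()] with integer percentages.
#' @export
write_conf_map <- function(grid, path) {
  stopifnot(inherits(grid, "kg_conf_grid"))
  vals <- round(grid$values)
  write_geotiff_band(vals, grid$spec, path, nodata = 0, type = "uint8")
  invisible(path)
}

#' @rdname write_conf_map
#' @export
read_conf_map <- function(path) {
  r <- read_geotiff_band(path)
  if (any(r$values > 100L))
    stop("invalid confidence map: values above 100 in ", path)
  vals <- r$values + 0.0
  vals[vals == 0] <- NA_real_
  kg_conf_grid(vals, r$spec)
}

upscale_factor <- function(source, target) {
  f <- target$cell_size / source$cell_size
  if (abs(f - round(f)) > 1e-9 || round(f) < 1)
    stop("incompatible grids: target cell size must be an integer multiple of the source")
  tol <- 1e-9
  if (abs(source$xmin - target$xmin) > tol || abs(source$ymax - target$ymax) > tol ||
      source$rows != target$rows * round(f) || source$cols != target$cols * round(f))
    stop("incompatible grids: grids are not nested/aligned")
  as.integer(round(f))
}

#' Upscale a classification map by majority resampling
#'
#' Each target cell takes the modal class of its block of source cells,
#' ignoring nodata; ties are broken toward the lowest class code, and a block
#' that is nodata throughout stays nodata. This is how the 1/120 degree map
#' is aggregated to the 1/12 and 1/2 degree products.
#'
#' @param grid a [kg_class_grid()].
#' @param target a coarser, nested [kg_grid()].
#' @return a [kg_class_grid()] on `target`.
#' @export
upscale_majority <- function(grid, target) {
  stopifnot(inherits(grid, "kg_class_grid"))
  f <- upscale_factor(grid$spec, target)
  best_cnt  <- matrix(0, target$rows, target$cols)
  best_code <- matrix(0L, target$rows, target$cols)
  present <- setdiff(sort(unique(as.vector(grid$codes))), 0L)
  for (k in present) {
    cnt <- block_aggregate((grid$codes == k) + 0, f, "sum")
    better <- cnt > best_cnt
    if (any(better)) {
      best_code[better] <- k
      best_cnt[better] <- cnt[better]
    }
  }
  kg_class_grid(best_code, target)
}

#' Upscale a confidence map by block averaging
#'
#' Aggregates confidence levels to a coarser grid as the mean of the
#' unmasked source cells in each block; blocks with no unmasked cell stay
#' nodata.
#'
#' @param grid a [kg_conf_grid()].
#' @param target a coarser, nested [kg_grid()].
#' @return a [kg_conf_grid()] on `target`.
#' @export
upscale_mean <- function(grid, target) {
  stopifnot(inherits(grid, "kg_conf_grid"))
  f <- upscale_factor(grid$spec, target)
  kg_conf_grid(block_aggregate(grid$values, f, "mean"), target)
}

#' File name for a published map product
#'
#' Follows the `<prefix>_<epoch>[_conf]_<res>.tif` convention, with
#' resolution tokens `0p0083`, `0p083` and `0p5` for the fine, medium and
#' coarse grids.
#'
#' @param epoch `"present"` or `"future"`.
#' @param resolution `"fine"`, `"medium"` or `"coarse"`.
#' @param conf TRUE for the confidence companion map.
#' @param prefix file name prefix.
#' @return the file name as a string.
#' @examples
#' map_filename("present", "fine")          # "KG_present_0p0083.tif"
#' map_filename("future", "coarse", TRUE)   # "KG_future_conf_0p5.tif"
#' @export
map_filename <- function(epoch = c("present", "future"),
                         resolution = c("fine", "medium", "coarse"),
                         conf = FALSE, prefix = "KG") {
  epoch <- match.arg(epoch); resolution <- match.arg(resolution)
  res_tok <- c(fine = "0p0083", medium = "0p083", coarse = "0p5")[resolution]
  paste0(prefix, "_", epoch, if (conf) "_conf" else "", "_", res_tok, ".tif")
}

#' Read and write monthly climatology stacks as GeoTIFF files
#'
#' A 12-month stack is stored as twelve single-band float32 GeoTIFFs named
#' `<prefix>_01.tif` ... `<prefix>_12.tif` (nodata -9999). This is the
#' on-disk form the command-line pipeline uses for climatology inputs.
#'
#' @param stack a [kg_stack()].
#' @param prefix path prefix for the twelve files.
#' @param var variable of the stack being read (`"temp"` or `"precip"`).
#' @return `write_stack_tifs()`: the twelve paths, invisibly;
#'   `read_stack_tifs()`: a [kg_stack()].
#' @export
write_stack_tifs <- function(stack, prefix) {
  stopifnot(inherits(stack, "kg_stack"))
  spec <- stack_spec(stack)
  paths <- sprintf("%s_%02d.tif", prefix, 1:12)
  for (m in 1:12)
    write_geotiff_band(unclass(stack)[, , m], spec, paths[m],
                       nodata = -9999, type = "float32")
  invisible(paths)
}

#' @rdname write_stack_tifs
#' @export
read_stack_tifs <- function(prefix, var = c("temp", "precip")) {
  var <- match.arg(var)
  paths <- sprintf("%s_%02d.tif", prefix, 1:12)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing monthly band files: ", paste(missing, collapse = ", "))
  first <- read_geotiff_band(paths[1])
  vals <- array(NA_real_, c(first$spec$rows, first$spec$cols, 12))
  vals[, , 1] <- first$values
  for (m in 2:12) {
    r <- read_geotiff_band(paths[m])
    check_same_grid(first$spec, r$spec, "monthly band files")
    vals[, , m] <- r$values
  }
  if (var == "precip") vals <- pmax(vals, 0)   # float32 rounding guard
  kg_stack(vals, first$spec, var)
}
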