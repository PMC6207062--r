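#' Koppen-Geiger class legend
#'
#' The fixed bijection between numeric class codes 1-30, class symbols
#' (Af ... EF) and display colors. Codes follow the conventional row order of
#' the classification table: tropical (Af=1, Am=2, Aw=3), arid (BWh=4, BWk=5,
#' BSh=6, BSk=7), temperate (Csa=8 ... Cfc=16), cold (Dsa=17 ... Dfd=28) and
#' polar (ET=29, EF=30). Colors are adapted from the Peel color scheme.
#'
#' @return a data.frame with columns `code`, `symbol`, `major`, `r`, `g`, `b`.
#' @examples
#' leg <- koppen_legend()
#' nrow(leg)            # 30
#' leg$symbol[leg$code == 8]  # "Csa"
#' @export
koppen_legend <- function() {
  leg <- data.frame(
    code = 1:30,
    symbol = c("Af", "Am", "Aw",
               "BWh", "BWk", "BSh", "BSk",
               "Csa", "Csb", "Csc", "Cwa", "Cwb", "Cwc", "Cfa", "Cfb", "Cfc",
               "Dsa", "Dsb", "Dsc", "Dsd", "Dwa", "Dwb", "Dwc", "Dwd",
               "Dfa", "Dfb", "Dfc", "Dfd",
               "ET", "EF"),
    r = c(0, 0, 70, 255, 255, 245, 255, 255, 200, 150, 150, 100, 50, 200,
          100, 50, 255, 200, 150, 150, 170, 90, 75, 50, 0, 55, 0, 0, 178, 102),
    g = c(0, 120, 170, 0, 150, 165, 220, 255, 200, 150, 255, 200, 150, 255,
          255, 200, 0, 0, 50, 100, 175, 120, 80, 0, 255, 200, 125, 70, 178, 102),
    b = c(255, 255, 250, 0, 150, 0, 100, 0, 0, 0, 150, 100, 50, 80, 80, 0,
          255, 200, 150, 150, 255, 220, 180, 135, 255, 255, 125, 95, 178, 102),
    stringsAsFactors = FALSE)
  leg$major <- substr(leg$symbol, 1, 1)
  leg[, c("code", "symbol", "major", "r", "g", "b")]
}

#' Convert between class codes and symbols
#'
#' @param code integer class codes (1-30; 0 and NA map to NA).
#' @param symbol class symbols such as "Csa".
#' @return `koppen_symbol()`: character symbols; `koppen_code()`: integer codes.
#' @export
koppen_symbol <- function(code) {
  leg <- koppen_legend()
  out <- rep(NA_character_, length(code))
  ok <- !is.na(code) & code >= 1 & code <= 30
  out[ok] <- leg$symbol[code[ok]]
  out
}

#' @rdname koppen_symbol
#' @export
koppen_code <- function(symbol) {
  leg <- koppen_legend()
  out <- leg$code[match(symbol, leg$symbol)]
  if (anyNA(out) && !anyNA(symbol))
    stop("unknown class symbol: ", paste(symbol[is.na(out)], collapse = ", "))
  out
}

#' Write the plain-text legend file
#'
#' One line per class: `<code> <symbol> <R> <G> <B>`. The same file ships as a
#' packaged resource (`system.file("extdata", "legend.txt", package =
#' "koppenmap")`).
#'
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_legend <- function(path) {
  leg <- koppen_legend()
  writeLines(sprintf("%d %s %d %d %d", leg$code, leg$symbol, leg$r, leg$g, leg$b),
             path)
  invisible(path)
}

# months of the two fixed half-year blocks
MONTHS_APR_SEP <- 4:9
MONTHS_OCT_MAR <- c(10:12, 1:3)

validate_monthly <- function(x, what) {
  if (length(x) != 12 || !is.numeric(x) || any(!is.finite(x)))
    stop("invalid climatology: ", what, " must be 12 finite numeric values",
         call. = FALSE)
  invisible(TRUE)
}

#' Determine the summer and winter half-years
#'
#' Summer is whichever of the two fixed six-month blocks April-September and
#' October-March has the higher mean temperature; winter is the other. On an
#' exact tie summer defaults to April-September (relevant only for seasonally
#' flat profiles, where the seasonal sub-criteria are inert).
#'
#' @param temp 12 monthly mean temperatures (degrees C, January first).
#' @return a list with integer month vectors `summer` and `winter` and the
#'   logical flag `apr_sep` (TRUE when summer is April-September).
#' @examples
#' season_split(c(8, 9, 11, 13, 17, 21, 24, 24, 21, 16, 12, 9))$apr_sep  # TRUE
#' @export
season_split <- function(temp) {
  validate_monthly(temp, "temperature")
  apr_sep <- mean(temp[MONTHS_APR_SEP]) >= mean(temp[MONTHS_OCT_MAR])
  if (apr_sep) list(summer = MONTHS_APR_SEP, winter = MONTHS_OCT_MAR, apr_sep = TRUE)
  else         list(summer = MONTHS_OCT_MAR, winter = MONTHS_APR_SEP, apr_sep = FALSE)
}

#' Aridity threshold of the B (arid) class
#'
#' `P_threshold = 2*MAT` when more than 70% of precipitation falls in winter,
#' `2*MAT + 28` when more than 70% falls in summer, and `2*MAT + 14`
#' otherwise. The 70% boundaries are strict: exactly 70% takes the
#' "otherwise" branch, as does an undefined winter fraction (zero annual
#' precipitation).
#'
#' @param mat mean annual air temperature (degrees C).
#' @param winter_frac fraction of annual precipitation falling in the winter
#'   half-year (0-1, or NA when annual precipitation is zero).
#' @return the threshold, on the mm/year scale used by the arid criteria
#'   (`MAP < 10 * P_threshold`).
#' @examples
#' p_threshold(15.42, 0.758)  # winter branch: 30.84
#' p_threshold(10, 0.2)       # summer branch: 48
#' p_threshold(25, 0.5)       # otherwise:     64
#' @export
p_threshold <- function(mat, winter_frac) {
  if (any(winter_frac < 0 | winter_frac > 1, na.rm = TRUE))
    stop("winter_frac must lie in [0, 1] (or NA when undefined)")
  n <- max(length(mat), length(winter_frac))
  mat <- rep_len(mat, n)
  wf <- rep_len(winter_frac, n)
  out <- 2 * mat + 14
  winter <- !is.na(wf) & wf > 0.7
  summer <- !is.na(wf) & (1 - wf) > 0.7
  out[winter] <- 2 * mat[winter]
  out[summer] <- 2 * mat[summer] + 28
  out
}

# Vectorized index computation over n x 12 matrices. Returns a list of
# n-vectors. Rows containing NA yield NA indices (nodata); non-finite
# non-NA values or negative precipitation raise an error.
indices_matrix <- function(temp, precip) {
  stopifnot(is.matrix(temp), is.matrix(precip),
            ncol(temp) == 12, ncol(precip) == 12,
            nrow(temp) == nrow(precip))
  if (any(is.nan(temp)) || any(is.infinite(temp)) ||
      any(is.nan(precip)) || any(is.infinite(precip)))
    stop("invalid climatology: non-finite values (use NA for nodata)", call. = FALSE)
  if (any(precip < 0, na.rm = TRUE))
    stop("invalid climatology: negative precipitation", call. = FALSE)

  tc <- as.data.frame(temp); pc <- as.data.frame(precip)
  rmin <- function(df, cols) do.call(pmin, df[cols])
  rmax <- function(df, cols) do.call(pmax, df[cols])

  MAT   <- rowMeans(temp)
  MAP   <- rowSums(precip)
  T_cold <- do.call(pmin, tc)
  T_hot  <- do.call(pmax, tc)
  T_mon10 <- rowSums(temp > 10)

  mean49  <- rowMeans(temp[, MONTHS_APR_SEP, drop = FALSE])
  mean103 <- rowMeans(temp[, MONTHS_OCT_MAR, drop = FALSE])
  apr_sep <- mean49 >= mean103   # tie -> Apr-Sep summer

  min49  <- rmin(pc, MONTHS_APR_SEP);  max49  <- rmax(pc, MONTHS_APR_SEP)
  min103 <- rmin(pc, MONTHS_OCT_MAR);  max103 <- rmax(pc, MONTHS_OCT_MAR)
  sum49  <- rowSums(precip[, MONTHS_APR_SEP, drop = FALSE])
  sum103 <- rowSums(precip[, MONTHS_OCT_MAR, drop = FALSE])

  P_sdry <- ifelse(apr_sep, min49, min103)
  P_swet <- ifelse(apr_sep, max49, max103)
  P_wdry <- ifelse(apr_sep, min103, min49)
  P_wwet <- ifelse(apr_sep, max103, max49)
  P_summer <- ifelse(apr_sep, sum49, sum103)
  P_winter <- MAP - P_summer

  winter_frac <- ifelse(MAP > 0, P_winter / MAP, NA_real_)
  # rows that are entirely NA keep NA via arithmetic; guard the MAP>0 test
  winter_frac[is.na(MAP)] <- NA_real_

  list(MAT = MAT, MAP = MAP, T_cold = T_cold, T_hot = T_hot,
       T_mon10 = T_mon10, P_dry = pmin(P_sdry, P_wdry),
       P_sdry = P_sdry, P_swet = P_swet, P_wdry = P_wdry, P_wwet = P_wwet,
       P_summer = P_summer, P_winter = P_winter,
       winter_frac = winter_frac,
       P_threshold = p_threshold(MAT, winter_frac),
       apr_sep = apr_sep)
}

#' Bioclimatic indices of a monthly climatology
#'
#' Computes every derived quantity the classifier uses: mean annual
#' temperature (MAT, degrees C), mean annual precipitation (MAP, mm/year),
#' coldest/warmest month temperatures, the count of months above 10 degrees C,
#' driest-month precipitation overall and within the summer/winter half-years,
#' the wettest summer/winter months, the winter precipitation fraction and the
#' aridity threshold [p_threshold()]. Seasonal extremes use the half-year
#' blocks from [season_split()].
#'
#' @param temp 12 monthly mean temperatures (degrees C, January first).
#' @param precip 12 monthly precipitation totals (mm/month, January first).
#' @return a named list of scalar indices.
#' @examples
#' ind <- climate_indices(rep(25, 12), rep(100, 12))
#' ind$MAP          # 1200
#' ind$P_threshold  # 64
#' @export
climate_indices <- function(temp, precip) {
  validate_monthly(temp, "temperature")
  validate_monthly(precip, "precipitation")
  idx <- indices_matrix(matrix(temp, 1), matrix(precip, 1))
  lapply(idx, `[`, 1)
}

# Vectorized classifier core over n x 12 matrices -> integer codes
# (0 = nodata for rows containing NA).
codes_from_matrices <- function(temp, precip) {
  idx <- indices_matrix(temp, precip)
  n <- length(idx$MAT)
  code <- integer(n)
  valid <- !is.na(idx$MAT) & !is.na(idx$MAP)

  with(idx, {
    B <- valid & MAP < 10 * P_threshold
    desert <- MAP < 5 * P_threshold
    hot <- MAT >= 18
    code[B &  desert &  hot] <- 4L
    code[B &  desert & !hot] <- 5L
    code[B & !desert &  hot] <- 6L
    code[B & !desert & !hot] <- 7L

    rest <- valid & !B
    E <- rest & T_hot <= 10
    code[E & T_hot > 0]  <- 29L
    code[E & T_hot <= 0] <- 30L

    A <- rest & !E & T_cold >= 18
    af <- P_dry >= 60
    am <- !af & P_dry >= 100 - MAP / 25
    code[A & af] <- 1L
    code[A & am] <- 2L
    code[A & !af & !am] <- 3L

    C <- rest & !E & T_hot > 10 & T_cold > 0 & T_cold < 18
    D <- rest & !E & T_hot > 10 & T_cold <= 0
    CD <- C | D

    # second letter: s / w mutually exclusive; when both criteria hold,
    # s iff winter receives more precipitation than summer, else w
    s_crit <- P_sdry < 40 & P_sdry < P_wwet / 3
    w_crit <- P_wdry < P_swet / 10
    sec <- rep(2L, n)                               # f
    sec[s_crit & !w_crit] <- 0L                     # s
    sec[w_crit & !s_crit] <- 1L                     # w
    both <- s_crit & w_crit
    sec[both & P_winter >  P_summer] <- 0L
    sec[both & P_winter <= P_summer] <- 1L

    a3 <- T_hot >= 22
    b3 <- !a3 & T_mon10 >= 4
    thC <- rep(2L, n); thC[b3] <- 1L; thC[a3] <- 0L
    code[C] <- 8L + 3L * sec[C] + thC[C]

    d3 <- !a3 & !b3 & T_cold < -38
    thD <- rep(2L, n); thD[d3] <- 3L; thD[b3] <- 1L; thD[a3] <- 0L
    code[D] <- 17L + 4L * sec[D] + thD[D]

    if (any(code[valid] == 0L))
      stop("internal error: a valid climatology matched no class", call. = FALSE)
    code
  })
}

#' Classify monthly climatologies into Koppen-Geiger classes
#'
#' Assigns exactly one of the 30 classes. The arid class B takes precedence
#' (`MAP < 10 * P_threshold`); the remaining cells are polar E when the
#' warmest month is at most 10 degrees C, tropical A when the coldest month is
#' at least 18 degrees C, temperate C when the coldest month lies strictly
#' between 0 and 18 degrees C, and cold D when it is at most 0 degrees C.
#' Within C and D the dry-summer (s) and dry-winter (w) sub-types are mutually
#' exclusive: when both seasonal criteria hold, s is assigned if more
#' precipitation falls in winter than in summer, w otherwise.
#'
#' `koppen_classify()` takes one climatology (two length-12 vectors) and
#' returns the class record; `koppen_codes()` is the vectorized form over
#' `n x 12` matrices and returns integer codes (0 where a row contains NA).
#'
#' @param temp monthly mean temperatures: length-12 vector, or `n x 12` matrix
#'   for `koppen_codes()`.
#' @param precip monthly precipitation totals (mm/month), same shape.
#' @return `koppen_classify()`: a list with `code`, `symbol`, `major` and
#'   `color` (RGB); `koppen_codes()`: an integer vector of codes.
#' @examples
#' koppen_classify(rep(25, 12), rep(200, 12))$symbol  # "Af"
#' koppen_classify(rep(25, 12), rep(0, 12))$symbol    # "BWh"
#' @export
koppen_classify <- function(temp, precip) {
  validate_monthly(temp, "temperature")
  validate_monthly(precip, "precipitation")
  if (any(precip < 0)) stop("invalid climatology: negative precipitation")
  code <- codes_from_matrices(matrix(temp, 1), matrix(precip, 1))
  leg <- koppen_legend()
  row <- leg[leg$code == code, ]
  list(code = code, symbol = row$symbol, major = row$major,
       color = c(row$r, row$g, row$b))
}

#' @rdname koppen_classify
#' @export
koppen_codes <- function(temp, precip) {
  codes_from_matrices(temp, precip)
}

#' Categorical class grid
#'
#' A grid of Koppen-Geiger class codes: integers 1-30, with 0 marking nodata
#' (ocean / unclassified), matching the unsigned 8-bit storage convention of
#' the published maps.
#'
#' @param codes integer matrix of codes in 0-30 (NA is coerced to 0).
#' @param spec the [kg_grid()] the codes live on.
#' @return an object of class `kg_class_grid`.
#' @export
kg_class_grid <- function(codes, spec) {
  stopifnot(is.matrix(codes))
  if (nrow(codes) != spec$rows || ncol(codes) != spec$cols)
    stop("codes matrix does not match the grid spec")
  codes[is.na(codes)] <- 0L
  storage.mode(codes) <- "integer"
  if (any(codes < 0L | codes > 30L))
    stop("class codes must lie in 0-30 (0 = nodata)")
  structure(list(codes = codes, spec = spec), class = "kg_class_grid")
}

#' @export
print.kg_class_grid <- function(x, ...) {
  n_valid <- sum(x$codes > 0L)
  cat(sprintf("<kg_class_grid> %d x %d; %d classified cells, %d classes present\n",
              x$spec$rows, x$spec$cols, n_valid,
              length(setdiff(unique(as.vector(x$codes)), 0L))))
  invisible(x)
}

#' Confidence grid
#'
#' Per-cell ensemble confidence levels in percent: the share of ensemble
#' members voting for the modal class. Unmasked values lie in (0, 100];
#' NA marks nodata.
#'
#' @param values numeric matrix of percentages.
#' @param spec the [kg_grid()].
#' @return an object of class `kg_conf_grid`.
#' @export
kg_conf_grid <- function(values, spec) {
  stopifnot(is.matrix(values))
  if (nrow(values) != spec$rows || ncol(values) != spec$cols)
    stop("confidence matrix does not match the grid spec")
  if (any(values <= 0 | values > 100, na.rm = TRUE))
    stop("confidence values must lie in (0, 100]")
  structure(list(values = values, spec = spec), class = "kg_conf_grid")
}

#' Classify a pair of climatology stacks cell-wise
#'
#' @param temp a `"temp"` [kg_stack()].
#' @param precip a `"precip"` [kg_stack()] on the same grid.
#' @return a [kg_class_grid()]; cells with nodata in any month are 0.
#' @export
classify_stack <- function(temp, precip) {
  stopifnot(inherits(temp, "kg_stack"), inherits(precip, "kg_stack"))
  if (stack_var(temp) != "temp" || stack_var(precip) != "precip")
    stop("classify_stack() needs a temperature stack and a precipitation stack")
  spec <- stack_spec(temp)
  check_same_grid(spec, stack_spec(precip), "climatology stacks")
  n <- spec$rows * spec$cols
  tm <- matrix(as.vector(temp), n, 12)
  pm <- matrix(as.vector(precip), n, 12)
  codes <- codes_from_matrices(tm, pm)
  kg_class_grid(matrix(codes, spec$rows, spec$cols), spec)
}

#' Display form of a confidence level
#'
#' Truncates (not rounds) to one decimal, so that 8 of 12 votes prints as
#' 66.6 rather than 66.7, matching the convention used for reporting
#' ensemble confidence.
#'
#' @param x confidence percentages.
#' @return numeric values truncated to one decimal place.
#' @examples
#' format_confidence(100 * 8 / 12)   # 66.6
#' format_confidence(100 * 24 / 32)  # 75.0
#' @export
format_confidence <- function(x) floor(x * 10) / 10
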