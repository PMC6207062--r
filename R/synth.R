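# Synthetic planet generator. The world is built from smooth analytic
# temperature and precipitation fields chosen so that the full latitudinal
# ladder of climates appears (tropical -> arid -> temperate -> cold -> polar)
# and longitude supplies a maritime/continental contrast plus wet/dry arid
# sectors. It is deliberately a caricature: no topography unless an
# elevation field is supplied, no weather, no interannual variability beyond
# the prescribed drift and noise.

#' Recipe for a synthetic world
#'
#' Parameters of the analytic temperature and precipitation models.
#' Temperature: an equator-to-pole decline of the annual mean, a seasonal
#' amplitude that grows toward mid/high latitudes and is modulated by a
#' longitudinal continentality factor (with a hemisphere phase flip: the warm
#' month is July north of the equator, January south of it), and an optional
#' elevation field cooled at a fixed lapse rate. Precipitation: zonal bands
#' with prescribed seasonality regimes (uniform equatorial, summer-dominant
#' tropical, arid with a longitudinal wet/dry cycle, winter-dominant
#' Mediterranean, uniform temperate, summer-dominant subpolar, uniform
#' polar). Noise, when enabled, is additive white for temperature and
#' multiplicative lognormal for precipitation.
#'
#' @param spec grid to generate on (default the 0.5 degree global grid).
#' @param t_eq annual-mean temperature at the equator (degrees C).
#' @param t_drop equator-to-pole drop of the annual mean (degrees C).
#' @param t_exp exponent of the latitudinal decline.
#' @param amp_max maximum seasonal amplitude scale (degrees C).
#' @param cont_range amplitude of the continentality modulation (fraction).
#' @param cont_cool annual-mean cooling of continental high latitudes
#'   (degrees C at the pole for fully continental cells).
#' @param elevation optional matrix (km) on `spec`; cells are cooled by
#'   `lapse_rate * elevation`.
#' @param lapse_rate temperature lapse rate (degrees C per km).
#' @param temp_noise_sd additive temperature noise SD (degrees C; 0 = none).
#' @param precip_noise_sdlog lognormal sdlog of multiplicative precipitation
#'   noise (0 = none).
#' @param seed integer seed for the noise.
#' @return a list of class `kg_world_recipe`.
#' @export
world_recipe <- function(spec = kg_grid(360, 720, 1/2),
                         t_eq = 28, t_drop = 44, t_exp = 1.5,
                         amp_max = 26, cont_range = 0.45, cont_cool = 24,
                         elevation = NULL, lapse_rate = 6.5,
                         temp_noise_sd = 0, precip_noise_sdlog = 0,
                         seed = 1L) {
  stopifnot(is_kg_grid(spec), is.finite(t_eq), is.finite(t_drop),
            is.finite(amp_max), temp_noise_sd >= 0, precip_noise_sdlog >= 0)
  if (!is.null(elevation))
    stopifnot(is.matrix(elevation), nrow(elevation) == spec$rows,
              ncol(elevation) == spec$cols)
  structure(list(spec = spec, t_eq = t_eq, t_drop = t_drop, t_exp = t_exp,
                 amp_max = amp_max, cont_range = cont_range,
                 cont_cool = cont_cool, elevation = elevation,
                 lapse_rate = lapse_rate, temp_noise_sd = temp_noise_sd,
                 precip_noise_sdlog = precip_noise_sdlog,
                 seed = as.integer(seed)),
            class = "kg_world_recipe")
}

# seasonal weight: 1 at the peak month, 0 six months away
halfcos <- function(month, peak) 0.5 * (1 + cos(2 * pi * (month - peak) / 12))

# precipitation band parameters by absolute latitude
precip_band <- function(abslat) {
  if (abslat < 12)      list(regime = "uniform", wet = 180, dry = 180)
  else if (abslat < 25) list(regime = "summer", wet = 400 - 20 * (abslat - 12), dry = 8)
  else if (abslat < 37) list(regime = "arid",   wet = 38, dry = 6)
  else if (abslat < 48) list(regime = "winter", wet = 90, dry = 5)
  else if (abslat < 62) list(regime = "uniform", wet = 75, dry = 75)
  else if (abslat < 75) list(regime = "summer", wet = 65, dry = 6)
  else                  list(regime = "uniform", wet = 30, dry = 30)
}

# noise-free analytic fields
world_fields <- function(recipe) {
  spec <- recipe$spec
  lat <- grid_lats(spec); lon <- grid_lons(spec)
  al <- abs(lat)

  tbar <- recipe$t_eq - recipe$t_drop * (al / 90)^recipe$t_exp
  # seasonal amplitude envelope: small in the tropics, peaking near 65 deg,
  # declining toward the poles
  g <- ifelse(al <= 65, (pmax(al - 10, 0) / 55)^2, 1 - 0.8 * (al - 65) / 25)
  cont_raw <- 0.5 - 0.5 * cos(2 * pi * (lon + 180) / 360)    # 1 = mid-continent
  taper <- pmin(al / 30, 1)
  cmod <- 1 + outer(taper, 2 * cont_raw - 1) * recipe$cont_range
  amp <- (1 + recipe$amp_max * g) * cmod
  tbar_eff <- matrix(tbar, spec$rows, spec$cols) -
    recipe$cont_cool * pmax(cmod - 1, 0) * (al / 90)^2
  if (!is.null(recipe$elevation))
    tbar_eff <- tbar_eff - recipe$lapse_rate * recipe$elevation

  peak_t <- ifelse(lat >= 0, 7, 1)    # warm month: July NH, January SH
  temp <- array(NA_real_, c(spec$rows, spec$cols, 12))
  for (m in 1:12)
    temp[, , m] <- tbar_eff + amp * halfcos(m, peak_t) * 2 - amp
  # halfcos in [0,1]; 2*halfcos-1 in [-1,1] gives the cosine seasonal cycle

  wet_arid <- 0.5 - 0.5 * cos(2 * 2 * pi * (lon + 180) / 360)  # two wet/dry cycles
  precip <- array(NA_real_, c(spec$rows, spec$cols, 12))
  for (r in seq_len(spec$rows)) {
    band <- precip_band(al[r])
    if (band$regime == "arid") {
      level <- band$dry + (band$wet - band$dry) * wet_arid
      for (m in 1:12) precip[r, , m] <- level
    } else if (band$regime == "uniform") {
      for (m in 1:12) precip[r, , m] <- band$wet
    } else {
      peak <- if (band$regime == "summer") peak_t[r] else (peak_t[r] + 6 - 1) %% 12 + 1
      for (m in 1:12)
        precip[r, , m] <- band$dry + (band$wet - band$dry) * halfcos(m, peak)
    }
  }
  list(temp = temp, precip = precip)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a synthetic world
#'
#' Returns monthly temperature and precipitation climatology stacks built
#' from the recipe's analytic fields (plus noise if configured), together
#' with the ground-truth classification computed from the noise-free fields.
#' Identical recipes (including seed) give bit-identical output.
#'
#' @param recipe a [world_recipe()].
#' @return a list with `temp` and `precip` ([kg_stack()]s), `truth`
#'   (a [kg_class_grid()]) and the noise-free `temp_clean` / `precip_clean`
#'   stacks.
#' @export
synth_world <- function(recipe = world_recipe()) {
  stopifnot(inherits(recipe, "kg_world_recipe"))
  spec <- recipe$spec
  if (spec$rows < 2 || spec$cols < 2) stop("degenerate grid: need at least 2 x 2")
  f <- world_fields(recipe)
  temp <- f$temp; precip <- f$precip
  if (recipe$temp_noise_sd > 0 || recipe$precip_noise_sdlog > 0) {
    with_seed(recipe$seed, {
      if (recipe$temp_noise_sd > 0)
        temp <- temp + array(stats::rnorm(length(temp), 0, recipe$temp_noise_sd),
                             dim(temp))
      if (recipe$precip_noise_sdlog > 0)
        precip <- precip * array(stats::rlnorm(length(precip), 0,
                                               recipe$precip_noise_sdlog),
                                 dim(precip))
    })
  }
  truth_t <- kg_stack(f$temp, spec, "temp")
  truth_p <- kg_stack(f$precip, spec, "precip")
  list(temp = kg_stack(temp, spec, "temp"),
       precip = kg_stack(precip, spec, "precip"),
       truth = classify_stack(truth_t, truth_p),
       temp_clean = truth_t, precip_clean = truth_p)
}

# aggregate a fine stack to a nested coarser grid by block means
aggregate_stack <- function(stack, coarse) {
  spec <- stack_spec(stack)
  fac <- coarse$cell_size / spec$cell_size
  if (abs(fac - round(fac)) > 1e-9)
    stop("coarse cell size must be an integer multiple of the world's")
  fac <- as.integer(round(fac))
  out <- array(NA_real_, c(coarse$rows, coarse$cols, 12))
  for (m in 1:12) out[, , m] <- block_aggregate(unclass(stack)[, , m], fac)
  kg_stack(out, coarse, stack_var(stack))
}

#' Synthetic coarse time-varying series
#'
#' Emulates a coarse-resolution observational time series: the world's
#' noise-free climatology aggregated to a coarse grid, plus a linear trend
#' and optional year-to-year noise. The trend is anchored at the first year
#' of the period: temperature drifts by `drift` degrees C per decade,
#' precipitation by a fractional `drift` per decade (multiplicative).
#'
#' @param world a [synth_world()] result.
#' @param var `"temp"` or `"precip"`.
#' @param period inclusive year range to generate.
#' @param coarse target [kg_grid()] (default 2 degrees, nested in the world).
#' @param drift per-decade trend (degrees C for temperature; fraction for
#'   precipitation).
#' @param noise_sd additive SD (temperature) or lognormal sdlog
#'   (precipitation) of interannual noise; 0 disables it.
#' @param seed integer seed.
#' @return a [kg_series()].
#' @export
synth_coarse_series <- function(world, var = c("temp", "precip"),
                                period = c(1980, 2016),
                                coarse = kg_grid(90, 180, 2),
                                drift = 0, noise_sd = 0, seed = 1L) {
  var <- match.arg(var)
  stopifnot(is.finite(drift))
  base <- aggregate_stack(world[[paste0(var, "_clean")]], coarse)
  years <- period[1]:period[2]
  nele <- coarse$rows * coarse$cols * 12L
  dy <- (years - period[1]) / 10
  data <- rep(as.vector(unclass(base)), length(years))
  if (drift != 0) {
    data <- if (var == "temp") data + rep(drift * dy, each = nele)
            else pmax(data * rep(1 + drift * dy, each = nele), 0)
  }
  if (noise_sd > 0) {
    with_seed(seed, {
      data <- if (var == "temp") data + stats::rnorm(length(data), 0, noise_sd)
              else data * stats::rlnorm(length(data), 0, noise_sd)
    })
  }
  dim(data) <- c(coarse$rows, coarse$cols, 12L, length(years))
  kg_series(data, years, coarse, var)
}

#' Synthetic climate-model historical/future pair
#'
#' Emulates one climate model: coarse historical series equal to the
#' aggregated world (plus noise), and a future series shifted by a uniform
#' `warming` (temperature, degrees C) and scaled by `precip_scale`
#' (precipitation), plus noise. Feeding such pairs to [future_ensemble()]
#' should recover the injected warming and scaling through the anomaly
#' method.
#'
#' @param world a [synth_world()] result.
#' @param warming future-minus-historical temperature change (degrees C).
#' @param precip_scale future/historical precipitation ratio (> 0).
#' @param hist_period,fut_period inclusive year ranges.
#' @param coarse model grid (default 2 degrees).
#' @param noise_sd interannual noise (see [synth_coarse_series()]).
#' @param seed integer seed.
#' @param label model name.
#' @return a list with `label`, `hist_temp`, `hist_precip`, `fut_temp`,
#'   `fut_precip`, ready for [future_ensemble()].
#' @export
synth_model_pair <- function(world, warming = 0, precip_scale = 1,
                             hist_period = c(1980, 2016),
                             fut_period = c(2071, 2100),
                             coarse = kg_grid(90, 180, 2),
                             noise_sd = 0, seed = 1L, label = "model") {
  stopifnot(precip_scale > 0)
  ht <- synth_coarse_series(world, "temp", hist_period, coarse,
                            noise_sd = noise_sd, seed = seed)
  hp <- synth_coarse_series(world, "precip", hist_period, coarse,
                            noise_sd = noise_sd, seed = seed + 1L)
  ft <- synth_coarse_series(world, "temp", fut_period, coarse,
                            noise_sd = noise_sd, seed = seed + 2L)
  fp <- synth_coarse_series(world, "precip", fut_period, coarse,
                            noise_sd = noise_sd, seed = seed + 3L)
  ft$data <- ft$data + warming
  fp$data <- fp$data * precip_scale
  list(label = label, hist_temp = ht, hist_precip = hp,
       fut_temp = ft, fut_precip = fp)
}

#' Synthetic daily station records
#'
#' Samples station locations from the world's grid and generates daily
#' temperature and precipitation series from the cell's noise-free
#' climatology, with optional day-to-day noise, randomly missing days, and
#' optionally a set of stations engineered to fail the completeness rules
#' (every January capped at 24 daily values, so the 25-day rule discards all
#' Januaries and the 10-year rule then rejects the station).
#'
#' @param world a [synth_world()] result.
#' @param n number of stations.
#' @param years inclusive year range of the records.
#' @param gap_fraction probability that any given day is missing (both
#'   variables), in `[0, 1)`.
#' @param noise_t daily temperature noise SD (degrees C).
#' @param noise_p lognormal sdlog of daily precipitation noise.
#' @param n_bad number of additional stations engineered to fail QC.
#' @param seed integer seed.
#' @return a data.frame of daily records (columns `id`, `lat`, `lon`,
#'   `date`, `tavg`, `prcp`).
#' @export
synth_stations <- function(world, n = 50, years = c(2001, 2012),
                           gap_fraction = 0, noise_t = 0, noise_p = 0,
                           n_bad = 0, seed = 1L) {
  stopifnot(n >= 1, gap_fraction >= 0, gap_fraction < 1)
  spec <- stack_spec(world$temp_clean)
  tmat <- matrix(unclass(world$temp_clean), spec$rows * spec$cols, 12)
  pmat <- matrix(unclass(world$precip_clean), spec$rows * spec$cols, 12)
  yy <- years[1]:years[2]
  with_seed(seed, {
    total <- n + n_bad
    cells <- sample.int(spec$rows * spec$cols, total, replace = TRUE)
    row <- (cells - 1L) %% spec$rows + 1L
    col <- (cells - 1L) %/% spec$rows + 1L
    lat <- grid_lats(spec)[row] + stats::runif(total, -0.49, 0.49) * spec$cell_size
    lon <- grid_lons(spec)[col] + stats::runif(total, -0.49, 0.49) * spec$cell_size
    out <- vector("list", total)
    for (s in seq_len(total)) {
      recs <- list()
      for (y in yy) for (m in 1:12) {
        nd <- days_in_month(y, m)
        keep <- rep(TRUE, nd)
        if (gap_fraction > 0) keep <- stats::runif(nd) >= gap_fraction
        if (s > n && m == 1) keep[seq_len(nd)] <- c(rep(TRUE, 24), rep(FALSE, nd - 24))
        days <- which(keep)
        if (!length(days)) next
        tv <- rep(tmat[cells[s], m], length(days))
        pv <- rep(pmat[cells[s], m] / nd, length(days))
        if (noise_t > 0) tv <- tv + stats::rnorm(length(days), 0, noise_t)
        if (noise_p > 0) pv <- pv * stats::rlnorm(length(days), 0, noise_p)
        recs[[length(recs) + 1L]] <- data.frame(
          date = as.Date(sprintf("%04d-%02d-%02d", y, m, days)),
          tavg = tv, prcp = pv)
      }
      rec <- do.call(rbind, recs)
      rec$id <- sprintf("SYN%05d", s)
      rec$lat <- lat[s]; rec$lon <- lon[s]
      out[[s]] <- rec[, c("id", "lat", "lon", "date", "tavg", "prcp")]
    }
    do.call(rbind, out)
  })
}
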