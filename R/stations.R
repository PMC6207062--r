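# Station records are plain data.frames in a GHCN-D-like dialect:
# columns id, lat, lon, date (Date or "YYYY-MM-DD"), tavg (degrees C),
# prcp (mm/day), optional source. One row per station-day.

days_in_month <- function(year, month) {
  dm <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  dm + ifelse(month == 2 & leap, 1L, 0L)
}

#' Monthly means and totals from daily station records
#'
#' Aggregates one station's daily series to (year, month) values, discarding
#' months with fewer than 25 daily values (per variable). Temperature is
#' aggregated by the mean; precipitation by the mean daily amount scaled by
#' the number of days in the month, so months with 25-30 present days are
#' handled consistently.
#'
#' @param daily data.frame with columns `date`, `tavg`, `prcp` for one
#'   station.
#' @param min_days minimum daily values required to keep a month (25).
#' @return a data.frame with columns `year`, `month`, `tavg`, `prcp`,
#'   `n_tavg`, `n_prcp`; a variable failing the rule in a month is NA there.
#' @export
monthly_means <- function(daily, min_days = 25) {
  stopifnot(all(c("date", "tavg", "prcp") %in% names(daily)))
  date <- as.Date(daily$date)
  year <- as.integer(format(date, "%Y"))
  month <- as.integer(format(date, "%m"))
  key <- factor(sprintf("%04d-%02d", year, month))   # levels sort chronologically
  agg <- function(x) {
    n <- as.integer(tapply(!is.na(x), key, sum))
    m <- as.numeric(tapply(x, key, mean, na.rm = TRUE))
    m[n < min_days] <- NA_real_
    list(n = n, mean = m)
  }
  t_agg <- agg(daily$tavg)
  p_agg <- agg(daily$prcp)
  yy <- as.integer(substr(levels(key), 1, 4))
  mm <- as.integer(substr(levels(key), 6, 7))
  data.frame(year = yy, month = mm,
             tavg = t_agg$mean,
             prcp = p_agg$mean * days_in_month(yy, mm),
             n_tavg = t_agg$n, n_prcp = p_agg$n)
}

#' Station monthly climatology with completeness quality control
#'
#' Builds the 12-month climatology by averaging the monthly values over
#' years, requiring at least `min_years` yearly values for every calendar
#' month of both variables. A station failing the rule for any month is
#' rejected (a reported outcome, not an error).
#'
#' @param monthly data.frame as produced by [monthly_means()] (or monthly
#'   observations directly, with `year`, `month`, `tavg`, `prcp`).
#' @param min_years minimum yearly values per calendar month (10).
#' @return a list: `accepted` (logical); when accepted, `temp` and `precip`
#'   (length-12 climatologies) and `n_years_temp` / `n_years_precip`
#'   (contributing-year counts); when rejected, `reason`.
#' @export
station_climatology <- function(monthly, min_years = 10) {
  stopifnot(all(c("year", "month", "tavg", "prcp") %in% names(monthly)))
  mo <- factor(monthly$month, levels = 1:12)
  nt <- as.integer(tapply(!is.na(monthly$tavg), mo, sum, default = 0L))
  np <- as.integer(tapply(!is.na(monthly$prcp), mo, sum, default = 0L))
  nt[is.na(nt)] <- 0L; np[is.na(np)] <- 0L
  if (any(nt < min_years) || any(np < min_years)) {
    bad_t <- which(nt < min_years); bad_p <- which(np < min_years)
    return(list(accepted = FALSE,
                reason = sprintf("gap in climatology (months with <%d years: T %s; P %s)",
                                 min_years,
                                 paste(bad_t, collapse = ","),
                                 paste(bad_p, collapse = ","))))
  }
  list(accepted = TRUE,
       temp = as.numeric(tapply(monthly$tavg, mo, mean, na.rm = TRUE)),
       precip = as.numeric(tapply(monthly$prcp, mo, mean, na.rm = TRUE)),
       n_years_temp = nt, n_years_precip = np)
}

#' Build quality-controlled climatologies for a station panel
#'
#' Applies [monthly_means()] and [station_climatology()] per station.
#' Duplicate station ids keep the first occurrence.
#'
#' @param daily data.frame of daily records with columns `id`, `lat`, `lon`,
#'   `date`, `tavg`, `prcp`.
#' @param min_days,min_years the completeness rules.
#' @return a list with `stations` (list of accepted climatologies, each with
#'   `id`, `lat`, `lon`, `temp`, `precip`) and `rejected` (data.frame of
#'   `id`, `reason`).
#' @export
build_station_climatologies <- function(daily, min_days = 25, min_years = 10) {
  stopifnot(all(c("id", "lat", "lon", "date", "tavg", "prcp") %in% names(daily)))
  ids <- unique(daily$id)
  accepted <- list(); rej_id <- character(); rej_reason <- character()
  for (sid in ids) {
    sub <- daily[daily$id == sid, ]
    mon <- monthly_means(sub, min_days = min_days)
    clim <- station_climatology(mon, min_years = min_years)
    if (clim$accepted) {
      accepted[[length(accepted) + 1L]] <- list(
        id = sid, lat = sub$lat[1], lon = sub$lon[1],
        temp = clim$temp, precip = clim$precip)
    } else {
      rej_id <- c(rej_id, sid); rej_reason <- c(rej_reason, clim$reason)
    }
  }
  list(stations = accepted,
       rejected = data.frame(id = rej_id, reason = rej_reason,
                             stringsAsFactors = FALSE))
}

# classify stations and look up map values at their cells
evaluate_stations <- function(map, stations) {
  stopifnot(inherits(map, "kg_class_grid"), length(stations) >= 1)
  lat <- vapply(stations, `[[`, numeric(1), "lat")
  lon <- vapply(stations, `[[`, numeric(1), "lon")
  id  <- vapply(stations, `[[`, character(1), "id")
  tm <- do.call(rbind, lapply(stations, `[[`, "temp"))
  pm <- do.call(rbind, lapply(stations, `[[`, "precip"))
  ref <- codes_from_matrices(tm, pm)
  loc <- grid_locate(map$spec, lat, lon)
  pred <- rep(NA_integer_, length(stations))
  inside <- !is.na(loc$row)
  pred[inside] <- map$codes[cbind(loc$row[inside], loc$col[inside])]
  status <- rep("evaluated", length(stations))
  status[!inside] <- "outside extent"
  status[inside & pred == 0L] <- "map nodata"
  data.frame(id = id, lat = lat, lon = lon,
             row = loc$row, col = loc$col,
             ref_code = ref, ref_symbol = koppen_symbol(ref),
             map_code = pred, map_symbol = koppen_symbol(pred),
             status = status,
             correct = status == "evaluated" & ref == pred,
             stringsAsFactors = FALSE)
}

#' Classification accuracy against station observations
#'
#' Each station's quality-controlled climatology is classified to give the
#' reference class; the prediction is the map value of the grid cell
#' containing the station coordinate (no interpolation — the data are
#' categorical). Accuracy is the percentage of evaluated stations whose map
#' class matches the reference. Stations outside the map extent or on nodata
#' cells are excluded from the denominator and counted.
#'
#' @param map a [kg_class_grid()].
#' @param stations list of station climatologies (see
#'   [build_station_climatologies()]).
#' @return a list with `accuracy` (percent), `n_evaluated`, `n_excluded` and
#'   the per-station data.frame `table`.
#' @export
classification_accuracy <- function(map, stations) {
  tab <- evaluate_stations(map, stations)
  ev <- tab$status == "evaluated"
  if (!any(ev)) stop("no evaluable stations: all outside the map or on nodata cells")
  list(accuracy = 100 * sum(tab$correct[ev]) / sum(ev),
       n_evaluated = sum(ev), n_excluded = sum(!ev), table = tab)
}

#' Mean confidence split by classification correctness
#'
#' Partitions evaluated stations into correctly and incorrectly classified
#' groups and reports the mean map confidence of each, a check that the
#' confidence map tracks actual accuracy. An empty group yields NA for that
#' mean, not an error.
#'
#' @param map a [kg_class_grid()].
#' @param conf the aligned [kg_conf_grid()].
#' @param stations list of station climatologies.
#' @return a list with `mean_conf_correct`, `mean_conf_wrong`, `n_correct`,
#'   `n_wrong` and the per-station `table` (with a `confidence` column).
#' @export
confidence_split <- function(map, conf, stations) {
  stopifnot(inherits(conf, "kg_conf_grid"))
  check_same_grid(map$spec, conf$spec, "class and confidence grids")
  tab <- evaluate_stations(map, stations)
  ev <- tab$status == "evaluated"
  tab$confidence <- NA_real_
  tab$confidence[ev] <- conf$values[cbind(tab$row[ev], tab$col[ev])]
  ok <- ev & tab$correct
  ko <- ev & !tab$correct
  list(mean_conf_correct = if (any(ok)) mean(tab$confidence[ok]) else NA_real_,
       mean_conf_wrong   = if (any(ko)) mean(tab$confidence[ko]) else NA_real_,
       n_correct = sum(ok), n_wrong = sum(ko), table = tab)
}

#' Read and write station daily records as CSV
#'
#' The dialect is GHCN-D-like: columns `id`, `lat`, `lon`, `date`
#' (YYYY-MM-DD), `tavg` (degrees C), `prcp` (mm/day); missing observations
#' are empty fields.
#'
#' @param path CSV file path.
#' @param daily data.frame of daily records.
#' @return `read_stations()`: the data.frame; `write_stations()`: the path,
#'   invisibly.
#' @export
read_stations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "lat", "lon", "date", "tavg", "prcp")
  if (!all(need %in% names(df)))
    stop("station file must have columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0) stop("station file is empty")
  df$id <- as.character(df$id)
  df
}

#' @rdname read_stations
#' @export
write_stations <- function(daily, path) {
  utils::write.csv(daily, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
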