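# one synthetic station's worth of daily data, built directly
daily_frame <- function(years, temp_by_month, prcp_daily_by_month,
                        drop_days = list()) {
  rows <- list()
  for (y in years) for (m in 1:12) {
    nd <- koppenmap:::days_in_month(y, m)
    days <- seq_len(nd)
    key <- sprintf("%d-%d", y, m)
    if (!is.null(drop_days[[key]])) days <- setdiff(days, drop_days[[key]])
    if (!length(days)) next
    rows[[length(rows) + 1L]] <- data.frame(
      date = as.Date(sprintf("%04d-%02d-%02d", y, m, days)),
      tavg = temp_by_month[m], prcp = prcp_daily_by_month[m])
  }
  do.call(rbind, rows)
}

test_that("months need 25 daily values; totals scale by days in month", {
  tm <- rep(10, 12); pm <- rep(2, 12)   # 2 mm/day
  # drop 8 days from January (31 -> 23 days), 6 from March (31 -> 25)
  df <- daily_frame(2000, tm, pm,
                    drop_days = list("2000-1" = 1:8, "2000-3" = 1:6))
  mon <- monthly_means(df)
  jan <- mon[mon$month == 1, ]
  expect_equal(jan$n_tavg, 23)
  expect_true(is.na(jan$tavg) && is.na(jan$prcp))      # < 25 days: discarded
  mar <- mon[mon$month == 3, ]
  expect_equal(mar$n_tavg, 25)
  expect_equal(mar$tavg, 10)                           # 25 days: retained
  expect_equal(mar$prcp, 2 * 31)                       # mean daily x days in month
  # a complete 31-day month of constant 10 degC
  may <- mon[mon$month == 5, ]
  expect_equal(may$tavg, 10)
  expect_equal(may$prcp, 62)
  # February of a leap year scales by 29 days
  feb <- mon[mon$month == 2, ]
  expect_equal(feb$prcp, 2 * 29)
})

test_that("a month with 24 daily values is discarded, 25 retained (boundary)", {
  tm <- rep(5, 12); pm <- rep(1, 12)
  df24 <- daily_frame(2001, tm, pm, drop_days = list("2001-1" = 1:7))  # 24 left
  expect_true(is.na(monthly_means(df24)[1, "tavg"]))
  df25 <- daily_frame(2001, tm, pm, drop_days = list("2001-1" = 1:6))  # 25 left
  expect_equal(monthly_means(df25)[1, "tavg"], 5)
})

test_that("station climatologies require 10 years per calendar month", {
  tm <- 1:12; pm <- rep(1, 12)
  # exactly 10 complete years -> accepted, climatology equals the constants
  df <- do.call(rbind, lapply(2001:2010, function(y) daily_frame(y, tm, pm)))
  mon <- monthly_means(df)
  clim <- station_climatology(mon)
  expect_true(clim$accepted)
  expect_equal(clim$temp, as.numeric(1:12))
  expected_precip <- vapply(1:12, function(m)
    mean(pm[m] * koppenmap:::days_in_month(2001:2010, m)), numeric(1))
  expect_equal(clim$precip, expected_precip)
  expect_equal(clim$n_years_temp, rep(10L, 12))

  # one calendar month with only 9 years -> rejected with a reason
  drop <- lapply(setNames(list(1:31), "2010-1"), identity)
  df9 <- rbind(do.call(rbind, lapply(2001:2009, function(y) daily_frame(y, tm, pm))),
               daily_frame(2010, tm, pm, drop_days = drop))
  clim9 <- station_climatology(monthly_means(df9))
  expect_false(clim9$accepted)
  expect_match(clim9$reason, "gap")

  # 30 years of constant values reproduce the constants
  df30 <- do.call(rbind, lapply(1981:2010, function(y) daily_frame(y, tm, pm)))
  clim30 <- station_climatology(monthly_means(df30))
  expect_true(clim30$accepted)
  expect_equal(clim30$temp, as.numeric(1:12))
})

test_that("accuracy is the percentage of matching evaluated stations", {
  spec <- kg_grid(4, 4, 10, xmin = 0, ymax = 40)
  codes <- matrix(1L, 4, 4); codes[1, ] <- 29L; codes[4, 4] <- 0L
  map <- kg_class_grid(codes, spec)
  st <- function(id, lat, lon, temp, precip)
    list(id = id, lat = lat, lon = lon, temp = temp, precip = precip)
  af <- list(temp = rep(25, 12), precip = rep(200, 12))   # classifies Af (1)
  et <- list(temp = rep(5, 12), precip = rep(50, 12))     # classifies ET (29)
  stations <- list(
    st("s1", 25, 5, af$temp, af$precip),    # row 2 -> map 1, correct
    st("s2", 15, 15, af$temp, af$precip),   # row 3 -> map 1, correct
    st("s3", 35, 25, af$temp, af$precip),   # row 1 -> map 29, wrong
    st("s4", 38, 33, et$temp, et$precip),   # row 1 -> map 29, correct
    st("s5", 5, 35, af$temp, af$precip),    # row 4 col 4 -> nodata, excluded
    st("s6", 75, 5, af$temp, af$precip))    # outside extent, excluded
  res <- classification_accuracy(map, stations)
  expect_equal(res$n_evaluated, 4)
  expect_equal(res$n_excluded, 2)
  expect_equal(res$accuracy, 75)
  expect_setequal(res$table$status[5:6], c("map nodata", "outside extent"))
  # permutation invariance
  res2 <- classification_accuracy(map, stations[c(3, 6, 1, 5, 2, 4)])
  expect_equal(res2$accuracy, res$accuracy)
  # all stations on nodata -> error
  allnd <- kg_class_grid(matrix(0L, 4, 4), spec)
  expect_error(classification_accuracy(allnd, stations[1:2]), "no evaluable")
})

test_that("stations on a cell edge fall in the cell to the south-east", {
  spec <- kg_grid(2, 2, 10, xmin = 0, ymax = 20)
  loc <- grid_locate(spec, lat = 10, lon = 10)   # interior corner
  expect_equal(loc$row, 2L)   # south of the lat-10 edge
  expect_equal(loc$col, 2L)   # east of the lon-10 edge
  # outer south/east edges clamp into the last cell
  expect_equal(grid_locate(spec, 0, 20), list(row = 2L, col = 2L))
  expect_equal(grid_locate(spec, 25, 5)$row, NA_integer_)
})

test_that("mean confidence splits by correctness", {
  spec <- kg_grid(2, 2, 10, xmin = 0, ymax = 20)
  map <- kg_class_grid(matrix(1L, 2, 2), spec)
  conf <- kg_conf_grid(matrix(c(80, 70, 60, 90), 2, 2), spec)
  af <- list(temp = rep(25, 12), precip = rep(200, 12))
  et <- list(temp = rep(5, 12), precip = rep(50, 12))
  stations <- list(
    list(id = "a", lat = 15, lon = 2, temp = af$temp, precip = af$precip),  # (1,1) 80 correct
    list(id = "b", lat = 5, lon = 12, temp = et$temp, precip = et$precip))  # (2,2) 90 wrong
  s <- confidence_split(map, conf, stations)
  expect_equal(s$mean_conf_correct, 80)
  expect_equal(s$mean_conf_wrong, 90)
  expect_equal(c(s$n_correct, s$n_wrong), c(1, 1))
  # all correct -> wrong-group mean is undefined, not an error
  s2 <- confidence_split(map, conf, stations[1])
  expect_true(is.na(s2$mean_conf_wrong))
  expect_equal(s2$mean_conf_correct, 80)
})

test_that("station CSV round trip preserves records and rejects bad files", {
  df <- daily_frame(2000, rep(3, 12), rep(1, 12))
  df$id <- "X1"; df$lat <- 10.25; df$lon <- -3.75
  df <- df[, c("id", "lat", "lon", "date", "tavg", "prcp")]
  path <- tempfile(fileext = ".csv")
  write_stations(df, path)
  back <- read_stations(path)
  expect_equal(nrow(back), nrow(df))
  expect_equal(back$tavg, df$tavg)
  expect_equal(as.Date(back$date), df$date)
  bad <- tempfile(fileext = ".csv")
  writeLines("foo,bar\n1,2", bad)
  expect_error(read_stations(bad), "columns")
})
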