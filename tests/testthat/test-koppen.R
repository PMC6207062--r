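test_that("summer/winter split follows the warmer fixed half-year", {
  s <- season_split(med_temp)
  expect_true(s$apr_sep)
  expect_equal(sort(s$summer), 4:9)
  expect_equal(sort(c(s$summer, s$winter)), 1:12)

  # rotating the year by six months flips the split
  rot <- med_temp[c(7:12, 1:6)]
  expect_false(season_split(rot)$apr_sep)

  # exact tie defaults to April-September
  expect_true(season_split(rep(25, 12))$apr_sep)

  expect_error(season_split(c(med_temp[-12], NA)), "invalid")
})

test_that("aridity threshold branches on the 70% seasonality rule", {
  expect_equal(p_threshold(15.42, 0.758), 30.84)
  expect_equal(p_threshold(10, 0.2), 48)      # >70% falls in summer
  expect_equal(p_threshold(25, 0.5), 64)      # otherwise
  # boundaries are strict: exactly 70% takes the otherwise branch
  expect_equal(p_threshold(10, 0.7), 34)
  expect_equal(p_threshold(10, 0.3), 34)
  expect_equal(p_threshold(10, 0.7 + 1e-9), 20)
  # undefined winter fraction (no precipitation) takes the otherwise branch
  expect_equal(p_threshold(-10, NA), -6)
  expect_error(p_threshold(10, 1.2), "winter_frac")
})

test_that("climate indices match hand evaluation", {
  ind <- climate_indices(rep(25, 12), rep(100, 12))
  expect_equal(ind$MAT, 25)
  expect_equal(ind$MAP, 1200)
  expect_equal(ind$T_cold, 25)
  expect_equal(ind$T_hot, 25)
  expect_equal(ind$T_mon10, 12)
  expect_equal(ind$P_dry, 100)
  expect_equal(ind$winter_frac, 0.5)
  expect_equal(ind$P_threshold, 64)

  ind <- climate_indices(med_temp, med_precip)
  expect_equal(ind$MAP, 600)
  expect_equal(ind$winter_frac, 455 / 600)
  expect_equal(ind$P_sdry, 5)
  expect_equal(ind$P_wwet, 90)
  expect_equal(ind$P_threshold, 2 * mean(med_temp))

  ind <- climate_indices(med_temp, rep(0, 12))
  expect_equal(ind$MAP, 0)
  expect_true(is.na(ind$winter_frac))
  expect_equal(ind$P_threshold, 2 * mean(med_temp) + 14)

  # structural invariants
  expect_lte(ind$T_cold, ind$MAT); expect_lte(ind$MAT, ind$T_hot)
  expect_equal(climate_indices(med_temp, med_precip)$P_dry,
               min(climate_indices(med_temp, med_precip)$P_sdry,
                   climate_indices(med_temp, med_precip)$P_wdry))
})

test_that("hand-derived profiles classify to their expected classes", {
  expect_equal(koppen_classify(rep(25, 12), rep(200, 12))$symbol, "Af")
  expect_equal(koppen_classify(rep(25, 12), rep(0, 12))$symbol, "BWh")
  expect_equal(koppen_classify(dfb_temp, rep(50, 12))$symbol, "Dfb")
  expect_equal(koppen_classify(med_temp, med_precip)$symbol, "Csa")
  expect_equal(
    koppen_classify(c(-25, -22, -18, -10, -2, 3, 8, 6, 0, -8, -15, -22),
                    rep(20, 12))$symbol, "ET")
  cl <- koppen_classify(med_temp, med_precip)
  expect_equal(cl$major, "C")
  expect_equal(cl$code, 8L)
  expect_error(koppen_classify(med_temp, c(med_precip[-1], -5)), "negative")
})

test_that("class boundaries sit exactly where the criteria put them", {
  warm <- rep(25, 11); wet <- rep(200, 12)
  # tropical boundary: T_cold = 18 is tropical, just below is temperate
  expect_equal(koppen_classify(c(18, warm), wet)$major, "A")
  expect_equal(koppen_classify(c(18 - 1e-8, warm), wet)$major, "C")
  # C/D boundary at 0: exactly 0 is cold, just above temperate
  expect_equal(koppen_classify(c(0, rep(15, 11)), rep(100, 12))$major, "D")
  expect_equal(koppen_classify(c(1e-8, rep(15, 11)), rep(100, 12))$major, "C")
  # desert/steppe boundary: MAP = 5 x P_threshold is steppe
  t20 <- rep(20, 12)  # uniform: P_threshold = 54
  expect_equal(koppen_classify(t20, rep(270 / 12, 12))$symbol, "BSh")
  expect_equal(koppen_classify(t20, rep(269 / 12, 12))$symbol, "BWh")
  # arid boundary: MAP = 10 x P_threshold is not arid
  expect_equal(koppen_classify(t20, rep(540 / 12, 12))$major, "A")
  expect_equal(koppen_classify(t20, rep(539 / 12, 12))$major, "B")
  # BWh/BWk at MAT = 18
  expect_equal(koppen_classify(rep(18, 12), rep(0, 12))$symbol, "BWh")
  expect_equal(koppen_classify(rep(18 - 1e-8, 12), rep(0, 12))$symbol, "BWk")
  # polar boundary: T_hot = 10 is polar, tundra/frost split at T_hot = 0
  expect_equal(koppen_classify(rep(10, 12), rep(100, 12))$symbol, "ET")
  expect_equal(koppen_classify(rep(0, 12), rep(100, 12))$symbol, "EF")
  expect_equal(koppen_classify(rep(10 + 1e-8, 12), rep(100, 12))$major, "C")
  # monsoon boundary: P_dry exactly at 100 - MAP/25 is Am
  # (integer-valued so the equality is exact: MAP = 2300, P_dry = 8 = 100 - 92)
  pr <- c(292, rep(200, 10), 8)
  expect_identical(min(pr), 100 - sum(pr) / 25)
  expect_equal(koppen_classify(rep(25, 12), pr)$symbol, "Am")
  expect_equal(koppen_classify(rep(25, 12), pr - c(rep(0, 11), 1e-6))$symbol, "Aw")
  # hot-summer boundary at T_hot = 22 and warm-summer at T_mon10 = 4
  tc <- c(rep(5, 8), rep(22, 4))
  expect_equal(koppen_classify(tc, rep(100, 12))$symbol, "Cfa")
  expect_equal(koppen_classify(pmin(tc, 21.99), rep(100, 12))$symbol, "Cfb")
  tc3 <- c(rep(5, 9), rep(21, 3))
  expect_equal(koppen_classify(tc3, rep(100, 12))$symbol, "Cfc")
  # very-cold-winter boundary at T_cold = -38 (strict)
  td <- c(-38, rep(-20, 7), rep(15, 3), -30)
  expect_equal(koppen_classify(td, rep(60, 12))$symbol, "Dfc")
  expect_equal(koppen_classify(td - c(0.01, rep(0, 11)), rep(60, 12))$symbol, "Dfd")
})

test_that("classifier is total and matches the literal oracle on random inputs", {
  set.seed(421)
  n <- 4000
  cases <- c(replicate(n / 2, random_climatology(), simplify = FALSE),
             replicate(n / 2, random_seasonal_climatology(), simplify = FALSE))
  tm <- do.call(rbind, lapply(cases, `[[`, "temp"))
  pm <- do.call(rbind, lapply(cases, `[[`, "precip"))
  codes <- koppen_codes(tm, pm)
  expect_true(all(codes >= 1L & codes <= 30L))        # totality
  expected <- vapply(cases, function(cl) koppen_oracle(cl$temp, cl$precip),
                     character(1))
  expect_identical(koppen_symbol(codes), expected)    # oracle equivalence
})

test_that("the arid class takes precedence whenever its criterion holds", {
  set.seed(77)
  for (i in 1:500) {
    cl <- random_climatology()
    ind <- climate_indices(cl$temp, cl$precip)
    sym <- koppen_classify(cl$temp, cl$precip)$symbol
    if (ind$MAP < 10 * ind$P_threshold) {
      expect_equal(substr(sym, 1, 1), "B")
    } else {
      expect_false(substr(sym, 1, 1) == "B")
    }
  }
})

test_that("the legend is the fixed 30-class bijection", {
  leg <- koppen_legend()
  expect_equal(nrow(leg), 30)
  expect_equal(leg$code, 1:30)
  expect_equal(leg$symbol[1], "Af")
  expect_equal(leg$symbol[8], "Csa")
  expect_equal(leg$symbol[30], "EF")
  expect_equal(leg$major, substr(leg$symbol, 1, 1))
  expect_false(any(duplicated(leg$symbol)))
  # round trip symbol <-> code
  expect_equal(koppen_code(koppen_symbol(1:30)), 1:30)
  expect_true(all(leg$r %in% 0:255 & leg$g %in% 0:255 & leg$b %in% 0:255))
})

test_that("the packaged legend resource matches the in-code legend", {
  path <- system.file("extdata", "legend.txt", package = "koppenmap")
  expect_true(nzchar(path))
  tmp <- tempfile()
  write_legend(tmp)
  expect_identical(readLines(path), readLines(tmp))
  got <- read.table(path, col.names = c("code", "symbol", "r", "g", "b"))
  expect_equal(got$code, 1:30)
  expect_equal(got$symbol, koppen_legend()$symbol)
})
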