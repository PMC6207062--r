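spec4 <- kg_grid(4, 4, 1, xmin = 0, ymax = 50)

test_that("period climatology averages the in-period years per cell and month", {
  yrs <- 1980:1989
  s <- const_series(5, spec4, "temp", yrs)
  clim <- period_climatology(s, c(1980, 2016))
  expect_true(all(unclass(clim) == 5))

  # half the years at 4, half at 6 -> mean 5
  d <- array(rep(c(4, 6), each = 4 * 4 * 12 * 5), c(4, 4, 12, 10))
  s2 <- kg_series(d, yrs, spec4, "temp")
  expect_true(all(abs(unclass(period_climatology(s2, c(1980, 1989))) - 5) < 1e-12))
  # subsetting the period selects only those years
  expect_true(all(unclass(period_climatology(s2, c(1980, 1984))) == 4))

  # a cell masked in every year stays masked
  d[2, 3, , ] <- NA
  s3 <- kg_series(d, yrs, spec4, "temp")
  clim3 <- period_climatology(s3, c(1980, 1989))
  expect_true(all(is.na(unclass(clim3)[2, 3, ])))
  expect_false(anyNA(unclass(clim3)[1, , ]))

  expect_error(period_climatology(s, c(1900, 1910)), "empty period")
})

test_that("change fields are differences for temperature, guarded ratios for precipitation", {
  src <- const_stack(5, spec4, "temp")
  tgt <- const_stack(6, spec4, "temp")
  off <- change_field(tgt, src)
  expect_equal(attr(off, "mode"), "offset")
  expect_true(all(unclass(off) == 1))

  psrc <- const_stack(100, spec4, "precip")
  ptgt <- const_stack(120, spec4, "precip")
  fac <- change_field(ptgt, psrc)
  expect_equal(attr(fac, "mode"), "factor")
  expect_true(all(abs(unclass(fac) - 1.2) < 1e-12))

  # zero baseline: ratio is epsilon-guarded and capped
  fac0 <- change_field(const_stack(3, spec4, "precip"),
                       const_stack(0, spec4, "precip"))
  expect_true(all(unclass(fac0) == 10))

  # identity: X vs X gives all-zero offsets / all-one factors
  expect_true(all(unclass(change_field(src, src)) == 0))
  expect_true(all(unclass(change_field(psrc, psrc)) == 1))

  other <- kg_grid(4, 4, 1, xmin = 10, ymax = 50)
  expect_error(change_field(tgt, const_stack(5, other, "temp")), "incompatible")
})

test_that("applying a change field adds offsets and multiplies factors", {
  clim <- const_stack(4.2, spec4, "temp")
  off <- kg_change_field(array(1, c(4, 4, 12)), spec4, "offset")
  expect_true(all(abs(unclass(apply_change(clim, off)) - 5.2) < 1e-12))

  p <- const_stack(80, spec4, "precip")
  fac <- kg_change_field(array(1.2, c(4, 4, 12)), spec4, "factor")
  expect_true(all(abs(unclass(apply_change(p, fac)) - 96) < 1e-12))

  # identity change reproduces the input exactly
  id_off <- kg_change_field(array(0, c(4, 4, 12)), spec4, "offset")
  expect_identical(unclass(apply_change(clim, id_off)), unclass(clim))
  id_fac <- kg_change_field(array(1, c(4, 4, 12)), spec4, "factor")
  expect_identical(unclass(apply_change(p, id_fac)), unclass(p))

  # offsets cannot be applied to precipitation
  expect_error(apply_change(p, off), "mismatch")
})

test_that("bilinear resampling reproduces nodes, midpoints and quarter points", {
  # 2 x 2 coarse grid, cell size 10: centers at lon 5,15 lat 45,35
  cspec <- kg_grid(2, 2, 10, xmin = 0, ymax = 50)
  v <- array(0, c(2, 2, 12))
  v[2, , ] <- 10   # south row = 10, north row = 0
  f <- kg_change_field(v, cspec, "offset")

  # fine cell centered exactly midway between the rows
  mid <- kg_grid(1, 1, 10, xmin = 5, ymax = 45)   # center (10, 40)
  expect_equal(unclass(bilinear_to_grid(f, mid))[1, 1, 1], 5)

  # fine cell centered exactly on a coarse center reproduces the node
  node <- kg_grid(1, 1, 2, xmin = 4, ymax = 36)   # center (5, 35)
  expect_equal(unclass(bilinear_to_grid(f, node))[1, 1, 1], 10)

  # quarter of the way from lat 45 to lat 35 -> 0.75/0.25 weights
  quarter <- kg_grid(1, 1, 5, xmin = 2.5, ymax = 45)  # center (5, 42.5)
  expect_equal(unclass(bilinear_to_grid(f, quarter))[1, 1, 1], 2.5)
})

test_that("bilinear resampling is exact on fields linear in lon/lat and bounded otherwise", {
  cspec <- kg_grid(10, 12, 1, xmin = 0, ymax = 50)
  lon <- grid_lons(cspec); lat <- grid_lats(cspec)
  lin <- outer(lat * (-0.7), lon * 0.3, `+`) + 2
  f <- kg_change_field(array(lin, c(10, 12, 12)), cspec, "offset")
  # fine grid strictly inside the coarse center hull
  fspec <- kg_grid(16, 20, 0.5, xmin = 1, ymax = 49)
  out <- bilinear_to_grid(f, fspec)
  expected <- outer(grid_lats(fspec) * (-0.7), grid_lons(fspec) * 0.3, `+`) + 2
  expect_equal(unclass(out)[, , 1], expected, tolerance = 1e-12)

  # boundedness on a random field
  set.seed(9)
  rv <- array(runif(10 * 12 * 12), c(10, 12, 12))
  rf <- kg_change_field(rv, cspec, "offset")
  ro <- bilinear_to_grid(rf, fspec)
  expect_true(all(unclass(ro) >= min(rv) - 1e-12 & unclass(ro) <= max(rv) + 1e-12))
})

test_that("masked coarse neighbors are renormalized, all-masked cells stay masked", {
  cspec <- kg_grid(2, 2, 10, xmin = 0, ymax = 50)
  v <- array(c(NA, 10, NA, 10), c(2, 2, 12))   # north row masked
  f <- kg_change_field(v, cspec, "offset")
  mid <- kg_grid(1, 1, 10, xmin = 5, ymax = 45)
  # only the southern neighbors contribute -> value 10, not NA
  expect_equal(unclass(bilinear_to_grid(f, mid))[1, 1, 1], 10)

  allna <- kg_change_field(array(NA_real_, c(2, 2, 12)), cspec, "offset")
  expect_true(is.na(unclass(bilinear_to_grid(allna, mid))[1, 1, 1]))

  disjoint <- kg_grid(2, 2, 1, xmin = 100, ymax = 20)
  expect_error(bilinear_to_grid(f, disjoint), "incompatible")
})

test_that("interpolation wraps across the antimeridian on global grids", {
  cspec <- kg_grid(2, 4, 90, xmin = -180, ymax = 90)  # centers at -135,-45,45,135
  v <- array(0, c(2, 4, 12)); v[, 1, ] <- 4; v[, 4, ] <- 8
  f <- kg_change_field(v, cspec, "offset")
  # fine cell centered on the antimeridian edge: midway between 135 and -135(+360)
  seam <- kg_grid(1, 1, 2, xmin = -181, ymax = 46)   # center lon -180, lat 45
  expect_equal(unclass(bilinear_to_grid(f, seam))[1, 1, 1], 6)
})

test_that("homogenizing a dataset to its own span leaves classifications unchanged", {
  w <- small_world()
  ref_t <- synth_coarse_series(w, "temp", c(1980, 2016), kg_grid(45, 90, 4),
                               drift = 0.2, noise_sd = 0, seed = 3)
  adj <- homogenize(w$temp, ref_t, c(1980, 2016), c(1980, 2016))
  expect_equal(unclass(adj), unclass(w$temp), tolerance = 1e-10)
})

test_that("homogenization shifts a dataset by the reference trend", {
  w <- small_world()
  coarse <- kg_grid(45, 90, 4)
  # reference drifting +0.2 degC/decade; dataset spans 1960-1990, target 1980-2016
  ref <- synth_coarse_series(w, "temp", c(1960, 2016), coarse,
                             drift = 0.2, noise_sd = 0, seed = 3)
  adj <- homogenize(w$temp, ref, c(1960, 1990), c(1980, 2016))
  # expected offset: drift * (mean(1980:2016) - mean(1960:1990)) / 10
  expected <- 0.2 * (mean(1980:2016) - mean(1960:1990)) / 10
  delta <- unclass(adj) - unclass(w$temp)
  expect_equal(mean(delta), expected, tolerance = 1e-6)
  expect_lt(max(abs(delta - expected)), 1e-6)
})
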