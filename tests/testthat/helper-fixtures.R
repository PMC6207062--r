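# Shared fixtures. The "small world" (2 degree grid) keeps most tests fast;
# the full default world is exercised in the acceptance suite.

med_temp <- c(8, 9, 11, 13, 17, 21, 24, 24, 21, 16, 12, 9)
med_precip <- c(80, 70, 60, 50, 30, 10, 5, 10, 40, 70, 90, 85)
dfb_temp <- c(-10, -8, -2, 5, 12, 16, 18, 17, 12, 5, -2, -8)

small_world_cache <- new.env()
small_world <- function() {
  if (is.null(small_world_cache$w))
    small_world_cache$w <- synth_world(world_recipe(spec = kg_grid(90, 180, 2)))
  small_world_cache$w
}

# constant-valued stack helper
const_stack <- function(value, spec, var) {
  kg_stack(array(value, c(spec$rows, spec$cols, 12)), spec, var)
}

# series with identical grids every year
const_series <- function(value, spec, var, years) {
  kg_series(array(value, c(spec$rows, spec$cols, 12, length(years))),
            years, spec, var)
}
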