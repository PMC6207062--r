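# Independent, deliberately literal rule-by-rule classifier used as an
# oracle. It mirrors the classification table line by line with scalar
# arithmetic and shares no code with the package's vectorized classifier.
koppen_oracle <- function(temp, precip) {
  apr_sep <- 4:9
  oct_mar <- c(10:12, 1:3)
  if (mean(temp[apr_sep]) >= mean(temp[oct_mar])) {
    summer <- apr_sep; winter <- oct_mar
  } else {
    summer <- oct_mar; winter <- apr_sep
  }

  MAT <- mean(temp)
  MAP <- sum(precip)
  T_cold <- min(temp)
  T_hot <- max(temp)
  T_mon10 <- sum(temp > 10)
  P_dry <- min(precip)
  P_sdry <- min(precip[summer]); P_swet <- max(precip[summer])
  P_wdry <- min(precip[winter]); P_wwet <- max(precip[winter])
  P_summer <- sum(precip[summer]); P_winter <- sum(precip[winter])

  if (MAP > 0 && P_winter / MAP > 0.7) {
    Pth <- 2 * MAT
  } else if (MAP > 0 && P_summer / MAP > 0.7) {
    Pth <- 2 * MAT + 28
  } else {
    Pth <- 2 * MAT + 14
  }

  # B has precedence over every other class
  if (MAP < 10 * Pth) {
    first <- if (MAP < 5 * Pth) "BW" else "BS"
    return(paste0(first, if (MAT >= 18) "h" else "k"))
  }
  if (T_hot <= 10) {
    return(if (T_hot > 0) "ET" else "EF")
  }
  if (T_cold >= 18) {
    if (P_dry >= 60) return("Af")
    if (P_dry >= 100 - MAP / 25) return("Am")
    return("Aw")
  }
  # temperate or cold; s and w made mutually exclusive by seasonal totals
  s_crit <- P_sdry < 40 && P_sdry < P_wwet / 3
  w_crit <- P_wdry < P_swet / 10
  second <- if (s_crit && w_crit) {
    if (P_winter > P_summer) "s" else "w"
  } else if (s_crit) "s" else if (w_crit) "w" else "f"

  if (T_cold > 0 && T_cold < 18) {
    third <- if (T_hot >= 22) "a" else if (T_mon10 >= 4) "b" else "c"
    return(paste0("C", second, third))
  }
  # D: T_cold <= 0 and T_hot > 10
  third <- if (T_hot >= 22) "a"
           else if (T_mon10 >= 4) "b"
           else if (T_cold < -38) "d"
           else "c"
  paste0("D", second, third)
}

# random climatology generators for property tests: an unstructured draw
# spanning -60..40 degrees C and 0..1000 mm/month, and a seasonal draw with
# a sinusoidal temperature cycle and seasonally concentrated precipitation
random_climatology <- function() {
  list(temp = stats::runif(12, -60, 40), precip = stats::runif(12, 0, 1000))
}

random_seasonal_climatology <- function() {
  tbar <- stats::runif(1, -30, 30)
  amp <- stats::runif(1, 0, 30)
  phase <- sample.int(12, 1)
  temp <- tbar + amp * cos(2 * pi * ((1:12) - phase) / 12)
  pbase <- stats::runif(1, 0, 150)
  pamp <- stats::runif(1, 0, 1) * pbase
  pphase <- sample.int(12, 1)
  precip <- pmax(pbase + pamp * cos(2 * pi * ((1:12) - pphase) / 12) +
                   stats::rnorm(12, 0, 5), 0)
  list(temp = temp, precip = precip)
}
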