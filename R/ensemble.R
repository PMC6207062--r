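#' Build the present-day classification ensemble
#'
#' One ensemble member per (temperature dataset, precipitation dataset)
#' combination: each pair is classified cell-wise. With 3 temperature and 4
#' precipitation datasets this yields the 12-member present-day ensemble.
#'
#' @param temp_list list of homogenized temperature [kg_stack()]s (optionally
#'   named; names become part of the member labels).
#' @param precip_list list of homogenized precipitation [kg_stack()]s.
#' @return a list of ensemble members, each a list with `label` and
#'   `classification` (a [kg_class_grid()]).
#' @export
present_ensemble <- function(temp_list, precip_list) {
  stopifnot(length(temp_list) >= 1, length(precip_list) >= 1)
  tn <- names(temp_list);   if (is.null(tn)) tn <- paste0("T", seq_along(temp_list))
  pn <- names(precip_list); if (is.null(pn)) pn <- paste0("P", seq_along(precip_list))
  spec <- stack_spec(temp_list[[1]])
  for (s in c(temp_list, precip_list))
    check_same_grid(spec, stack_spec(s), "ensemble input stacks")
  members <- list()
  for (i in seq_along(temp_list))
    for (j in seq_along(precip_list))
      members[[length(members) + 1L]] <- list(
        label = paste0(tn[i], "x", pn[j]),
        classification = classify_stack(temp_list[[i]], precip_list[[j]]))
  members
}

member_codes <- function(m) {
  if (inherits(m, "kg_class_grid")) m$codes else m$classification$codes
}
member_spec <- function(m) {
  if (inherits(m, "kg_class_grid")) m$spec else m$classification$spec
}

#' Majority vote over a classification ensemble
#'
#' Per grid cell, the final class is the most common class among the valid
#' member votes; the confidence level is 100 times the modal frequency
#' divided by the full ensemble size `n`. Ties are broken toward the lowest
#' class code. Cells with no valid vote in any member are nodata.
#'
#' @param members list of ensemble members ([kg_class_grid()]s, or lists with
#'   a `classification` element as produced by [present_ensemble()]).
#' @param n ensemble size used as the confidence denominator; defaults to
#'   `length(members)` and stays fixed even at cells where some members are
#'   nodata.
#' @return a list with `classes` (a [kg_class_grid()]) and `confidence`
#'   (a [kg_conf_grid()]).
#' @examples
#' # 8 of 12 votes for the modal class gives confidence 100*8/12 = 66.66...
#' # (displayed as 66.6 by format_confidence())
#' @export
majority_vote <- function(members, n = length(members)) {
  if (length(members) == 0) stop("empty ensemble")
  spec <- member_spec(members[[1]])
  mats <- lapply(members, function(m) {
    check_same_grid(spec, member_spec(m), "ensemble members")
    member_codes(m)
  })
  best_cnt  <- matrix(0L, spec$rows, spec$cols)
  best_code <- matrix(0L, spec$rows, spec$cols)
  for (k in 1:30) {
    cnt <- matrix(0L, spec$rows, spec$cols)
    for (m in mats) cnt <- cnt + (m == k)
    better <- cnt > best_cnt
    if (any(better)) {
      best_code[better] <- k
      best_cnt[better] <- cnt[better]
    }
  }
  conf <- 100 * best_cnt / n
  conf[best_cnt == 0L] <- NA_real_
  list(classes = kg_class_grid(best_code, spec),
       confidence = kg_conf_grid(conf, spec))
}

#' Ensemble-mean reference climatology
#'
#' Simple per-cell, per-month average of a set of temporally-homogenized
#' climatology stacks — the observed baseline onto which modeled anomalies
#' are superimposed. A cell that is nodata in any member is nodata in the
#' reference.
#'
#' @param stacks list of [kg_stack()]s of one variable on one grid.
#' @return the mean [kg_stack()].
#' @export
reference_climatology <- function(stacks) {
  stopifnot(length(stacks) >= 1)
  spec <- stack_spec(stacks[[1]]); var <- stack_var(stacks[[1]])
  for (s in stacks) {
    check_same_grid(spec, stack_spec(s), "reference inputs")
    if (stack_var(s) != var) stop("reference inputs mix variables")
  }
  acc <- unclass(stacks[[1]])
  if (length(stacks) > 1)
    for (s in stacks[-1]) acc <- acc + unclass(s)  # NA in any member propagates
  kg_stack(acc / length(stacks), spec, var)
}

#' Build the future classification ensemble by the anomaly method
#'
#' For each climate model: period climatologies of its historical and future
#' runs are formed, per-month change offsets (temperature) and factors
#' (precipitation) are computed between the two periods, resampled from the
#' model grid to the fine grid by bilinear interpolation, and applied to the
#' observed reference climatologies; the adjusted fields are then classified.
#' Models missing a variable or period are skipped with a warning.
#'
#' @param reference_temp,reference_precip fine-grid reference [kg_stack()]s
#'   (see [reference_climatology()]).
#' @param models list of model runs; each a list with `label`, `hist_temp`,
#'   `hist_precip`, `fut_temp`, `fut_precip` ([kg_series()] objects on the
#'   model's native coarse grid).
#' @param hist_period,fut_period inclusive year ranges of the baseline and
#'   future periods (defaults 1980-2016 and 2071-2100).
#' @param epsilon,cap factor-mode guards, see [change_field()].
#' @return a list of ensemble members as in [present_ensemble()], with an
#'   attribute `n_skipped` counting dropped models.
#' @export
future_ensemble <- function(reference_temp, reference_precip, models,
                            hist_period = c(1980, 2016),
                            fut_period = c(2071, 2100),
                            epsilon = 0.01, cap = 10) {
  stopifnot(length(models) >= 1)
  fine <- stack_spec(reference_temp)
  check_same_grid(fine, stack_spec(reference_precip), "reference stacks")
  members <- list(); n_skipped <- 0L
  for (mod in models) {
    need <- c("hist_temp", "hist_precip", "fut_temp", "fut_precip")
    have <- vapply(need, function(f) !is.null(mod[[f]]), logical(1))
    ok <- all(have) && all(vapply(need, function(f) {
      s <- mod[[f]]
      per <- if (grepl("^hist", f)) hist_period else fut_period
      any(s$years >= per[1] & s$years <= per[2])
    }, logical(1)))
    if (!ok) {
      warning("skipping model '", mod$label %||% "?",
              "': missing variable or period", call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    t_off <- change_field(period_climatology(mod$fut_temp, fut_period),
                          period_climatology(mod$hist_temp, hist_period))
    p_fac <- change_field(period_climatology(mod$fut_precip, fut_period),
                          period_climatology(mod$hist_precip, hist_period),
                          epsilon = epsilon, cap = cap)
    t_adj <- apply_change(reference_temp, bilinear_to_grid(t_off, fine))
    p_adj <- apply_change(reference_precip, bilinear_to_grid(p_fac, fine))
    members[[length(members) + 1L]] <- list(
      label = mod$label %||% paste0("model", length(members) + 1L),
      classification = classify_stack(t_adj, p_adj))
  }
  if (length(members) == 0) stop("all models were skipped: no usable model data")
  attr(members, "n_skipped") <- n_skipped
  members
}

`%||%` <- function(a, b) if (is.null(a)) b else a
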