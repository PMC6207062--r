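res_token <- function(spec) {
  cs <- spec$cell_size
  if (abs(cs - 1/120) < 1e-12) "0p0083"
  else if (abs(cs - 1/12) < 1e-12) "0p083"
  else if (abs(cs - 1/2) < 1e-12) "0p5"
  else sub("\\.", "p", sub("0+$", "", sprintf("%.6f", cs)))
}

write_products <- function(classes, confidence, out_dir, epoch, prefix,
                           upscale_to) {
  files <- character(0)
  emit <- function(cl, cf) {
    tok <- res_token(cl$spec)
    f1 <- file.path(out_dir, sprintf("%s_%s_%s.tif", prefix, epoch, tok))
    f2 <- file.path(out_dir, sprintf("%s_%s_conf_%s.tif", prefix, epoch, tok))
    write_class_map(cl, f1); write_conf_map(cf, f2)
    c(f1, f2)
  }
  files <- c(files, emit(classes, confidence))
  for (target in upscale_to)
    files <- c(files, emit(upscale_majority(classes, target),
                           upscale_mean(confidence, target)))
  files
}

#' Build the present-day classification and confidence maps
#'
#' Optionally homogenizes each climatic dataset to the target period using a
#' coarse reference series, classifies every (temperature, precipitation)
#' dataset combination, majority-votes the ensemble, and writes class and
#' confidence GeoTIFFs (plus upscaled versions) together with a
#' machine-readable run manifest. Reruns with the same inputs are
#' byte-identical.
#'
#' @param temp_list,precip_list lists of fine-grid [kg_stack()]s (named lists
#'   give labeled ensemble members).
#' @param out_dir output directory (created if needed).
#' @param reference_temp,reference_precip optional coarse [kg_series()] used
#'   to homogenize the datasets; when NULL, homogenization is skipped with a
#'   warning unless `source_periods_*` is also NULL.
#' @param source_periods_temp,source_periods_precip lists of inclusive year
#'   ranges, one per dataset, giving each dataset's native temporal span.
#' @param target_period period the maps should represent (default 1980-2016).
#' @param upscale_to list of coarser nested [kg_grid()]s to also emit.
#' @param prefix file-name prefix.
#' @param epsilon,cap factor guards, see [change_field()].
#' @return a list with `classes`, `confidence`, `members`, `files` and
#'   `manifest` (path to the JSON manifest).
#' @export
run_present <- function(temp_list, precip_list, out_dir,
                        reference_temp = NULL, reference_precip = NULL,
                        source_periods_temp = NULL, source_periods_precip = NULL,
                        target_period = c(1980, 2016),
                        upscale_to = list(), prefix = "KG",
                        epsilon = 0.01, cap = 10) {
  if (length(temp_list) < 1 || length(precip_list) < 1)
    stop("missing inputs: need at least one temperature and one precipitation dataset")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  homogenized <- FALSE
  if (!is.null(reference_temp) && !is.null(source_periods_temp)) {
    temp_list <- mapply(function(s, per)
      homogenize(s, reference_temp, per, target_period, epsilon, cap),
      temp_list, source_periods_temp, SIMPLIFY = FALSE)
    homogenized <- TRUE
  } else if (!is.null(source_periods_temp)) {
    warning("no temperature reference series: homogenization skipped")
  }
  if (!is.null(reference_precip) && !is.null(source_periods_precip)) {
    precip_list <- mapply(function(s, per)
      homogenize(s, reference_precip, per, target_period, epsilon, cap),
      precip_list, source_periods_precip, SIMPLIFY = FALSE)
    homogenized <- TRUE
  } else if (!is.null(source_periods_precip)) {
    warning("no precipitation reference series: homogenization skipped")
  }

  members <- present_ensemble(temp_list, precip_list)
  vote <- majority_vote(members)
  files <- write_products(vote$classes, vote$confidence, out_dir, "present",
                          prefix, upscale_to)
  manifest <- file.path(out_dir, "present_manifest.json")
  jsonlite::write_json(list(
    kind = "present",
    n_members = length(members),
    member_labels = vapply(members, `[[`, character(1), "label"),
    target_period = target_period,
    homogenized = homogenized,
    options = list(epsilon = epsilon, cap = cap),
    outputs = basename(files),
    package = as.character(utils::packageVersion("koppenmap"))),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  list(classes = vote$classes, confidence = vote$confidence,
       members = members, files = files, manifest = manifest)
}

#' Build the future classification and confidence maps (anomaly method)
#'
#' Averages the homogenized present-day datasets into reference
#' climatologies, derives per-model change offsets/factors between the
#' historical and future periods, applies them to the reference, classifies
#' each model's adjusted fields, majority-votes the model ensemble and
#' writes the map products and a manifest.
#'
#' @param temp_list,precip_list homogenized fine-grid [kg_stack()]s whose
#'   mean is the reference climatology.
#' @param models list of model runs (see [future_ensemble()]).
#' @param out_dir output directory.
#' @param hist_period,fut_period baseline and future periods (defaults
#'   1980-2016 and 2071-2100).
#' @param upscale_to,prefix,epsilon,cap as in [run_present()].
#' @return a list with `classes`, `confidence`, `members`, `n_skipped`,
#'   `files` and `manifest`.
#' @export
run_future <- function(temp_list, precip_list, models, out_dir,
                       hist_period = c(1980, 2016), fut_period = c(2071, 2100),
                       upscale_to = list(), prefix = "KG",
                       epsilon = 0.01, cap = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref_t <- reference_climatology(temp_list)
  ref_p <- reference_climatology(precip_list)
  members <- future_ensemble(ref_t, ref_p, models, hist_period, fut_period,
                             epsilon, cap)
  vote <- majority_vote(members)
  files <- write_products(vote$classes, vote$confidence, out_dir, "future",
                          prefix, upscale_to)
  manifest <- file.path(out_dir, "future_manifest.json")
  jsonlite::write_json(list(
    kind = "future",
    n_members = length(members),
    n_skipped = attr(members, "n_skipped"),
    member_labels = vapply(members, `[[`, character(1), "label"),
    hist_period = hist_period, fut_period = fut_period,
    options = list(epsilon = epsilon, cap = cap),
    outputs = basename(files),
    package = as.character(utils::packageVersion("koppenmap"))),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  list(classes = vote$classes, confidence = vote$confidence,
       members = members, n_skipped = attr(members, "n_skipped"),
       files = files, manifest = manifest)
}

#' Validate a classification map against station records
#'
#' Builds quality-controlled station climatologies from daily records,
#' classifies them as the reference, and reports the map's classification
#' accuracy, the mean confidence split by correctness, a per-station result
#' table (written as CSV) and the QC rejection tally.
#'
#' @param classes a [kg_class_grid()] or path to a class GeoTIFF.
#' @param confidence a [kg_conf_grid()] or path, or NULL to skip the split.
#' @param stations data.frame of daily records or path to a station CSV.
#' @param out_dir output directory for `station_results.csv` and
#'   `validation_report.json`.
#' @param min_days,min_years completeness rules (see
#'   [build_station_climatologies()]).
#' @return a list with `accuracy`, `n_evaluated`, `n_excluded`,
#'   `mean_conf_correct`, `mean_conf_wrong`, `n_rejected`, `rejected` and
#'   `table`.
#' @export
run_validate <- function(classes, confidence = NULL, stations, out_dir,
                         min_days = 25, min_years = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(classes)) classes <- read_class_map(classes)
  if (is.character(confidence)) confidence <- read_conf_map(confidence)
  if (is.character(stations)) stations <- read_stations(stations)
  if (nrow(stations) == 0) stop("empty station records")

  qc <- build_station_climatologies(stations, min_days, min_years)
  if (length(qc$stations) == 0)
    stop("no stations passed quality control (",
         nrow(qc$rejected), " rejected)")
  acc <- classification_accuracy(classes, qc$stations)
  split <- if (!is.null(confidence))
    confidence_split(classes, confidence, qc$stations)
  else list(mean_conf_correct = NA_real_, mean_conf_wrong = NA_real_,
            n_correct = NA_integer_, n_wrong = NA_integer_, table = acc$table)

  utils::write.csv(split$table, file.path(out_dir, "station_results.csv"),
                   row.names = FALSE)
  report <- list(
    accuracy = acc$accuracy,
    n_evaluated = acc$n_evaluated, n_excluded = acc$n_excluded,
    mean_conf_correct = split$mean_conf_correct,
    mean_conf_wrong = split$mean_conf_wrong,
    n_correct = split$n_correct, n_wrong = split$n_wrong,
    n_rejected = nrow(qc$rejected))
  jsonlite::write_json(report, file.path(out_dir, "validation_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  c(report, list(rejected = qc$rejected, table = split$table))
}
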