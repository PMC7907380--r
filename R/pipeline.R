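#' Run the full analysis pipeline on a synthetic study
#'
#' simulate -> preprocess -> features -> behavior classification (grouped
#' cross-validation) -> intrusion detection (repeated stratified twofold
#' cross-validation) -> localization geometry fit -> per-minute surfaces ->
#' evaluation. Returns every stage's result plus a reproducibility
#' manifest (config hash, derived seeds, metric summary).
#'
#' @param config an `ews_config`
#' @param n_intrusions intrusion segments (a matched control each)
#' @param spec a [behavior_spec()]
#' @param n_features detector model size
#' @param detector_repeats twofold repetitions
#' @param localize_every_min surface cadence (minutes)
#' @param out_dir optional directory for CSV reports
#' @param verbose progress messages
#' @return an `ews_run`: `study`, `features` (prepared), `loio`, `pr`,
#'   `detection`, `detector_cv`, `geometry`, `surfaces`, `localization`,
#'   `manifest`
#' @export
run_pipeline <- function(config, n_intrusions = 10, spec = behavior_spec(),
                         n_features = 7, detector_repeats = 25,
                         localize_every_min = 5, duration_s = 7200,
                         out_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  say("simulating study (", n_intrusions, " intrusions + controls) ...")
  study <- simulate_study(config, n_intrusions = n_intrusions,
                          duration_s = duration_s)
  say("engineering features ...")
  fbase <- prepare_features(study$minutes, study$landscape)
  say("behavior classification (leave-one-intrusion-out) ...")
  loio <- loio_cross_validate(fbase, study$segments, spec, verbose = verbose)
  boundary <- if (!is.null(loio$pr)) loio$pr$boundary_f1 else 0.5
  say("intrusion detection (", detector_repeats, "x twofold) ...")
  det <- detection_dataset(loio$predictions, study$segments,
                           boundary = boundary)
  cv <- cross_validate_detector(det, n_features = n_features,
                                repeats = detector_repeats,
                                seed = config$seed)
  say("localization ...")
  geom <- fit_geometry_from_predictions(loio$predictions, study, boundary,
                                        seed = config$seed)
  surf <- localize_study(loio$predictions, study, geom, boundary,
                         every_min = localize_every_min)
  loc <- evaluate_localization(surf)
  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    n_intrusions = n_intrusions,
    n_animal_minutes = nrow(study$minutes),
    n_feature_columns = feature_count(fbase),
    behavior_ap = loio$ap,
    behavior_prevalence = loio$prevalence,
    boundary_f1 = boundary,
    detection_accuracy = cv$accuracy,
    detection_precision = cv$precision,
    detection_recall = cv$recall,
    localization_fraction_within = as.list(loc$fraction_within),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  run <- structure(list(study = study, features = fbase, loio = loio,
                        detection = det, detector_cv = cv, geometry = geom,
                        surfaces = surf, localization = loc,
                        manifest = manifest), class = "ews_run")
  if (!is.null(out_dir)) write_run_reports(run, out_dir)
  run
}

#' @export
print.ews_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("<ews_run seed %d: behavior AP %.3f (prev %.3f), ",
                     "detection acc %.3f, localization <500m %.0f%%>\n"),
              m$seed, m$behavior_ap, m$behavior_prevalence,
              m$detection_accuracy,
              100 * m$localization_fraction_within[["500m"]]))
  invisible(x)
}

#' Write a run's tables and manifest under a directory
#' @param run an `ews_run`
#' @param dir output directory (created)
#' @return the directory, invisibly
#' @export
write_run_reports <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$loio$predictions, file.path(dir, "behavior_probabilities.csv"),
                   row.names = FALSE)
  utils::write.csv(run$detection$summaries, file.path(dir, "segment_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(run$detector_cv$metrics, file.path(dir, "detector_cv_metrics.csv"),
                   row.names = FALSE)
  if (!is.null(run$surfaces))
    utils::write.csv(run$surfaces, file.path(dir, "localization_surfaces.csv"),
                     row.names = FALSE)
  utils::write.csv(run$localization$per_intrusion,
                   file.path(dir, "localization_errors.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Adapter for field data in the deposited-collar CSV schema
#'
#' Maps externally supplied GPS-fix and ODBA-window tables onto the
#' internal sensor-track type. Expected columns (case-insensitive):
#' fixes `animal_id, timestamp, x, y`; ODBA
#' `animal_id, window_start, odba_mean, odba_max, odba_var`. Unmapped
#' columns are reported; missing required columns raise a column-level
#' error. Never used by the simulation tests.
#'
#' @param fix_path,odba_path CSV paths
#' @return list of `ews_sensor_track`
#' @export
load_field_data <- function(fix_path, odba_path) {
  if (!file.exists(fix_path)) stop("fix file not found: ", fix_path)
  if (!file.exists(odba_path)) stop("ODBA file not found: ", odba_path)
  fx <- utils::read.csv(fix_path)
  od <- utils::read.csv(odba_path)
  names(fx) <- tolower(names(fx)); names(od) <- tolower(names(od))
  need_fx <- c("animal_id", "timestamp", "x", "y")
  need_od <- c("animal_id", "window_start", "odba_mean", "odba_max", "odba_var")
  miss <- c(setdiff(need_fx, names(fx)), setdiff(need_od, names(od)))
  if (length(miss) > 0)
    stop("missing required columns: ", paste(miss, collapse = ", "))
  unmapped <- c(setdiff(names(fx), need_fx), setdiff(names(od), need_od))
  if (length(unmapped) > 0)
    message("unmapped columns ignored: ", paste(unique(unmapped), collapse = ", "))
  parse_t <- function(s) {
    if (is.numeric(s)) return(as.numeric(s))
    as.numeric(as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  }
  ids <- unique(fx$animal_id)
  lapply(ids, function(id) {
    f <- fx[fx$animal_id == id, ]
    o <- od[od$animal_id == id, ]
    structure(list(
      animal_id = id,
      fixes = data.frame(time = parse_t(f$timestamp), x = f$x, y = f$y),
      odba_windows = data.frame(window_start = parse_t(o$window_start),
                                mean = o$odba_mean, max = o$odba_max,
                                variance = o$odba_var)),
      class = "ews_sensor_track")
  })
}
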