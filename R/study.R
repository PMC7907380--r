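#' Simulate a full experimental-intrusion study
#'
#' Generates the complete synthetic dataset the downstream analysis
#' consumes: a landscape, a schedule of intrusion segments (each ca. 2 h,
#' stratified over mornings / middays / afternoons) with matched control
#' segments one or two days earlier or later at the same clock time, herds
#' simulated independently per segment, behavioral responses planted during
#' intrusions, sensor degradation, and five-step trajectory reconstruction.
#' Ground-truth labels (undisturbed / flight / regroup), response
#' intensities and distances to the intruder are carried at minute
#' resolution.
#'
#' @param config an `ews_config`
#' @param n_intrusions number of intrusion segments (a matched control is
#'   generated for each)
#' @param duration_s segment duration (s)
#' @param keep_sensor keep the raw sensor tracks in the result
#' @param preprocess reconstruct 1-min tracks (set `FALSE` to keep only the
#'   decimated truth, used by fast tests)
#' @return an `ews_study`: `landscape`, `segments` (metadata incl. paired
#'   control and active-sensor count), `intrusions` (list by segment id),
#'   `minutes` (data.table of animal-minutes with positions, ODBA stats,
#'   truth labels), `config`
#' @export
simulate_study <- function(config, n_intrusions = 10, duration_s = 7200,
                           keep_sensor = FALSE, preprocess = TRUE) {
  landscape <- generate_landscape(config$seed, config$extent_m, config$cell_m,
                                  species = names(config$n_per_species))
  day0 <- as.numeric(as.POSIXct("2017-10-01", tz = "UTC"))
  tods <- c(morning = 7 * 3600, midday = 12 * 3600, afternoon = 16 * 3600)
  sched <- with_seed(derive_seed(config$seed, "schedule"), {
    data.frame(
      intr = seq_len(n_intrusions),
      day = 5 * (seq_len(n_intrusions) - 1),
      tod = sample(names(tods), n_intrusions, replace = TRUE),
      mode = sample(c("foot", "vehicle"), n_intrusions, replace = TRUE,
                    prob = c(0.7, 0.3)),
      offset = sample(c(-2, -1, 1, 2), n_intrusions, replace = TRUE)
    )
  })

  segs <- list(); intrs <- list(); minute_parts <- list(); sensors <- list()
  for (k in seq_len(n_intrusions)) {
    iid <- sprintf("intr_%02d", k)
    t_int <- day0 + sched$day[k] * 86400 + tods[[sched$tod[k]]]
    t_ctl <- t_int + sched$offset[k] * 86400
    intr <- generate_intrusion(landscape, config$seed, start_time = t_int + 300,
                               mode = sched$mode[k], duration_s = duration_s - 600,
                               group_size = 2, intrusion_id = iid)
    for (role in c("intrusion", "control")) {
      sid <- sprintf("%s_%s", iid, substr(role, 1, 4))
      t0 <- if (role == "intrusion") t_int else t_ctl
      seed_k <- derive_seed(config$seed, sid)
      part <- simulate_segment(landscape, config, duration_s, t0, seed_k,
                               intrusion = if (role == "intrusion") intr,
                               segment_id = sid, keep_sensor = keep_sensor,
                               preprocess = preprocess)
      minute_parts[[sid]] <- part$minutes
      if (keep_sensor) sensors[[sid]] <- part$sensor
      segs[[sid]] <- data.frame(
        segment_id = sid, truth = role, intrusion_id = iid,
        start_time = t0, end_time = t0 + duration_s,
        tod = sched$tod[k], mode = sched$mode[k],
        control_offset_days = if (role == "control") sched$offset[k] else NA,
        n_active_sensors = part$n_active, stringsAsFactors = FALSE)
      if (role == "intrusion") intrs[[sid]] <- intr
    }
  }
  structure(list(
    landscape = landscape,
    segments = do.call(rbind, segs),
    intrusions = intrs,
    minutes = data.table::rbindlist(minute_parts),
    sensor = if (keep_sensor) sensors,
    config = config
  ), class = "ews_study")
}

# one simulated segment: herds (+ planted responses), degradation,
# reconstruction, truth merge at minute marks
simulate_segment <- function(landscape, config, duration_s, start_time, seed,
                             intrusion = NULL, segment_id = "seg",
                             keep_sensor = FALSE, preprocess = TRUE) {
  tr <- simulate_herd_core(landscape, config, duration_s, start_time, seed,
                           intrusion = intrusion)
  sts <- degrade_tracks(tr, config, seed = derive_seed(seed, "sensor"))
  ids <- tr$animals$animal_id
  rts <- list()
  if (preprocess) {
    for (a in seq_along(sts)) {
      rt <- suppressWarnings(preprocess_track(sts[[a]], landscape$bbox))
      if (!is.null(rt)) rts[[length(rts) + 1]] <- rt
    }
  } else {
    grid <- seq(ceiling(min(tr$times) / 60) * 60, floor(max(tr$times) / 60) * 60, 60)
    idx <- match(grid, tr$times)
    for (a in seq_along(ids)) {
      rts[[a]] <- data.frame(animal_id = ids[a], time = grid,
                             x = tr$x[idx, a], y = tr$y[idx, a],
                             odba_mean = tr$odba[idx, a],
                             odba_max = tr$odba[idx, a],
                             odba_var = 0, provenance = "observed")
    }
  }
  mins <- data.table::rbindlist(rts)
  # merge ground truth at minute marks
  idx <- match(mins$time, tr$times)
  a_idx <- match(mins$animal_id, ids)
  flat <- cbind(idx, a_idx)
  mins[, `:=`(
    segment_id = segment_id,
    species = tr$animals$species[a_idx],
    label = tr$label[flat],
    intensity = tr$intensity[flat],
    true_x = tr$x[flat], true_y = tr$y[flat]
  )]
  if (!is.null(intrusion)) {
    ip <- intrusion_at(intrusion, mins$time)
    mins[, dist_intruder := sqrt((x - ip$x)^2 + (y - ip$y)^2)]
  } else {
    mins[, dist_intruder := NA_real_]
  }
  list(minutes = mins,
       n_active = length(unique(mins$animal_id)),
       sensor = if (keep_sensor) sts)
}

#' @export
print.ews_study <- function(x, ...) {
  cat(sprintf("<ews_study: %d segments (%d intrusion), %d animal-minutes>\n",
              nrow(x$segments), sum(x$segments$truth == "intrusion"),
              nrow(x$minutes)))
  invisible(x)
}
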