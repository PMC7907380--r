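#' Degrade a true 1-s track to sensor-like data
#'
#' Emulates the collar firmware: ODBA summarized per contiguous 15-s window
#' (mean / max / variance, with sensor noise); GPS fixes on an adaptive
#' schedule — every 15 min when the windowed mean ODBA is below the activity
#' threshold, every 2 or 10 min (a per-collar setting) when active; a 5-m
#' geofence suppresses a new fix measured within 5 m of the previous
#' retained fix; Gaussian positional noise; occasional spike outliers
#' (single fixes displaced by 500-1500 m in a uniform direction).
#'
#' @param track data.frame with columns `time` (1-s regular), `x`, `y`,
#'   `odba` for one animal
#' @param config an `ews_config`
#' @param seed integer seed
#' @param animal_id identifier carried through
#' @return an `ews_sensor_track`: `fixes` (time, x, y, irregular) and
#'   `odba_windows` (window_start, mean, max, variance on the uninterrupted
#'   15-s grid)
#' @export
degrade_to_sensor <- function(track, config, seed, animal_id = "animal") {
  if (nrow(track) == 0) {
    return(structure(list(animal_id = animal_id,
                          fixes = data.frame(time = numeric(), x = numeric(), y = numeric()),
                          odba_windows = data.frame(window_start = numeric(), mean = numeric(),
                                                    max = numeric(), variance = numeric())),
                     class = "ews_sensor_track"))
  }
  stopifnot(all(diff(track$time) == 1))
  with_seed(derive_seed(seed, paste0("sensor-", animal_id)), {
    n <- nrow(track)
    # --- ODBA windows on the continuous 15-s grid
    meas_odba <- pmax(track$odba + stats::rnorm(n, 0, config$odba_noise_sd), 0)
    win <- (track$time - track$time[1]) %/% 15
    odba_dt <- data.table::data.table(w = win, v = meas_odba)[
      , .(window_start = track$time[1] + w[1] * 15, mean = mean(v),
          max = max(v), variance = stats::var(v)), by = w][, -"w"]

    # --- adaptive fix schedule: activity re-evaluated at every 15-s window
    # boundary, so the fast rate engages as soon as ODBA indicates activity
    active_setting <- sample(config$fix_active_min, 1) * 60
    t0 <- track$time[1]
    fix_t <- numeric(0); fix_x <- numeric(0); fix_y <- numeric(0)
    last_xy <- NULL; t_last <- -Inf
    for (w in seq_len(nrow(odba_dt))) {
      t_abs <- odba_dt$window_start[w]
      active <- odba_dt$mean[w] > config$activity_threshold
      interval <- if (active) active_setting else config$fix_inactive_min * 60
      if (t_abs - t_last < interval) next
      i <- as.integer(t_abs - t0) + 1L
      mx <- track$x[i] + stats::rnorm(1, 0, config$noise_sd_m)
      my <- track$y[i] + stats::rnorm(1, 0, config$noise_sd_m)
      spike <- stats::runif(1) < config$spike_rate
      if (spike) {
        mag <- stats::runif(1, config$spike_min_m, config$spike_max_m)
        ang <- stats::runif(1, -pi, pi)
        mx <- mx + mag * cos(ang); my <- my + mag * sin(ang)
      }
      t_last <- t_abs
      keep <- is.null(last_xy) ||
        sqrt((mx - last_xy[1])^2 + (my - last_xy[2])^2) > config$geofence_m
      if (keep) {
        fix_t <- c(fix_t, t_abs); fix_x <- c(fix_x, mx); fix_y <- c(fix_y, my)
        last_xy <- c(mx, my)
      }
    }
    structure(list(animal_id = animal_id,
                   fixes = data.frame(time = fix_t, x = fix_x, y = fix_y),
                   odba_windows = as.data.frame(odba_dt),
                   active_setting_s = active_setting),
              class = "ews_sensor_track")
  })
}

#' @export
print.ews_sensor_track <- function(x, ...) {
  cat(sprintf("<ews_sensor_track %s: %d fixes, %d ODBA windows>\n",
              x$animal_id, nrow(x$fixes), nrow(x$odba_windows)))
  invisible(x)
}

#' Degrade every animal of a simulated herd
#' @param tracks an `ews_true_tracks`
#' @param config an `ews_config`
#' @param seed integer seed
#' @return list of `ews_sensor_track`, one per animal
#' @export
degrade_tracks <- function(tracks, config, seed = config$seed) {
  ids <- tracks$animals$animal_id
  lapply(seq_along(ids), function(a) {
    degrade_to_sensor(
      data.frame(time = tracks$times, x = tracks$x[, a], y = tracks$y[, a],
                 odba = tracks$odba[, a]),
      config, seed, animal_id = ids[a])
  })
}

#' Write / read a sensor track as CSV (ISO-8601 timestamps)
#' @param st an `ews_sensor_track`
#' @param path_fixes,path_odba output paths
#' @export
write_sensor_track <- function(st, path_fixes, path_odba) {
  f <- st$fixes
  f$time <- format(as.POSIXct(f$time, origin = "1970-01-01", tz = "UTC"),
                   "%Y-%m-%dT%H:%M:%SZ")
  utils::write.csv(cbind(animal_id = st$animal_id, f), path_fixes, row.names = FALSE)
  o <- st$odba_windows
  o$window_start <- format(as.POSIXct(o$window_start, origin = "1970-01-01", tz = "UTC"),
                           "%Y-%m-%dT%H:%M:%SZ")
  utils::write.csv(cbind(animal_id = st$animal_id, o), path_odba, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_sensor_track
#' @export
read_sensor_track <- function(path_fixes, path_odba) {
  f <- utils::read.csv(path_fixes)
  o <- utils::read.csv(path_odba)
  parse_t <- function(s) as.numeric(as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  structure(list(animal_id = f$animal_id[1],
                 fixes = data.frame(time = parse_t(f$time), x = f$x, y = f$y),
                 odba_windows = data.frame(window_start = parse_t(o$window_start),
                                           mean = o$mean, max = o$max,
                                           variance = o$variance)),
            class = "ews_sensor_track")
}
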