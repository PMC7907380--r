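#' Simulate undisturbed multi-species herds
#'
#' Correlated random walk with three-zone herd interactions (repulsion /
#' alignment / cohesion) at 1-s resolution. Step speeds are drawn from a
#' species-specific lognormal moving-speed distribution, gated by a
#' persistent move/rest process, and scaled by local habitat suitability.
#' Animals leaving the landscape bounding box are reflected (count kept in
#' `attr(, "reflections")`).
#'
#' @param landscape an `ews_landscape`
#' @param config an `ews_config`
#' @param duration_s simulated duration in seconds
#' @param start_time segment start as UTC seconds (drives the time-of-day bin)
#' @param seed integer seed (defaults to `config$seed`)
#' @return an `ews_true_tracks` object: per-second position, heading, speed,
#'   true ODBA intensity, and behavior label (0 undisturbed, 1 flight,
#'   2 regroup) per animal
#' @export
simulate_herds <- function(landscape, config, duration_s = 7200,
                           start_time = 0, seed = config$seed) {
  simulate_herd_core(landscape, config, duration_s, start_time, seed,
                     intrusion = NULL)
}

#' Plant behavioral responses to an intrusion
#'
#' Re-runs the seeded herd dynamics that produced `tracks` with an intruder
#' present: animals coming within the detection radius switch to a flight
#' state (heading rotated away from the intruder, speed multiplied, turning
#' noise reduced, alignment raised, ODBA raised) for a species-specific
#' random duration, followed by a regroup phase with boosted cohesion. The
#' random number stream is consumed identically with and without the
#' intruder, so an intruder that never triggers any animal returns tracks
#' identical to the input.
#'
#' @param tracks an `ews_true_tracks` from [simulate_herds()]
#' @param intrusion an `ews_intrusion` from [generate_intrusion()]
#' @param config an `ews_config` (response fields are honoured;
#'   `response_enabled = FALSE` keeps the trigger bookkeeping — labels,
#'   intensities — but neutralizes every behavioral effect, which is the
#'   null world used for pipeline calibration)
#' @return an `ews_true_tracks` with labels/intensities filled in
#' @export
apply_response_model <- function(tracks, intrusion, config) {
  a <- attributes(tracks)
  simulate_herd_core(a$landscape, config, a$duration_s, a$start_time,
                     a$seed, intrusion = intrusion)
}

# shared seeded engine; intrusion = NULL gives undisturbed dynamics
simulate_herd_core <- function(landscape, config, duration_s, start_time,
                               seed, intrusion = NULL) {
  sp_names <- names(config$n_per_species)
  stopifnot(all(config$n_per_species >= 2))
  n <- sum(config$n_per_species)
  species <- rep(sp_names, config$n_per_species)
  # each species splits into herds_per_species herds (>= 2 animals each)
  hps <- max(1, config$herds_per_species %||% 1)
  herd_id <- integer(n)
  off <- 0L
  for (si in seq_along(sp_names)) {
    ns <- config$n_per_species[si]
    k <- max(1, min(hps, ns %/% 2))
    herd_id[off + seq_len(ns)] <- (si - 1) * hps + rep_len(seq_len(k), ns)
    off <- off + ns
  }
  herds <- split(seq_len(n), herd_id)
  tod <- time_of_day_bin(start_time)
  eff <- response_effects(config)

  # species-level lognormal speed parameters
  spl <- config$species[species]
  m <- vapply(spl, `[[`, 1, "speed_mean"); s <- vapply(spl, `[[`, 1, "speed_sd")
  lmu <- log(m^2 / sqrt(m^2 + s^2)); lsd <- sqrt(log(1 + s^2 / m^2))
  p_move <- vapply(spl, `[[`, 1, "p_move")

  # flight durations / intensities from separate per-run streams so the main
  # stream is untouched by trigger bookkeeping
  resp_draws <- with_seed(derive_seed(seed, "response-draws"), {
    lapply(seq_len(n), function(a) {
      fm <- spl[[a]]$flight_mean_min * 60; fs <- spl[[a]]$flight_sd_min * 60
      mu <- log(fm^2 / sqrt(fm^2 + fs^2)); sg <- sqrt(log(1 + fs^2 / fm^2))
      list(dur = stats::rlnorm(50, mu, sg),
           # how visually pronounced each response is (1 low .. 3 high)
           int = sample(1:3, 50, replace = TRUE, prob = c(0.25, 0.4, 0.35)))
    })
  })

  intr_xy <- if (!is.null(intrusion)) intruder_positions(intrusion, start_time, duration_s)

  T_ <- as.integer(duration_s)
  X <- matrix(NA_real_, T_, n); Y <- matrix(NA_real_, T_, n)
  H <- matrix(NA_real_, T_, n); S <- matrix(NA_real_, T_, n)
  OD <- matrix(NA_real_, T_, n)
  LBL <- matrix(0L, T_, n); INT <- matrix(0L, T_, n)
  reflections <- 0L

  dur_mat <- vapply(resp_draws, function(r) r$dur, numeric(50))
  int_mat <- vapply(resp_draws, function(r) r$int, integer(50))
  suit_mat <- vapply(sp_names, function(sp)
    as.vector(landscape$suitability[[sp]][[tod]]), numeric(landscape$n^2))
  suit_col <- match(species, sp_names)
  bb <- landscape$bbox

  reflections <- with_seed(derive_seed(seed, "herds"), {
    # herd starting positions: cluster per herd around a random interior point
    cx <- stats::runif(length(herds), bb$xmin + 500, bb$xmax - 500)
    cy <- stats::runif(length(herds), bb$ymin + 500, bb$ymax - 500)
    x <- cx[herd_id] + stats::rnorm(n, 0, 50)
    y <- cy[herd_id] + stats::rnorm(n, 0, 50)
    h <- stats::runif(n, -pi, pi)
    moving <- stats::runif(n) < p_move
    res <- herd_sim_core(
      T_, n, x, y, h, moving, as.integer(herd_id),
      lmu, lsd, p_move, m, suit_mat, as.integer(suit_col),
      landscape$origin[["x"]], landscape$origin[["y"]], landscape$cell_m,
      landscape$n,
      config$repulsion_radius, config$alignment_radius,
      config$repulsion_weight, config$alignment_weight,
      config$cohesion_weight, config$persistence_weight,
      config$turn_sd, config$speed_suitability_coupling,
      bb$xmin, bb$xmax, bb$ymin, bb$ymax,
      !is.null(intr_xy),
      if (is.null(intr_xy)) numeric(T_) else intr_xy$x,
      if (is.null(intr_xy)) numeric(T_) else intr_xy$y,
      if (is.null(intr_xy)) logical(T_) else intr_xy$active,
      config$detection_radius_m, dur_mat, int_mat,
      eff$active, eff$speed_mult, eff$turn_sd_flight, eff$align_mult,
      eff$odba_mult, eff$flee_weight, eff$regroup_cohesion_mult,
      config$regroup_duration_min * 60,
      X, Y, H, S, OD, LBL, INT)
    as.integer(res$reflections)
  })

  structure(list(
    animals = data.frame(animal_id = sprintf("%s_%02d", species, seq_len(n)),
                         species = species, herd_id = herd_id,
                         stringsAsFactors = FALSE),
    x = X, y = Y, heading = H, speed = S, odba = OD,
    label = LBL, intensity = INT,
    times = start_time + seq_len(T_) - 1
  ), class = "ews_true_tracks",
  landscape = landscape, duration_s = duration_s, start_time = start_time,
  seed = seed, reflections = reflections, tod = tod)
}

response_effects <- function(config) {
  if (isTRUE(config$response_enabled)) {
    list(active = TRUE,
         speed_mult = config$flight_speed_mult,
         turn_sd_flight = config$flight_turn_sd,
         align_mult = config$flight_align_mult,
         odba_mult = config$flight_odba_mult,
         flee_weight = 4, regroup_cohesion_mult = 4,
         duration_scale = 1,
         persistence = function(fl) ifelse(fl, 2 * config$persistence_weight,
                                           config$persistence_weight))
  } else {
    # null world: triggers and labels recorded, dynamics untouched
    list(active = FALSE,
         speed_mult = 1, turn_sd_flight = config$turn_sd, align_mult = 1,
         odba_mult = 1, flee_weight = 0, regroup_cohesion_mult = 1,
         duration_scale = 1,
         persistence = function(fl) config$persistence_weight)
  }
}

suitability_at <- function(landscape, x, y, species, tod) {
  ij <- cell_index(landscape, x, y)
  out <- numeric(length(x))
  for (sp in unique(species)) {
    k <- species == sp
    out[k] <- landscape$suitability[[sp]][[tod]][ij[k, , drop = FALSE]]
  }
  out
}

#' Time-of-day bin from UTC seconds
#'
#' Fixed local clock intervals: morning 05-10h, midday 10-15h,
#' afternoon 15-20h (anything else folds into the nearest bin).
#' @param time UTC seconds
#' @return character bin
#' @export
time_of_day_bin <- function(time) {
  hr <- (time / 3600) %% 24
  ifelse(hr < 10, "morning", ifelse(hr < 15, "midday", "afternoon"))[1]
}

#' Convert true tracks to a long data.table
#' @param tracks an `ews_true_tracks`
#' @param every_s keep one row per `every_s` seconds
#' @return data.table with animal_id, species, time, x, y, heading, speed,
#'   odba, label, intensity
#' @export
tracks_to_dt <- function(tracks, every_s = 1) {
  keep <- seq(1, length(tracks$times), by = every_s)
  n <- nrow(tracks$animals)
  data.table::data.table(
    animal_id = rep(tracks$animals$animal_id, each = length(keep)),
    species = rep(tracks$animals$species, each = length(keep)),
    time = rep(tracks$times[keep], n),
    x = as.vector(tracks$x[keep, ]), y = as.vector(tracks$y[keep, ]),
    heading = as.vector(tracks$heading[keep, ]),
    speed = as.vector(tracks$speed[keep, ]),
    odba = as.vector(tracks$odba[keep, ]),
    label = as.vector(tracks$label[keep, ]),
    intensity = as.vector(tracks$intensity[keep, ])
  )
}
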