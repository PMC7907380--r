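#' Default simulation configuration
#'
#' Bundles every tunable of the synthetic world: herd composition and
#' interaction weights, species movement distributions, behavioral-response
#' parameters (flight duration means/SDs per species), and the sensor model
#' (adaptive fix schedule, geofence, positional noise, spike outliers).
#'
#' Flight duration means default to the observed per-species means
#' (zebra 47, wildebeest 39, eland 46, impala 43 min, with SDs 28/33/18/14).
#'
#' @param seed master seed; per-stage seeds are derived from it
#' @param n_per_species named integer vector, animals per species (one herd
#'   per species by default)
#' @param ... overrides for any configuration entry
#' @return a `ews_config` list
#' @export
ews_config <- function(seed = 1L,
                       n_per_species = c(zebra = 10, wildebeest = 10),
                       ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_per_species = n_per_species,
    herds_per_species = 2,      # animals per species split into this many herds
    # herd interaction model (three-zone): radii in m, weights dimensionless
    repulsion_radius = 8,
    alignment_radius = 60,
    cohesion_radius = 300,
    repulsion_weight = 1.5,
    alignment_weight = 0.35,
    cohesion_weight = 0.25,
    persistence_weight = 1.0,
    turn_sd = 0.35,             # rad, per 1-s step, undisturbed
    # species mean step speed while moving (m/s) and rest probability
    species = list(
      zebra      = list(speed_mean = 0.55, speed_sd = 0.35, p_move = 0.55,
                        flight_mean_min = 47, flight_sd_min = 28),
      wildebeest = list(speed_mean = 0.50, speed_sd = 0.30, p_move = 0.50,
                        flight_mean_min = 39, flight_sd_min = 33),
      eland      = list(speed_mean = 0.45, speed_sd = 0.30, p_move = 0.50,
                        flight_mean_min = 46, flight_sd_min = 18),
      impala     = list(speed_mean = 0.40, speed_sd = 0.25, p_move = 0.55,
                        flight_mean_min = 43, flight_sd_min = 14)
    ),
    speed_suitability_coupling = 0.6,  # speed scale = (1-c) + c * suitability
    # behavioral response model
    response_enabled = TRUE,
    detection_radius_m = 300,   # distance at which animals perceive the intruder
    flight_speed_mult = 3,
    flight_turn_sd = 0.12,      # rad: straighter during flight
    flight_align_mult = 3,      # alignment weight multiplier during flight
    flight_odba_mult = 3,
    regroup_duration_min = 10,
    regroup_dist_m = 60,        # inter-individual contraction threshold
    # sensor model
    noise_sd_m = 15,
    spike_rate = 0.01,          # per emitted fix
    spike_min_m = 500,
    spike_max_m = 1500,
    geofence_m = 5,
    fix_inactive_min = 15,
    fix_active_min = c(2, 10),  # two sensor settings, assigned per collar
    activity_threshold = 0.10,  # windowed mean ODBA gating the fast schedule
    odba_noise_sd = 0.03,
    # landscape
    extent_m = 3000,
    cell_m = 10
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "ews_config")
}

#' @export
print.ews_config <- function(x, ...) {
  cat("<ews_config> seed", x$seed, "|",
      paste(names(x$n_per_species), x$n_per_species, collapse = ", "),
      "| response", if (isTRUE(x$response_enabled)) "on" else "off", "\n")
  invisible(x)
}

#' Read / write a simulation configuration as YAML
#' @param path file path
#' @param config an `ews_config`
#' @return `read_config` returns an `ews_config`
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$n_per_species <- as.list(out$n_per_species)  # keep names in YAML
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(ews_config, list(seed = raw$seed))
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$n_per_species <- unlist(raw$n_per_species)
  stopifnot(all(vapply(cfg[c("noise_sd_m", "spike_rate", "geofence_m")],
                       function(v) v >= 0, logical(1))))
  cfg
}
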