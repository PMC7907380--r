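# Shared small fixtures, built in code at test time.

# small world: 2 species x 6 animals, 40 min — fast enough for unit tests
small_config <- function(seed = 5) {
  ews_config(seed = seed, n_per_species = c(zebra = 6, wildebeest = 6))
}

small_world <- local({
  cache <- new.env()
  function(seed = 5, duration_s = 2400) {
    key <- paste0("w", seed, "_", duration_s)
    if (is.null(cache[[key]])) {
      cfg <- small_config(seed)
      ls1 <- generate_landscape(seed, 2000, 10,
                                species = names(cfg$n_per_species))
      tr <- simulate_herds(ls1, cfg, duration_s = duration_s,
                           start_time = 6 * 3600)
      cache[[key]] <- list(config = cfg, landscape = ls1, tracks = tr)
    }
    cache[[key]]
  }
})

# straight-transect sensor track with optional injected spikes; mirrors the
# airstrip test used to validate the spike corrector
make_transect <- function(n = 200, dt = 60, speed = 5, noise_sd = 0,
                          n_spikes = 0, seed = 1) {
  set.seed(seed)
  tm <- seq(0, by = dt, length.out = n)
  x <- speed * tm + rnorm(n, 0, noise_sd)
  y <- rnorm(n, 0, noise_sd)
  spike_idx <- integer()
  if (n_spikes > 0) {
    # non-adjacent interior fixes so each spike has clean neighbours
    spike_idx <- sort(sample(seq(2, n - 1, by = 3), n_spikes))
    mag <- runif(n_spikes, 600, 1500)
    ang <- runif(n_spikes, -pi, pi)
    x[spike_idx] <- x[spike_idx] + mag * cos(ang)
    y[spike_idx] <- y[spike_idx] + mag * sin(ang)
  }
  ow <- data.frame(window_start = seq(0, max(tm), 15))
  ow$mean <- 0.3; ow$max <- 0.4; ow$variance <- 0.01
  list(track = structure(list(animal_id = "transect",
                              fixes = data.frame(time = tm, x = x, y = y),
                              odba_windows = ow),
                         class = "ews_sensor_track"),
       spike_idx = spike_idx,
       truth = data.frame(time = tm, x = speed * tm, y = 0))
}

# cached tiny study (2 intrusions) reused across module tests
tiny_study <- local({
  cache <- new.env()
  function(seed = 21, response = TRUE) {
    key <- paste0("s", seed, "_", response)
    if (is.null(cache[[key]])) {
      cfg <- ews_config(seed = seed,
                        n_per_species = c(zebra = 8, wildebeest = 8),
                        response_enabled = response)
      cache[[key]] <- simulate_study(cfg, n_intrusions = 3, duration_s = 3600)
    }
    cache[[key]]
  }
})
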