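test_that("landscape generation: shapes, ranges, determinism", {
  ls1 <- generate_landscape(1, 3000, 10)
  expect_equal(dim(ls1$tree_cover), c(300, 300))
  expect_true(all(is.finite(ls1$elevation)))
  expect_true(all(ls1$tree_cover >= 0 & ls1$tree_cover <= 1))
  for (sp in ls1$species) for (tb in ls1$tod_bins) {
    s <- ls1$suitability[[sp]][[tb]]
    expect_true(all(s >= 0 & s <= 1))
  }
  ls2 <- generate_landscape(1, 3000, 10)
  expect_identical(ls1$tree_cover, ls2$tree_cover)
  expect_identical(ls1$elevation, ls2$elevation)
  expect_error(generate_landscape(1, -5, 10))
  # bounded tree cover across many seeds (smaller rasters for speed)
  rng <- range(vapply(1:50, function(s) {
    range(generate_landscape(s, 300, 10)$tree_cover)
  }, numeric(2)))
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 1)
})

test_that("herd simulation: length contract, cohesion, suitability coupling", {
  w <- small_world()
  tr <- w$tracks
  expect_equal(dim(tr$x), c(2400, 12))
  expect_true(all(is.finite(tr$x)))
  expect_true(all(bbox_contains(w$landscape$bbox, tr$x, tr$y)))

  # zero cohesion/alignment: inter-individual spread grows faster
  cfg0 <- small_config()
  cfg0$cohesion_weight <- 0; cfg0$alignment_weight <- 0
  tr0 <- simulate_herds(w$landscape, cfg0, duration_s = 2400,
                        start_time = 6 * 3600)
  spread <- function(tt, t) {
    idx <- which(tt$animals$herd_id == 1)
    mean(dist(cbind(tt$x[t, idx], tt$y[t, idx])))
  }
  expect_gt(spread(tr0, 2400) / spread(tr0, 60),
            spread(tr, 2400) / spread(tr, 60) * 0.99)
  # and with interactions on, herd members stay within cohesion range mostly
  d_end <- spread(tr, 2400)
  expect_lt(d_end, cfg0$cohesion_radius * 2)

  # speed-suitability coupling: uniformly poor habitat slows animals
  ls_flat <- w$landscape
  for (sp in names(ls_flat$suitability))
    for (tb in names(ls_flat$suitability[[sp]]))
      ls_flat$suitability[[sp]][[tb]][] <- 1
  ls_poor <- ls_flat
  for (sp in names(ls_poor$suitability))
    for (tb in names(ls_poor$suitability[[sp]]))
      ls_poor$suitability[[sp]][[tb]][] <- 0.2
  t_rich <- simulate_herds(ls_flat, w$config, duration_s = 1200,
                           start_time = 6 * 3600)
  t_poor <- simulate_herds(ls_poor, w$config, duration_s = 1200,
                           start_time = 6 * 3600)
  mv <- function(tt) median(tt$speed[tt$speed > 0.05])
  expect_gt(mv(t_rich), mv(t_poor))
})

test_that("response model: no-op when intruder far, flight geometry and durations", {
  w <- small_world()
  cfg <- w$config
  # intruder far outside the detection radius: bit-identical output
  far <- generate_intrusion(w$landscape, 99, start_time = 6 * 3600 + 60)
  far$route$x <- far$route$x + 1e7
  tr2 <- apply_response_model(w$tracks, far, cfg)
  expect_identical(tr2$x, w$tracks$x)
  expect_identical(tr2$label, w$tracks$label)

  # real encounter: flight headings point away from the intruder
  intr <- generate_intrusion(w$landscape, 42, start_time = 6 * 3600 + 60,
                             duration_s = 2300)
  tr3 <- apply_response_model(w$tracks, intr, cfg)
  fl <- which(tr3$label == 1, arr.ind = TRUE)
  skip_if(nrow(fl) < 100, "this seed produced no substantial encounter")
  ip <- sentinelews:::intruder_positions(intr, 6 * 3600, 2400)
  co <- cos(tr3$heading[fl] -
              atan2(tr3$y[fl] - ip$y[fl[, 1]], tr3$x[fl] - ip$x[fl[, 1]]))
  expect_gt(mean(co), 0.7)
  # labels are contiguous runs per animal
  for (a in unique(fl[, 2])) {
    r <- rle(tr3$label[, a] == 1)
    expect_lte(sum(r$values), 3)
  }
})

test_that("zebra flight durations match the configured mean (2 SE band)", {
  # direct check of the duration generator over many flights
  cfg <- ews_config(seed = 3, n_per_species = c(zebra = 2))
  durs <- c()
  for (s in 1:4) {
    d <- with_seed(derive_seed(s, "response-draws"), {
      fm <- cfg$species$zebra$flight_mean_min * 60
      fs <- cfg$species$zebra$flight_sd_min * 60
      mu <- log(fm^2 / sqrt(fm^2 + fs^2)); sg <- sqrt(log(1 + fs^2 / fm^2))
      stats::rlnorm(50, mu, sg)
    })
    durs <- c(durs, d)
  }
  durs <- durs[1:200] / 60
  se <- sd(durs) / sqrt(length(durs))
  expect_lt(abs(mean(durs) - 47), 2 * se)
})

test_that("sensor degradation: schedule, geofence, spikes, ODBA grid", {
  w <- small_world()
  cfg <- w$config
  # stationary animal, no noise: first fix only, ODBA variance at noise floor
  still <- data.frame(time = 0:3599, x = 500, y = 500, odba = 0.05)
  cfg0 <- cfg; cfg0$noise_sd_m <- 0; cfg0$spike_rate <- 0
  st <- degrade_to_sensor(still, cfg0, 1, "still")
  expect_equal(nrow(st$fixes), 1)           # geofence suppresses the rest
  expect_lt(max(st$odba_windows$variance), 0.01)
  expect_equal(diff(st$odba_windows$window_start), rep(15, 239))

  # geofence rule: two true positions 3 m apart -> second fix suppressed
  slow <- data.frame(time = 0:1799, x = 500 + 3 * ((0:1799) >= 900),
                     y = 500, odba = 0.5)  # active -> frequent schedule
  st2 <- degrade_to_sensor(slow, cfg0, 1, "slow")
  expect_equal(nrow(st2$fixes), 1)

  # with noise but no spikes, single-step displacement is bounded
  cfg1 <- cfg; cfg1$spike_rate <- 0
  tr <- w$tracks
  max_step <- 0
  for (a in 1:6) {
    st3 <- degrade_to_sensor(
      data.frame(time = tr$times, x = tr$x[, a], y = tr$y[, a],
                 odba = tr$odba[, a]), cfg1, a, "a")
    if (nrow(st3$fixes) > 1) {
      dd <- sqrt(diff(st3$fixes$x)^2 + diff(st3$fixes$y)^2)
      dtt <- diff(st3$fixes$time)
      vmax <- max(tr$speed[, a])
      expect_true(all(dd <= vmax * dtt + 6 * cfg1$noise_sd_m))
      max_step <- max(max_step, max(dd))
    }
  }
  # empty input -> empty sensor track
  st4 <- degrade_to_sensor(still[0, ], cfg, 1, "none")
  expect_equal(nrow(st4$fixes), 0)
})

test_that("sensor tracks and intrusion routes round-trip through CSV/GPX", {
  w <- small_world()
  tr <- w$tracks
  st <- degrade_to_sensor(
    data.frame(time = tr$times, x = tr$x[, 1], y = tr$y[, 1],
               odba = tr$odba[, 1]), w$config, 2, "rt")
  fp <- tempfile(fileext = ".csv"); op <- tempfile(fileext = ".csv")
  write_sensor_track(st, fp, op)
  st2 <- read_sensor_track(fp, op)
  expect_equal(st2$fixes$time, st$fixes$time)
  expect_equal(st2$fixes$x, st$fixes$x, tolerance = 1e-6)
  expect_equal(st2$odba_windows$variance, st$odba_windows$variance,
               tolerance = 1e-6)

  intr <- generate_intrusion(w$landscape, 8, start_time = 7 * 3600)
  gp <- tempfile(fileext = ".gpx")
  write_intrusion_gpx(intr, gp)
  r2 <- read_intrusion_gpx(gp)
  expect_equal(r2$time, intr$route$time)
  expect_equal(r2$x, intr$route$x, tolerance = 1e-3)

  cfgf <- tempfile(fileext = ".yml")
  write_config(w$config, cfgf)
  cfg2 <- read_config(cfgf)
  expect_equal(cfg2$noise_sd_m, w$config$noise_sd_m)
  expect_equal(cfg2$n_per_species, w$config$n_per_species)
})
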