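test_that("gross-error filter removes out-of-area and over-speed fixes", {
  bb <- ews_bbox(0, 2000, -1000, 1000)
  tt <- make_transect(n = 50, speed = 0.5)
  st <- tt$track
  st$fixes$x[10] <- 5e4                      # 50 km out
  st1 <- filter_gross_errors(st, bb, prep_options(bbox_margin_m = 100))
  expect_equal(attr(st1, "n_removed"), 1)
  # clean track unchanged
  clean <- make_transect(n = 30, speed = 0.5)$track
  st2 <- filter_gross_errors(clean, bb)
  expect_equal(attr(st2, "n_removed"), 0)
  expect_equal(st2$fixes, clean$fixes)
  # three injected far-out fixes -> exactly three removals
  st3 <- clean
  st3$fixes$x[c(5, 12, 20)] <- -9e5
  st3 <- filter_gross_errors(st3, bb)
  expect_equal(attr(st3, "n_removed"), 3)
})

test_that("spike criteria: constructed spike flagged, straight run not", {
  mk <- function(xy) structure(list(animal_id = "t",
                                    fixes = data.frame(time = c(0, 60, 120),
                                                       x = xy[, 1], y = xy[, 2]),
                                    odba_windows = data.frame()),
                               class = "ews_sensor_track")
  sp <- correct_spikes(mk(cbind(c(0, 0, 0), c(0, 600, 10))))
  expect_equal(nrow(sp$diagnostics), 1)
  expect_equal(sp$diagnostics$fix, 2)
  # shifted towards (0, 5), strictly closer than before
  expect_lt(abs(sp$track$fixes$y[2] - 5), abs(600 - 5))
  expect_lt(sp$track$fixes$y[2], 300)
  no <- correct_spikes(mk(cbind(c(0, 600, 1200), c(0, 0, 0))))
  expect_equal(nrow(no$diagnostics), 0)
  expect_equal(no$track$fixes$x, c(0, 600, 1200))
})

test_that("airstrip transect: >=95% of injected spikes flagged, RMSE reduced", {
  # slow transect: neighbour fixes stay close (criterion b attainable)
  tt <- make_transect(n = 300, speed = 0.5, noise_sd = 5, n_spikes = 90,
                      seed = 42)
  res <- correct_spikes(tt$track)
  flagged <- res$diagnostics$fix
  recall <- mean(tt$spike_idx %in% flagged)
  expect_gte(recall, 0.95)
  rmse <- function(f) sqrt(mean((f$x - tt$truth$x)^2 + (f$y - tt$truth$y)^2))
  expect_lt(rmse(res$track$fixes), rmse(tt$track$fixes))
  # spike-free tracks: no false flags at default thresholds
  n_flags <- 0
  for (s in 1:100) {
    cl <- make_transect(n = 40, speed = 3, noise_sd = 10, seed = s)
    n_flags <- n_flags + nrow(correct_spikes(cl$track)$diagnostics)
  }
  expect_equal(n_flags, 0)
})

test_that("Kalman smoother: exact on linear motion, reduces noise, constant-safe", {
  lin <- make_transect(n = 60, speed = 4, noise_sd = 0)
  sm <- kalman_smooth(lin$track)
  expect_equal(sm$fixes$x, lin$track$fixes$x, tolerance = 0.5)
  expect_equal(sm$fixes$y, lin$track$fixes$y, tolerance = 0.5)

  noisy <- make_transect(n = 120, speed = 4, noise_sd = 25, seed = 7)
  sm2 <- kalman_smooth(noisy$track)
  rmse <- function(f) sqrt(mean((f$x - noisy$truth$x)^2 + (f$y - noisy$truth$y)^2))
  expect_lt(rmse(sm2$fixes), rmse(noisy$track$fixes))

  const <- make_transect(n = 30, speed = 0, noise_sd = 0)
  sm3 <- kalman_smooth(const$track)
  expect_equal(sd(sm3$fixes$x), 0, tolerance = 1e-6)
  expect_error(kalman_smooth(make_transect(n = 3)$track))
})

test_that("ODBA-informed interpolation allocates movement to active slots", {
  # one 10-min gap; ODBA high only in the second half
  fixes <- data.frame(time = c(0, 600), x = c(0, 100), y = 0)
  ow <- data.frame(window_start = seq(0, 600, 15), mean = 0.02,
                   max = 0.02, variance = 0)
  ow$mean[ow$window_start >= 300] <- 0.5
  st <- structure(list(animal_id = "g", fixes = fixes, odba_windows = ow),
                  class = "ews_sensor_track")
  d <- odba_interpolate(st)
  # first half stationary at origin, movement in second half only
  expect_lt(max(d$x[d$time <= 290]), 1)
  expect_gt(d$x[d$time == 310], 0)
  expect_equal(d$x[nrow(d)], 100)

  # all-stationary gap: points stay at the start until the terminal fix
  ow2 <- ow; ow2$mean <- 0.02
  st2 <- st; st2$odba_windows <- ow2
  d2 <- odba_interpolate(st2)
  expect_lt(max(abs(d2$x[-nrow(d2)])), 1e-6)
  expect_equal(d2$x[nrow(d2)], 100)

  # uniformly active gap reduces to plain linear interpolation
  ow3 <- ow; ow3$mean <- 0.5
  st3 <- st; st3$odba_windows <- ow3
  d3 <- odba_interpolate(st3)
  lin <- approx(c(0, 600), c(0, 100), xout = d3$time)$y
  expect_equal(d3$x, lin, tolerance = 1)

  # missing ODBA -> plain linear, flagged
  st4 <- st; st4$odba_windows <- ow[0, ]
  d4 <- odba_interpolate(st4)
  expect_true(all(d4$odba_gap[-1]))
  expect_equal(d4$x, approx(c(0, 600), c(0, 100), xout = d4$time)$y,
               tolerance = 1e-6)
})

test_that("X-spline resampling: regular grid, collinear preserved", {
  tt <- make_transect(n = 40, speed = 3)
  dens <- odba_interpolate(tt$track)
  rt <- xspline_resample(dens, tt$track$odba_windows, animal_id = "t")
  expect_true(all(rt$time %% 60 == 0))
  expect_equal(diff(rt$time), rep(60, nrow(rt) - 1))
  # collinear input stays collinear (y identically ~0 here)
  expect_lt(max(abs(rt$y)), 1)
  fit <- lm(rt$x ~ rt$time)
  expect_equal(unname(coef(fit)[2]) * 60, 180, tolerance = 2)
  # ODBA stats carried onto steps
  expect_true(all(is.finite(rt$odba_mean)))
  expect_error(xspline_resample(dens[1:2, ], tt$track$odba_windows))
})

test_that("full pipeline: 60-s regular output that beats the raw sensor", {
  w <- small_world(seed = 9, duration_s = 7200)
  tr <- w$tracks
  err_rec <- c(); err_raw <- c()
  for (a in 1:8) {
    st <- degrade_to_sensor(
      data.frame(time = tr$times, x = tr$x[, a], y = tr$y[, a],
                 odba = tr$odba[, a]), w$config, a, paste0("a", a))
    rt <- suppressWarnings(preprocess_track(st, w$landscape$bbox))
    if (is.null(rt)) next
    expect_equal(diff(rt$time), rep(60, nrow(rt) - 1))
    idx <- match(rt$time, tr$times)
    err_rec <- c(err_rec, sqrt((rt$x - tr$x[idx, a])^2 + (rt$y - tr$y[idx, a])^2))
    fi <- match(st$fixes$time, tr$times)
    err_raw <- c(err_raw, sqrt((st$fixes$x - tr$x[fi, a])^2 +
                                 (st$fixes$y - tr$y[fi, a])^2))
  }
  expect_gt(length(err_rec), 100)
  # minute-resolution reconstruction beats the raw measured fixes
  expect_lt(median(err_rec), median(err_raw))
})

test_that("pipeline is near-idempotent on clean regular tracks", {
  tt <- make_transect(n = 60, speed = 2, noise_sd = 0)
  st1 <- suppressWarnings(preprocess_track(tt$track, ews_bbox(-1e4, 1e5, -1e4, 1e4)))
  idx <- match(st1$time, tt$truth$time)
  expect_lt(max(abs(st1$x - tt$truth$x[idx])), 5)
  # monotone timestamps, no extrapolation beyond observed range
  expect_true(all(diff(st1$time) > 0))
  expect_gte(min(st1$time), min(tt$track$fixes$time))
  expect_lte(max(st1$time), max(tt$track$fixes$time))
})

test_that("intrusion decimation yields 1-min synchronized routes", {
  w <- small_world()
  intr <- generate_intrusion(w$landscape, 3, start_time = 6 * 3600)
  d <- decimate_intrusion(intr)
  expect_true(all(d$time %% 60 == 0))
  chk <- intrusion_at(intr, d$time)
  expect_equal(d$x, chk$x, tolerance = 1e-9)
})
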