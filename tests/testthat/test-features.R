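test_that("individual geometry identities: straight line, random walk, circle", {
  # uniform straight motion at 1 m/s
  tm <- seq(0, 60 * 59, 60)
  straight <- data.frame(time = tm, x = 60 * seq_along(tm), y = 0)
  g <- individual_geometry(straight)
  expect_equal(g$speed[-1], rep(1, 59), tolerance = 1e-9)
  expect_equal(g$persistence[20], 1, tolerance = 1e-9)
  expect_equal(g$net_gross[20], 1, tolerance = 1e-9)
  expect_equal(g$msd_slope[30], 2, tolerance = 1e-6)  # ballistic MSD ~ t^2

  # pure random walk: net-gross small, MSD near linear in time
  set.seed(4)
  n <- 1000
  rw <- data.frame(time = seq(0, by = 60, length.out = n),
                   x = cumsum(rnorm(n, 0, 30)), y = cumsum(rnorm(n, 0, 30)))
  g2 <- individual_geometry(rw, window = 200)
  ng <- g2$net_gross[is.finite(g2$net_gross)]
  expect_lt(mean(ng), 0.35)
  ms <- g2$msd_slope[is.finite(g2$msd_slope)]
  expect_lt(abs(mean(ms) - 1), 0.35)       # diffusive exponent ~ 1

  # circle at constant speed: constant turning angle 2*pi / steps-per-lap
  k <- 36
  th <- 2 * pi * (0:(3 * k)) / k
  circ <- data.frame(time = seq(0, by = 60, length.out = length(th)),
                     x = 500 * cos(th), y = 500 * sin(th))
  g3 <- individual_geometry(circ)
  expect_equal(g3$turn_abs[10:20], rep(2 * pi / k, 11), tolerance = 1e-9)
})

test_that("accelerometer features: constants and missing windows", {
  tr <- data.frame(odba_mean = rep(0.3, 30), odba_max = 0.5, odba_var = 0)
  a <- accelerometer_features(tr)
  expect_equal(a$odba_mean, rep(0.3, 30))
  expect_equal(a$odba_mean_w[10], 0.3)
  expect_true(is.na(a$odba_mean_w[2]))      # insufficient history
})

test_that("collective features: identical movers, circular null, singleton", {
  two <- data.frame(x = c(0, 50), y = c(0, 0), heading = c(1, 1),
                    speed = c(2, 2))
  cf <- collective_features(two)
  expect_equal(cf$align, c(1, 1))
  expect_equal(cf$speed_sync, c(1, 1))
  expect_equal(cf$nn_dist, c(50, 50))

  # headings uniform on the circle: mean resultant length ~ sqrt(pi)/2/sqrt(n)
  set.seed(2)
  reps <- vapply(1:200, function(i) {
    n <- 101
    snap <- data.frame(x = runif(n, 0, 50), y = runif(n, 0, 50),
                       heading = runif(n, -pi, pi), speed = 1)
    collective_features(snap, radius = 1000)$align[1]
  }, 0)
  expect_lt(abs(mean(reps) - sqrt(pi) / 2 / sqrt(100)), 0.01)

  one <- collective_features(data.frame(x = 0, y = 0, heading = 0, speed = 1))
  expect_equal(one$density, 0)
  expect_true(is.na(one$align))
})

test_that("space use: Tobler function values and constant suitability", {
  expect_equal(tobler_speed(0), 6 * exp(-3.5 * 0.05), tolerance = 1e-12)
  expect_equal(tobler_speed(-0.05), 6)                 # stationary point
  expect_lt(tobler_speed(0.2), tobler_speed(0))
  w <- small_world()
  ls1 <- w$landscape
  for (tb in ls1$tod_bins) ls1$suitability$zebra[[tb]][] <- 0.5
  tr <- data.frame(time = seq(0, 540, 60),
                   x = seq(100, 1000, length.out = 10), y = 500)
  su <- space_use_features(tr, ls1, "zebra", "morning")
  expect_equal(su$suitability, rep(0.5, 10))
  expect_equal(su$suit_gradient[-1], rep(0, 9))
})

test_that("standardization: zero mean / unit variance on the reference pool", {
  st <- tiny_study()
  f <- prepare_features(st$minutes, st$landscape)
  fc <- contextualize_features(f)
  und <- fc$label == 0
  for (cl in c("speed__z_species", "odba_mean__z_species", "align__z_species")) {
    for (sp in unique(fc$species)) {
      v <- fc[[cl]][und & fc$species == sp]
      v <- v[is.finite(v)]
      expect_lt(abs(mean(v)), 0.05)
      expect_lt(abs(var(v) - 1), 0.12)
    }
  }
  # feature equal to its group mean -> z = 0 (via inversion identity)
  ref <- build_reference(fc, "species", "speed")
  g <- ref$stats[1, ]
  expect_equal(unstandardize(0, ref, g[, "species"], "speed"),
               g$speed.m, tolerance = 1e-12)
})

test_that("contextual standardization sharpens planted responses when normal behavior varies by habitat", {
  st <- tiny_study()
  f <- prepare_features(st$minutes, st$landscape)
  fc <- contextualize_features(f)
  resp <- fc$label > 0 & fc$intensity >= 2
  skip_if(sum(resp) < 50, "seed produced too few medium/high responses")
  m_global <- mean(abs(fc$speed__z_species[resp]), na.rm = TRUE)
  m_ctx <- mean(abs(fc$speed__z_area_timeofday_5wk[resp]), na.rm = TRUE)
  expect_gt(m_ctx, 0.8 * m_global)   # contextual deviation at least comparable
  # both deviate strongly from the undisturbed mean of ~0
  expect_gt(m_global, 0.8)
})

test_that("window features: constants, step change, insufficient history", {
  seg <- data.table::data.table(
    segment_id = "s", animal_id = "a", species = "zebra",
    time = seq(0, by = 60, length.out = 60),
    speed = c(rep(1, 30), rep(5, 30)))
  reg <- data.frame(column = "speed", base = "speed",
                    class = "individual_geometry", variant = "raw")
  data.table::setattr(seg, "registry", reg)
  w <- window_features(seg, columns = "speed")
  expect_true(all(is.na(w$speed__win_20l_mean[1:19])))
  cst <- w[time < 1500]
  expect_equal(cst$speed__win_5c_mean[10], 1)
  expect_equal(cst$speed__win_5c_sd[10], 0)
  # diff(5c - 20l) maximal shortly after the step at row 31
  d <- w$speed__win_diff_5c_20l
  expect_true(which.max(d) %in% 31:36)
  # brute-force check of one value
  expect_equal(w$speed__win_10l_mean[40], mean(seg$speed[31:40]))
})

test_that("truncation and ordinal discretization behave as quantile operations", {
  set.seed(8)
  n <- 100000
  dt <- data.table::data.table(species = "zebra", val = rnorm(n))
  reg <- data.frame(column = "val", base = "val", class = "accelerometer",
                    variant = "raw")
  data.table::setattr(dt, "registry", reg)
  out <- transform_truncate_discretize(dt, n_bins = 10, log_cols = character())
  n_changed <- sum(out$val != dt$val[seq_len(n)] - 0)  # winsorized entries
  expect_lte(n_changed, 2 * 0.001 * n + 2)
  # ~equal bin occupancy on continuous data
  tab <- table(out$val__ordinal)
  expect_equal(length(tab), 10)
  expect_lt(max(abs(tab / n - 0.1)), 0.005)
  # monotone transform preserves the bins
  dt2 <- data.table::data.table(species = "zebra", val = exp(dt$val))
  data.table::setattr(dt2, "registry", reg)
  out2 <- transform_truncate_discretize(dt2, n_bins = 10, log_cols = character())
  expect_equal(out2$val__ordinal, out$val__ordinal)
})

test_that("features are invariant to translating the world in space and time", {
  st <- tiny_study()
  m1 <- data.table::copy(st$minutes)[segment_id == segment_id[1]]
  m2 <- data.table::copy(m1)
  m2[, `:=`(x = x + 500, y = y + 500, true_x = true_x + 500,
            true_y = true_y + 500, time = time + 7 * 86400)]
  # landscape translated identically: reuse lookup by shifting its origin
  ls2 <- st$landscape
  ls2$origin <- c(x = 500, y = 500)
  ls2$bbox <- ews_bbox(500, 500 + ls2$n * ls2$cell_m,
                       500, 500 + ls2$n * ls2$cell_m)
  f1 <- compute_base_features(m1, st$landscape)
  f2 <- compute_base_features(m2, ls2)
  for (cl in c("speed", "turn_abs", "net_gross", "align", "nn_dist",
               "suitability", "cost_tobler")) {
    expect_equal(f2[[cl]], f1[[cl]], tolerance = 1e-5, label = cl)
  }
})

test_that("feature count is reported and stable under fixed configuration", {
  st <- tiny_study()
  f <- prepare_features(st$minutes, st$landscape)
  fc1 <- contextualize_features(f)
  n1 <- feature_count(fc1)
  expect_gt(n1, 100)
  fc2 <- contextualize_features(f)
  expect_identical(feature_count(fc2), n1)
  reg <- attr(fc1, "registry")
  expect_true(all(c("raw", "z_species", "win_5c_mean", "ordinal") %in%
                    reg$variant))
  expect_setequal(unique(reg$class),
                  c("individual_geometry", "accelerometer", "collective",
                    "space_use"))
})
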