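test_that("importance metrics match hand formulas to machine precision", {
  # plug-in example: mu1=2, mu0=0, sd0=1, sd1=1
  set.seed(1)
  n <- 4000
  x <- c(rnorm(n, 0, 1), rnorm(n, 2, 1))
  lab <- rep(0:1, each = n)
  df <- data.frame(f_shift = x, f_null = rnorm(2 * n))
  imp <- importance(df, lab, rf_rows = 500, ntree = 50)
  i1 <- imp[imp$feature == "f_shift", ]
  mu1 <- mean(x[lab == 1]); mu0 <- mean(x[lab == 0])
  s1 <- sd(x[lab == 1]); s0 <- sd(x[lab == 0])
  expect_equal(i1$marginality, (mu1 - mu0) / s0, tolerance = 1e-12)
  expect_equal(i1$specialization, s1 / s0, tolerance = 1e-12)
  sp <- sqrt(((n - 1) * s1^2 + (n - 1) * s0^2) / (2 * n - 2))
  expect_equal(i1$mahalanobis, abs(mu1 - mu0) / sp, tolerance = 1e-12)
  # null feature: near-zero marginality, specialization ~ 1
  i0 <- imp[imp$feature == "f_null", ]
  expect_lt(abs(i0$marginality), 0.1)
  expect_lt(abs(i0$specialization - 1), 0.1)
  expect_equal(i1$rank_marginality, 1)
  # sd0 = 0 -> excluded with warning
  df$flat <- rep(c(0, 1), c(n, n))
  expect_warning(imp2 <- importance(df, lab, rf_rows = 200, ntree = 20),
                 "sd0")
  expect_true(is.na(imp2$marginality[imp2$feature == "flat"]))
})

test_that("top-union selection agrees with a brute-force set union", {
  set.seed(3)
  nf <- 2000
  sc <- data.frame(feature = sprintf("f%04d", 1:nf),
                   mahalanobis = runif(nf), marginality = rnorm(nf),
                   specialization = exp(rnorm(nf, 0, 0.5)),
                   rf_mda = rnorm(nf))
  sc$rank_mahalanobis <- rank(-abs(sc$mahalanobis), ties.method = "first")
  sc$rank_marginality <- rank(-abs(sc$marginality), ties.method = "first")
  sc$rank_specialization <- rank(-abs(log(sc$specialization)), ties.method = "first")
  sc$rank_rf_mda <- rank(-sc$rf_mda, ties.method = "first")
  sel <- select_top_union(sc, k = 125)
  brute <- sort(unique(c(
    sc$feature[order(sc$rank_mahalanobis)][1:125],
    sc$feature[order(sc$rank_marginality)][1:125],
    sc$feature[order(sc$rank_specialization)][1:125],
    sc$feature[order(sc$rank_rf_mda)][1:125])))
  expect_identical(sel, brute)
  expect_gte(length(sel), 125)
  expect_lte(length(sel), 500)
  # identical rankings -> union of size k
  sc2 <- sc
  for (rc in c("rank_marginality", "rank_specialization", "rank_rf_mda"))
    sc2[[rc]] <- sc2$rank_mahalanobis
  expect_length(select_top_union(sc2, 125), 125)
})

test_that("two-stage PCA: retention, rank-1 class, centring, round-trip", {
  set.seed(5)
  n <- 400
  mat <- data.frame(
    a1 = rnorm(n), a2 = rnorm(n), a3 = rnorm(n),
    b1 = rnorm(n), b2 = rnorm(n), c1 = rnorm(n))
  classes <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", c1 = "C")
  pcs <- fit_pc_stack(mat, classes, var_target = 0.95)
  # white noise: ~95% of dimensions kept per multi-feature class
  expect_gte(sum(pcs$kept_per_class), 4)
  expect_equal(unname(pcs$kept_per_class["C"]), 1)  # single feature passes through
  # training mean row scores to ~0
  mu_row <- as.data.frame(t(colMeans(mat)))
  sc <- predict(pcs, mu_row)
  expect_lt(max(abs(sc)), 0.2)
  # transform is deterministic and matches training scores
  sc_all <- predict(pcs, mat)
  expect_equal(dim(sc_all), c(n, pcs$n_components))

  # correlated data: stage-1 keeps fewer dimensions
  mat2 <- mat
  mat2$a2 <- mat2$a1 + rnorm(n, 0, 0.01)
  mat2$a3 <- mat2$a1 + rnorm(n, 0, 0.01)
  pcs2 <- fit_pc_stack(mat2, classes)
  expect_lt(unname(pcs2$kept_per_class["A"]), 3)
})

test_that("clustering recovers separated blobs and is seed-stable", {
  set.seed(6)
  k <- 5
  centers <- rbind(c(0, 0, 0), c(40, 0, 0), c(0, 40, 0),
                   c(0, 0, 40), c(40, 40, 40))
  rows <- do.call(rbind, lapply(1:k, function(i) {
    sweep(matrix(rnorm(60 * 3, sd = 0.5), 60), 2, centers[i, ], "+")
  }))
  truth <- rep(1:k, each = 60)
  cl <- unsupervised_clusters(rows, rep("zebra", nrow(rows)), n = k,
                              n_components = 3, seed = 2)
  # blob recovery: dominant true blob per cluster covers nearly all members
  tab <- table(cl$assignment, truth)
  purity <- sum(apply(tab, 1, max)) / nrow(rows)
  expect_gt(purity, 0.98)
  cl2 <- unsupervised_clusters(rows, rep("zebra", nrow(rows)), n = k,
                               n_components = 3, seed = 2)
  expect_identical(cl$assignment, cl2$assignment)
  # n = 1 -> single cluster
  cl3 <- unsupervised_clusters(rows[1:10, ], rep("zebra", 10), n = 1,
                               n_components = 3)
  expect_length(unique(cl3$assignment), 1)
  # predict: training rows map to their own clusters
  pr <- predict(cl, rows, rep("zebra", nrow(rows)))
  expect_gt(mean(pr == cl$assignment), 0.98)
})

test_that("segment filtering drops under-sensored intrusions and vehicle-disturbed rows", {
  st <- tiny_study()
  f <- prepare_features(st$minutes, st$landscape)
  segs <- st$segments
  # clean dataset unchanged (min_sensors below actual)
  f1 <- filter_segments(f, segs, min_sensors = 2)
  expect_equal(nrow(f1), nrow(f))
  # an under-sensored intrusion is dropped along with its matched control
  segs2 <- segs
  intr1 <- segs2$segment_id[segs2$truth == "intrusion"][1]
  segs2$n_active_sensors[segs2$segment_id == intr1] <- 5
  f2 <- filter_segments(f, segs2, min_sensors = 10)
  expect_equal(attr(f2, "dropped_segments"), 2)  # the pair goes together
  # vehicle rule: rows near a synthetic vehicle track are removed
  veh <- data.frame(time = f$time[1], x = f$x[1], y = f$y[1])
  f3 <- filter_segments(f, segs, vehicles = veh, min_sensors = 2)
  expect_gt(attr(f3, "dropped_rows"), 0)
  expect_lt(nrow(f3), nrow(f))
})

test_that("proximity labels: threshold rule and balanced seeded controls", {
  st <- tiny_study()
  f <- prepare_features(st$minutes, st$landscape)
  lab <- proximity_labels(f, st$segments, dist_m = 1000, seed = 4)
  near <- !is.na(f$dist_intruder) & f$dist_intruder <= 1000
  expect_true(all(lab[near] == 1))
  expect_equal(sum(lab == 0, na.rm = TRUE), sum(lab == 1, na.rm = TRUE))
  ctl_ids <- st$segments$segment_id[st$segments$truth == "control"]
  expect_true(all(f$segment_id[which(lab == 0)] %in% ctl_ids))
  # reseeding changes membership, not size
  lab2 <- proximity_labels(f, st$segments, dist_m = 1000, seed = 5)
  expect_equal(sum(lab2 == 0, na.rm = TRUE), sum(lab == 0, na.rm = TRUE))
  expect_false(identical(which(lab2 == 0), which(lab == 0)))
})
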