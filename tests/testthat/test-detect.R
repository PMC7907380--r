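test_that("control pairing: offsets valid, overlaps rejected, reproducible", {
  st <- tiny_study()
  pairs <- make_segments(st$segments, seed = 3)
  expect_equal(nrow(pairs), sum(st$segments$truth == "intrusion"))
  expect_true(all(abs(pairs$offset) %in% 1:2))
  pairs2 <- make_segments(st$segments, seed = 3)
  expect_identical(pairs, pairs2)
  # a control overlapping an intrusion period is rejected
  segs <- st$segments
  ctl <- which(segs$truth == "control")[1]
  intr <- which(segs$truth == "intrusion" &
                  segs$intrusion_id == segs$intrusion_id[ctl])
  segs$start_time[ctl] <- segs$start_time[intr]
  segs$end_time[ctl] <- segs$end_time[intr]
  p3 <- make_segments(segs, seed = 3)
  expect_true(segs$intrusion_id[ctl] %in% attr(p3, "dropped") ||
                !(segs$segment_id[ctl] %in% p3$control_segment))
})

test_that("block summaries: constants, spatially sorted probabilities, clustering", {
  bl <- data.table::data.table(animal_id = rep(letters[1:4], each = 3),
                               x = rep(c(0, 0, 100, 100), each = 3),
                               y = rep(c(0, 100, 0, 100), each = 3),
                               p_smooth = 0.3, cluster = "z.1")
  s <- summarize_block(bl)
  expect_equal(s$p_mean, 0.3)
  expect_equal(s$moran_p, 0)       # all equal -> 0 by convention
  # probabilities sorted in one corner -> positive spatial autocorrelation
  set.seed(2)
  n <- 16
  gx <- rep(seq(0, 300, length.out = 4), 4)
  gy <- rep(seq(0, 300, length.out = 4), each = 4)
  bl2 <- data.table::data.table(animal_id = sprintf("a%02d", 1:n),
                                x = gx, y = gy,
                                p_smooth = as.numeric(gx < 150 & gy < 150),
                                cluster = "z.1")
  s2 <- summarize_block(bl2)
  expect_gt(s2$moran_p, 0.05)
  # independent check against ape on the same configuration
  d <- as.matrix(dist(cbind(gx, gy))); w <- 1 / (d + 1); diag(w) <- 0
  expect_equal(s2$moran_p, ape::Moran.I(bl2$p_smooth, w)$observed)
  # hand-computed Moran's I on a 4-point toy (2x2 corners, one hot corner)
  px <- c(0, 100, 0, 100); py <- c(0, 0, 100, 100)
  v <- c(1, 0, 0, 0)
  dd <- as.matrix(dist(cbind(px, py))); ww <- 1 / (dd + 1); diag(ww) <- 0
  z <- v - mean(v)
  I_hand <- (4 / sum(ww)) * sum(ww * outer(z, z)) / sum(z^2)
  expect_equal(ape::Moran.I(v, ww)$observed, I_hand, tolerance = 1e-12)
})

test_that("nearest-neighbour index orders scattered vs clustered point sets", {
  set.seed(4)
  scattered <- cbind(runif(30, 0, 1000), runif(30, 0, 1000))
  tight <- cbind(runif(30, 0, 60), runif(30, 0, 60))
  # same hull scale: embed the tight cluster inside a wide triangle of 3 points
  tight2 <- rbind(tight, c(0, 1000), c(1000, 0), c(1000, 1000))
  nni_s <- nn_index(scattered[, 1], scattered[, 2])
  nni_t <- nn_index(tight2[, 1], tight2[, 2])
  expect_lt(nni_t, nni_s)
  expect_gt(nni_s, 0.6)   # CSR expectation ~ 1
  expect_lt(nni_s, 1.6)
})

test_that("residualized t-test ordering matches a brute-force reimplementation", {
  set.seed(12)
  n <- 24
  truth <- rep(c("intrusion", "control"), each = n / 2)
  y <- truth == "intrusion"
  mat <- as.data.frame(matrix(rnorm(n * 10), n))
  names(mat) <- sprintf("f%02d", 1:10)
  mat$f01 <- mat$f01 + ifelse(y, 2, 0)        # pure signal
  ordering <- order_features(mat, truth)
  expect_equal(ordering$feature[1], "f01")
  expect_setequal(ordering$feature, names(mat))

  # independent brute-force reimplementation
  brute <- local({
    work <- mat; orig <- mat; out <- character(); ts_out <- numeric()
    while (ncol(work) > 0) {
      tv <- sapply(work, function(v) unname(t.test(v[y], v[!y])$statistic))
      cand <- sort(names(tv)[abs(tv) == max(abs(tv))])[1]
      out <- c(out, cand); ts_out <- c(ts_out, tv[[cand]])
      xo <- orig[[cand]]
      work <- work[, setdiff(names(work), cand), drop = FALSE]
      if (ncol(work) > 0) {
        work <- as.data.frame(lapply(work, function(v) {
          r <- resid(lm(v ~ xo)); as.numeric(scale(r))
        }))
      }
    }
    list(features = out, t = ts_out)
  })
  expect_identical(ordering$feature, brute$features)
  expect_equal(ordering$t_value, brute$t, tolerance = 1e-8)

  # a perfect duplicate's residual signal dies after its source is added
  mat2 <- mat
  mat2$dup <- mat2$f01
  o2 <- order_features(mat2, truth)
  expect_equal(o2$feature[1], "dup")        # name order breaks the tie
  expect_lt(abs(o2$t_value[o2$feature == "f01"]), 1e-6)
  expect_equal(o2$feature[nrow(o2)], "f01") # copy ranked last

  # ordering invariant to affine rescaling
  mat3 <- mat
  mat3$f03 <- mat3$f03 * 100 + 5
  o3 <- order_features(mat3, truth)
  expect_identical(o3$feature, ordering$feature)
})

test_that("logistic detector: separating feature, 2x2 log-odds oracle", {
  su <- data.frame(segment_id = sprintf("s%02d", 1:20),
                   truth = rep(c("intrusion", "control"), 10),
                   sig = rep(c(5, -5), 10) + rnorm(20, 0, 0.1),
                   noise = rnorm(20))
  ordd <- order_features(su[, c("sig", "noise")], su$truth)
  m <- fit_detector(su, ordd, n_features = 1)
  expect_true(m$separated)
  expect_equal(unname(predict(m, su) > 0.5), su$truth == "intrusion")
  # closed-form check on a binary regressor: coef = log-odds difference
  set.seed(2)
  xb <- rep(c(0, 1), each = 50)
  yb <- c(rbinom(50, 1, 0.2), rbinom(50, 1, 0.8))
  fit <- glm(yb ~ xb, family = binomial())
  p0 <- mean(yb[xb == 0]); p1 <- mean(yb[xb == 1])
  expect_equal(unname(coef(fit)[2]),
               log(p1 / (1 - p1)) - log(p0 / (1 - p0)), tolerance = 1e-6)
  # metrics arithmetic on the fixed confusion layout (52, 10, 5, 47)
  expect_equal((52 + 47) / 114, 0.8684, tolerance = 1e-4)
})

test_that("detector cross-validation separates an oracle feature from permuted labels", {
  set.seed(31)
  n <- 24
  su <- data.table::data.table(
    segment_id = sprintf("s%02d", 1:n),
    truth = rep(c("intrusion", "control"), each = n / 2))
  su[, oracle := ifelse(truth == "intrusion", 1, 0) + rnorm(n, 0, 0.05)]
  su[, junk1 := rnorm(n)][, junk2 := rnorm(n)]
  det <- structure(list(summaries = su, block_rows = NULL,
                        truth_map = setNames(su$truth, su$segment_id)),
                   class = "ews_detection_data")
  cv <- cross_validate_detector(det, n_features = 2, repeats = 10,
                                seed = 2, use_odds = FALSE)
  expect_gt(cv$accuracy, 0.95)
  expect_equal(sum(cv$confusion), n * 10)
  # permuted labels: accuracy compatible with coin flipping
  su2 <- data.table::copy(su)
  su2[, truth := sample(truth)]
  su2[, oracle := rnorm(n)]
  det2 <- structure(list(summaries = su2, block_rows = NULL,
                         truth_map = setNames(su2$truth, su2$segment_id)),
                    class = "ews_detection_data")
  cv2 <- cross_validate_detector(det2, n_features = 2, repeats = 10,
                                 seed = 2, use_odds = FALSE)
  expect_lt(abs(cv2$accuracy - 0.5), 0.25)
})

test_that("cluster odds: enriched clusters get positive log odds", {
  cl <- c(rep("z.1", 80), rep("z.2", 20), rep("z.1", 20), rep("z.2", 80))
  tr <- rep(c("intrusion", "control"), each = 100)
  lo <- cluster_odds(cl, tr)
  expect_gt(lo["z.1"], 0)
  expect_lt(lo["z.2"], 0)
  expect_equal(unname(lo["z.1"]),
               log((80 + 1) / (100 + 2)) - log((20 + 1) / (100 + 2)),
               tolerance = 1e-12)
})
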