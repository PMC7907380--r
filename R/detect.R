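#' Pair intrusion segments with valid control windows
#'
#' Controls are windows of the same clock period one or two days earlier or
#' later that overlap no intrusion. Offsets are chosen seeded-randomly
#' among the valid options; intrusions without any valid control are
#' dropped with a log attribute.
#'
#' @param segments segment table of an `ews_study` (contains both roles)
#' @param seed seed for the offset choice
#' @return data.frame: intrusion_id, intrusion segment, control segment,
#'   offset (days)
#' @export
make_segments <- function(segments, seed = 1) {
  intr <- segments[segments$truth == "intrusion", ]
  ctl <- segments[segments$truth == "control", ]
  out <- list(); dropped <- character()
  with_seed(derive_seed(seed, "make-segments"), {
    for (i in seq_len(nrow(intr))) {
      cands <- ctl[ctl$intrusion_id == intr$intrusion_id[i], , drop = FALSE]
      # a valid control window overlaps no intrusion period
      ok <- vapply(seq_len(nrow(cands)), function(j) {
        !any(cands$start_time[j] < intr$end_time &
               cands$end_time[j] > intr$start_time)
      }, logical(1))
      cands <- cands[ok, , drop = FALSE]
      if (nrow(cands) == 0) { dropped <- c(dropped, intr$intrusion_id[i]); next }
      pick <- cands[sample(nrow(cands), 1), ]
      out[[i]] <- data.frame(intrusion_id = intr$intrusion_id[i],
                             intrusion_segment = intr$segment_id[i],
                             control_segment = pick$segment_id,
                             offset = pick$control_offset_days)
    }
  })
  res <- do.call(rbind, out)
  attr(res, "dropped") <- dropped
  res
}

#' Summary features for one 15-min block
#'
#' From the animal-minutes of one segment block: mean / SD / max / 90th
#' percentile of the smoothed response probabilities; local spatial
#' autocorrelation (Moran's I with inverse-distance weights) of the
#' per-animal mean probabilities over the animal positions; the
#' nearest-neighbour clustering index of the animals predicted undisturbed
#' (observed over expected NN distance under complete spatial randomness in
#' the convex hull); and the mean log cluster-association odds.
#'
#' @param block data.table with `animal_id`, `x`, `y`, `p_smooth`,
#'   `cluster` for one block
#' @param odds named vector of per-cluster log odds (intrusion vs control
#'   association); missing clusters count as 0
#' @param boundary probability decision boundary separating predicted
#'   response from predicted undisturbed
#' @return one-row data.frame of block features
#' @export
summarize_block <- function(block, odds = NULL, boundary = 0.5) {
  lev <- if ("p_level" %in% names(block)) block$p_level else block$p_smooth
  an <- block[, .(x = mean(x), y = mean(y), p_raw = mean(p_smooth)),
              by = animal_id]
  an_lev <- block[, .(p = if ("p_level" %in% names(block)) mean(p_level)
                      else mean(p_smooth)), by = animal_id]$p
  p <- lev
  moran <- 0
  if (nrow(an) >= 3 && stats::sd(an_lev) > 1e-12) {
    d <- as.matrix(stats::dist(an[, .(x, y)]))
    w <- 1 / (d + 1); diag(w) <- 0
    moran <- ape::Moran.I(an_lev, w)$observed
  }
  und <- an[an$p_raw < boundary]
  nni <- NA_real_
  if (nrow(und) >= 3) nni <- nn_index(und$x, und$y)
  odds_mean <- 0
  if (!is.null(odds)) {
    lo <- odds[block$cluster]
    lo[is.na(lo)] <- 0
    odds_mean <- mean(lo)
  }
  data.frame(p_mean = mean(p), p_sd = stats::sd(p), p_max = max(p),
             p_q90 = stats::quantile(p, 0.9, names = FALSE),
             moran_p = moran, nni_undisturbed = nni, odds_mean = odds_mean)
}

#' Nearest-neighbour index (observed / expected NN distance under CSR)
#'
#' Expected NN distance: `0.5 * sqrt(A / n)` with `A` the convex hull
#' area. Values < 1 indicate clustering, > 1 overdispersion.
#' @param x,y point coordinates (>= 3 points)
#' @return the index
#' @export
nn_index <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3)
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  obs <- mean(apply(d, 1, min))
  ch <- grDevices::chull(x, y)
  A <- abs(sum(x[ch] * y[c(ch[-1], ch[1])] - x[c(ch[-1], ch[1])] * y[ch])) / 2
  if (A < 1e-9) return(NA_real_)
  obs / (0.5 * sqrt(A / n))
}

#' Per-cluster log association odds (intrusion vs control), smoothed
#' @param cluster cluster id per animal-minute
#' @param truth segment truth per animal-minute
#' @param alpha Laplace smoothing
#' @return named vector of log odds
#' @export
cluster_odds <- function(cluster, truth, alpha = 1) {
  k <- sort(unique(cluster))
  n1 <- table(factor(cluster[truth == "intrusion"], levels = k))
  n0 <- table(factor(cluster[truth == "control"], levels = k))
  N1 <- sum(n1); N0 <- sum(n0); K <- length(k)
  lo <- log((n1 + alpha) / (N1 + alpha * K)) - log((n0 + alpha) / (N0 + alpha * K))
  stats::setNames(as.numeric(lo), k)
}

#' Build the per-segment detection dataset
#'
#' Splits each segment into 15-min blocks, computes block features, and
#' aggregates each feature over the segment with the eight statistics:
#' mean, SD, min, max, and mean / SD / min / max of the lagged (first)
#' differences across consecutive blocks. Cluster-odds block features are
#' recomputed per cross-validation fold from training segments only, so
#' this function also returns the raw per-block cluster composition.
#'
#' @param predictions out-of-fold predictions of [loio_cross_validate()]
#'   (must carry `x`, `y`, `p_smooth`, `cluster`)
#' @param segments segment table
#' @param boundary decision boundary for "predicted undisturbed"
#' @param block_min block length (minutes)
#' @param normalize_by_fold standardize the smoothed probabilities within
#'   each cross-validation fold (zero mean, unit variance, no labels used)
#'   before computing the probability-level block features; removes
#'   fold-to-fold calibration drift of the SVM probability scale, which
#'   otherwise inflates the between-segment variance. Spatial features and
#'   the predicted-undisturbed rule keep the raw probabilities.
#' @return an `ews_detection_data`: `summaries` (segment x feature matrix
#'   with `truth`), `blocks` (block features), `block_rows` (row-level
#'   cluster/block bookkeeping)
#' @export
detection_dataset <- function(predictions, segments, boundary = 0.5,
                              block_min = 15, normalize_by_fold = TRUE) {
  dt <- data.table::as.data.table(predictions)
  seg0 <- segments$start_time[match(dt$segment_id, segments$segment_id)]
  dt[, block := floor((time - seg0) / (block_min * 60))]
  if (normalize_by_fold && "fold" %in% names(dt)) {
    dt[, p_level := (p_smooth - mean(p_smooth)) / (stats::sd(p_smooth) + 1e-9),
       by = fold]
  } else {
    dt[, p_level := p_smooth]
  }
  blocks <- dt[, summarize_block(.SD, odds = NULL, boundary = boundary),
               by = .(segment_id, block)]
  data.table::setorder(blocks, segment_id, block)
  base_feats <- setdiff(names(blocks), c("segment_id", "block", "odds_mean"))
  summaries <- blocks[, aggregate_blocks(.SD, base_feats), by = segment_id]
  truth <- segments$truth[match(summaries$segment_id, segments$segment_id)]
  summaries[, truth := truth]
  truth_map <- stats::setNames(segments$truth, segments$segment_id)
  # per-segment and per-block cluster composition (for the odds features)
  lev <- sort(unique(dt$cluster))
  seg_counts <- NULL; block_counts <- NULL
  if (!is.null(lev) && length(lev) > 0 && !all(is.na(dt$cluster))) {
    seg_counts <- as.matrix(table(factor(dt$segment_id), factor(dt$cluster, lev)))
    block_counts <- as.matrix(table(paste(dt$segment_id, dt$block, sep = "@"),
                                    factor(dt$cluster, lev)))
  }
  structure(list(summaries = summaries, blocks = blocks,
                 block_rows = dt[, .(segment_id, block, cluster)],
                 seg_counts = seg_counts, block_counts = block_counts,
                 truth_map = truth_map,
                 boundary = boundary, block_min = block_min),
            class = "ews_detection_data")
}

# the eight aggregation statistics over a segment's block series
aggregate_blocks <- function(bl, feats) {
  out <- list()
  for (fv in feats) {
    v <- bl[[fv]]
    v <- v[is.finite(v)]
    if (length(v) == 0) v <- 0
    d <- if (length(v) > 1) diff(v) else 0
    out[[paste0(fv, "__mean")]] <- mean(v)
    out[[paste0(fv, "__sd")]] <- if (length(v) > 1) stats::sd(v) else 0
    out[[paste0(fv, "__min")]] <- min(v)
    out[[paste0(fv, "__max")]] <- max(v)
    out[[paste0(fv, "__dmean")]] <- mean(d)
    out[[paste0(fv, "__dsd")]] <- if (length(d) > 1) stats::sd(d) else 0
    out[[paste0(fv, "__dmin")]] <- min(d)
    out[[paste0(fv, "__dmax")]] <- max(d)
  }
  out
}

# Add cluster-odds summary features computed from training segments only.
# Training segments receive cross-fitted (leave-own-segment-out) odds so the
# feature's in-fold t-value reflects generalization rather than the segment's
# own label; held-out segments use odds from the full training set.
add_odds_features <- function(det, train_segments) {
  su <- det$summaries
  if (is.null(det$seg_counts))
    return(su)
  lev <- colnames(det$seg_counts)
  odds_from <- function(segs) {
    segs <- intersect(segs, rownames(det$seg_counts))
    tm <- det$truth_map[segs]
    n1 <- colSums(det$seg_counts[segs[tm == "intrusion"], , drop = FALSE])
    n0 <- colSums(det$seg_counts[segs[tm == "control"], , drop = FALSE])
    K <- length(lev); a <- 1
    log((n1 + a) / (sum(n1) + a * K)) - log((n0 + a) / (sum(n0) + a * K))
  }
  lo_full <- odds_from(train_segments)
  bc <- det$block_counts
  key <- do.call(rbind, strsplit(rownames(bc), "@", fixed = TRUE))
  seg_of_block <- key[, 1]
  blk <- as.integer(key[, 2])
  vals <- numeric(nrow(bc))
  for (s in unique(seg_of_block)) {
    lo <- if (s %in% train_segments) odds_from(setdiff(train_segments, s))
          else lo_full
    r <- seg_of_block == s
    vals[r] <- (bc[r, , drop = FALSE] %*% lo) / pmax(rowSums(bc[r, , drop = FALSE]), 1)
  }
  bo <- data.table::data.table(segment_id = seg_of_block, block = blk,
                               odds_mean = vals)
  data.table::setorder(bo, segment_id, block)
  so <- bo[, aggregate_blocks(.SD, "odds_mean"), by = segment_id]
  out <- merge(su, so, by = "segment_id", sort = FALSE)
  # merge must not disturb the summaries' row order (callers index by row)
  out[match(su$segment_id, out$segment_id), ]
}

#' Residualized t-test feature ordering
#'
#' Independent two-sample t-tests between intrusions and controls rank the
#' features; the top feature is added, its correlation with the remaining
#' features removed by linear regression (residuals standardized to zero
#' mean and unit variance), and the t-tests repeated until all features
#' are ordered. Zero-variance features are skipped with a warning; ties
#' break by feature name.
#'
#' @param mat data.frame of summary features (rows = segments)
#' @param truth "intrusion"/"control" per row
#' @return data.frame: feature, t value at selection, order
#' @export
order_features <- function(mat, truth) {
  mat <- as.data.frame(mat)
  y <- truth == "intrusion"
  stopifnot(sum(y) >= 2, sum(!y) >= 2)
  keep <- vapply(mat, function(v) is.finite(stats::sd(v)) && stats::sd(v) > 1e-12,
                 logical(1))
  if (any(!keep)) warning(sum(!keep), " zero-variance features skipped")
  work <- mat[, keep, drop = FALSE]
  orig <- work
  out <- list()
  ord <- 0L
  while (ncol(work) > 0) {
    tv <- vapply(work, function(v) {
      if (stats::sd(v) < 1e-12) return(0)
      unname(stats::t.test(v[y], v[!y])$statistic)
    }, 0)
    cand <- names(tv)[abs(tv) == max(abs(tv))]
    pick <- sort(cand)[1]
    ord <- ord + 1L
    out[[pick]] <- data.frame(feature = pick, t_value = tv[[pick]], order = ord)
    xo <- orig[[pick]]
    work <- work[, setdiff(names(work), pick), drop = FALSE]
    if (ncol(work) > 0) {
      X <- cbind(1, xo)
      beta <- qr.coef(qr(X), as.matrix(work))
      res <- as.matrix(work) - X %*% beta
      res <- scale(res)
      res[!is.finite(res)] <- 0
      work <- as.data.frame(res)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the logistic intrusion detector
#'
#' Logistic regression on the top-n ordered (original) features, optionally
#' with all two-way interactions. Complete separation triggers a ridge
#' fallback via glmnet with a small penalty, flagged in the result.
#'
#' @param summaries an `ews_detection_data` summaries table (or any
#'   data.frame with `truth`)
#' @param ordering output of [order_features()]
#' @param n_features number of features in the model (default 7, the
#'   parsimonious size)
#' @param interactions 1 (none) or 2 (all pairs)
#' @return an `ews_detector`
#' @export
fit_detector <- function(summaries, ordering, n_features = 7,
                         interactions = 1) {
  stopifnot(n_features <= nrow(ordering))
  feats <- ordering$feature[seq_len(n_features)]
  df <- as.data.frame(summaries)[, feats, drop = FALSE]
  df$y <- as.integer(summaries$truth == "intrusion")
  rhs <- if (interactions >= 2 && n_features > 1)
    sprintf("(%s)^2", paste(sprintf("`%s`", feats), collapse = " + "))
  else paste(sprintf("`%s`", feats), collapse = " + ")
  form <- stats::as.formula(paste("y ~", rhs))
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (any(fit$fitted.values > 1 - 1e-8) && any(fit$fitted.values < 1e-8))
    separated <- TRUE
  structure(list(fit = fit, features = feats, ordering = ordering,
                 n_features = n_features, interactions = interactions,
                 separated = separated),
            class = "ews_detector")
}

#' @export
print.ews_detector <- function(x, ...) {
  cat(sprintf("<ews_detector: %d features%s%s>\n", x$n_features,
              if (x$interactions >= 2) " + 2-way interactions" else "",
              if (x$separated) " [separation: interpret coefficients with care]" else ""))
  invisible(x)
}

#' Predict intrusion probability for segments
#' @param object an `ews_detector`
#' @param newdata summaries table
#' @param ... unused
#' @return probabilities
#' @export
predict.ews_detector <- function(object, newdata, ...) {
  stats::predict(object$fit, newdata = as.data.frame(newdata),
                 type = "response")
}

#' Repeated stratified twofold cross-validation of the detector
#'
#' 25 times (default), segments are split into two stratified folds and the
#' logistic model refitted per training fold and evaluated on the other.
#' By default the residualized t-test feature ordering is re-run inside
#' every training fold (leakage-safe: under a response-free null world the
#' cross-validated accuracy is centred on 0.5). `refit_ordering = FALSE`
#' determines the ordering once on the full segment set — the
#' sequence-determination variant, whose selection optimism inflates null
#' accuracy substantially when segments are few. Cluster-odds feature
#' values are always recomputed from training segments only. Reports
#' accuracy / precision / recall distributions and the pooled confusion
#' matrix.
#'
#' @param det an `ews_detection_data`
#' @param n_features model size
#' @param interactions 1 or 2
#' @param repeats repetitions
#' @param seed seed
#' @param use_odds include the cluster-odds features (requires `block_rows`)
#' @param refit_ordering re-run the feature ordering per training fold
#' @return an `ews_detector_cv`: metrics table, pooled confusion matrix,
#'   per-segment mean predicted probability
#' @export
cross_validate_detector <- function(det, n_features = 7, interactions = 1,
                                    repeats = 25, seed = 1, use_odds = TRUE,
                                    refit_ordering = TRUE) {
  su <- det$summaries
  truth <- su$truth
  ids <- su$segment_id
  ord_full <- NULL
  if (!refit_ordering) {
    su_full <- if (use_odds) add_odds_features(det, ids) else su
    feat_cols <- setdiff(names(su_full), c("segment_id", "truth"))
    ord_full <- order_features(as.data.frame(su_full)[, feat_cols, drop = FALSE],
                               truth)
  }
  conf <- matrix(0, 2, 2, dimnames = list(truth = c("control", "intrusion"),
                                          prediction = c("control", "intrusion")))
  mets <- list()
  pseg <- stats::setNames(numeric(length(ids)), ids)
  nseg <- stats::setNames(numeric(length(ids)), ids)
  with_seed(derive_seed(seed, "detector-cv"), {
    for (r in seq_len(repeats)) {
      # stratified twofold split
      f1 <- c(sample(which(truth == "intrusion"),
                     floor(sum(truth == "intrusion") / 2)),
              sample(which(truth == "control"),
                     ceiling(sum(truth == "control") / 2)))
      folds <- list(f1, setdiff(seq_along(ids), f1))
      pred_bin <- integer(length(ids))
      for (fd in folds) {
        tr <- setdiff(seq_along(ids), fd)
        su_all <- if (use_odds) add_odds_features(det, ids[tr]) else su
        ordd <- if (refit_ordering) {
          feat_cols <- setdiff(names(su_all), c("segment_id", "truth"))
          order_features(as.data.frame(su_all)[tr, feat_cols, drop = FALSE],
                         truth[tr])
        } else ord_full
        m <- fit_detector(su_all[tr, ], ordd,
                          n_features = min(n_features, nrow(ordd)),
                          interactions = interactions)
        p <- predict(m, su_all[fd, ])
        pred_bin[fd] <- as.integer(p > 0.5)
        pseg[fd] <- pseg[fd] + p; nseg[fd] <- nseg[fd] + 1
      }
      tb <- table(factor(ifelse(truth == "intrusion", "intrusion", "control"),
                         levels = c("control", "intrusion")),
                  factor(ifelse(pred_bin == 1, "intrusion", "control"),
                         levels = c("control", "intrusion")))
      conf <- conf + tb
      tp <- tb["intrusion", "intrusion"]; fp <- tb["control", "intrusion"]
      fn <- tb["intrusion", "control"]; tn <- tb["control", "control"]
      mets[[r]] <- data.frame(
        repeat_id = r,
        accuracy = (tp + tn) / sum(tb),
        precision = if (tp + fp > 0) tp / (tp + fp) else NA,
        recall = if (tp + fn > 0) tp / (tp + fn) else NA)
    }
  })
  metrics <- do.call(rbind, mets)
  structure(list(metrics = metrics, confusion = conf,
                 segment_prob = pseg / pmax(nseg, 1),
                 accuracy = mean(metrics$accuracy),
                 precision = mean(metrics$precision, na.rm = TRUE),
                 recall = mean(metrics$recall, na.rm = TRUE)),
            class = "ews_detector_cv")
}

#' @export
print.ews_detector_cv <- function(x, ...) {
  cat(sprintf("<ews_detector_cv: accuracy %.3f (sd %.3f), precision %.3f, recall %.3f>\n",
              x$accuracy, stats::sd(x$metrics$accuracy), x$precision, x$recall))
  print(x$confusion)
  invisible(x)
}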