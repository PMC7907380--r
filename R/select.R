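#' Filter segments and rows before importance analysis
#'
#' Drops intrusion segments with fewer than `min_sensors` active animal
#' sensors, and rows from animals located within `vehicle_dist_m` and
#' `vehicle_min` minutes of a non-experimental vehicle.
#'
#' @param features an `ews_features`
#' @param segments the study's segment table
#' @param vehicles optional data.frame of vehicle positions (`time`, `x`,
#'   `y`)
#' @param min_sensors minimum active sensors per intrusion segment
#' @param vehicle_dist_m,vehicle_min vehicle-disturbance exclusion rule
#' @return filtered features; attr `"dropped_segments"` and
#'   `"dropped_rows"` hold the counts; an empty result errors
#' @export
filter_segments <- function(features, segments, vehicles = NULL,
                            min_sensors = 30, vehicle_dist_m = 250,
                            vehicle_min = 20) {
  bad_seg <- segments$segment_id[segments$truth == "intrusion" &
                                   segments$n_active_sensors < min_sensors]
  # an intrusion's control is dropped with it (pairs stay balanced)
  bad_intr <- segments$intrusion_id[segments$segment_id %in% bad_seg]
  bad_seg <- segments$segment_id[segments$intrusion_id %in% bad_intr]
  dt <- data.table::as.data.table(features)[!segment_id %in% bad_seg]
  dropped_rows <- 0L
  if (!is.null(vehicles) && nrow(vehicles) > 0 && nrow(dt) > 0) {
    keep <- rep(TRUE, nrow(dt))
    for (i in seq_len(nrow(vehicles))) {
      near_t <- abs(dt$time - vehicles$time[i]) <= vehicle_min * 60
      if (!any(near_t)) next
      d <- sqrt((dt$x[near_t] - vehicles$x[i])^2 + (dt$y[near_t] - vehicles$y[i])^2)
      keep[which(near_t)[d <= vehicle_dist_m]] <- FALSE
    }
    dropped_rows <- sum(!keep)
    dt <- dt[keep]
  }
  if (nrow(dt) == 0) stop("filter_segments removed every row")
  data.table::setattr(dt, "registry", attr(features, "registry"))
  data.table::setattr(dt, "class", class(features))
  attr(dt, "dropped_segments") <- length(bad_seg)
  attr(dt, "dropped_rows") <- dropped_rows
  dt
}

#' Proximity labels for feature-importance scoring
#'
#' Label 1: rows within `dist_m` of a concurrent intrusion; label 0: an
#' equally sized seeded random sample of control-period rows.
#'
#' @param features an `ews_features` with `dist_intruder` filled for
#'   intrusion segments
#' @param segments segment table
#' @param dist_m proximity threshold (m)
#' @param seed control-sampling seed
#' @return integer vector (1 / 0 / NA) aligned with `features` rows
#' @export
proximity_labels <- function(features, segments, dist_m = 1000, seed = 1) {
  lab <- rep(NA_integer_, nrow(features))
  near <- !is.na(features$dist_intruder) & features$dist_intruder <= dist_m
  lab[near] <- 1L
  if (!any(near)) stop("no rows within ", dist_m, " m of an intrusion")
  ctl_ids <- segments$segment_id[segments$truth == "control"]
  ctl_rows <- which(features$segment_id %in% ctl_ids)
  n1 <- sum(near)
  if (length(ctl_rows) < n1) stop("not enough control rows to match")
  pick <- with_seed(derive_seed(seed, "proximity-controls"),
                    sample(ctl_rows, n1))
  lab[pick] <- 0L
  lab
}

#' Four-way feature importance
#'
#' For every feature: univariate Mahalanobis distance between the groups
#' (|mu1 - mu0| / pooled sd), marginality ((mu1 - mu0) / sd0),
#' specialization (sd1 / sd0), and the Mean Decrease Accuracy of a random
#' forest. Features whose label-0 standard deviation is (near) zero are
#' excluded with a warning.
#'
#' @param mat numeric matrix / data.frame of features (rows = records)
#' @param labels 0/1 vector
#' @param rf_rows maximum rows used for the random forest (subsampled,
#'   seeded, for tractability; recorded in the result)
#' @param ntree random-forest trees (implementation default, recorded)
#' @param seed seed for subsampling and the forest
#' @return an `ews_importance` data.frame: one row per feature with the
#'   four scores and their ranks (1 = most important)
#' @export
importance <- function(mat, labels, rf_rows = 2000, ntree = 200, seed = 1) {
  mat <- as.data.frame(mat)
  ok <- !is.na(labels)
  mat <- mat[ok, , drop = FALSE]; labels <- labels[ok]
  stopifnot(all(labels %in% 0:1), length(unique(labels)) == 2)
  g1 <- labels == 1; g0 <- labels == 0
  mu1 <- vapply(mat, function(v) mean(v[g1], na.rm = TRUE), 0)
  mu0 <- vapply(mat, function(v) mean(v[g0], na.rm = TRUE), 0)
  s1 <- vapply(mat, function(v) stats::sd(v[g1], na.rm = TRUE), 0)
  s0 <- vapply(mat, function(v) stats::sd(v[g0], na.rm = TRUE), 0)
  n1 <- sum(g1); n0 <- sum(g0)
  sp <- sqrt(((n1 - 1) * s1^2 + (n0 - 1) * s0^2) / (n1 + n0 - 2))
  bad <- !is.finite(s0) | s0 < 1e-12
  if (any(bad)) warning(sum(bad), " features excluded (sd0 ~ 0)")
  marginality <- ifelse(bad, NA, (mu1 - mu0) / s0)
  specialization <- ifelse(bad, NA, s1 / s0)
  mahalanobis <- ifelse(sp < 1e-12, NA, abs(mu1 - mu0) / sp)

  with_seed(derive_seed(seed, "rf-mda"), {
    idx <- if (length(labels) > rf_rows) sample(length(labels), rf_rows) else seq_along(labels)
    m <- mat[idx, , drop = FALSE]
    m[] <- lapply(m, function(v) { v[!is.finite(v)] <- stats::median(v, na.rm = TRUE); v })
    m[] <- lapply(m, function(v) { v[is.na(v)] <- 0; v })
    rf <- randomForest::randomForest(m, factor(labels[idx]), ntree = ntree,
                                     importance = TRUE)
    mda <- randomForest::importance(rf, type = 1)[, 1]
  })
  out <- data.frame(feature = names(mat), mahalanobis = mahalanobis,
                    marginality = marginality, specialization = specialization,
                    rf_mda = mda[names(mat)], row.names = NULL,
                    stringsAsFactors = FALSE)
  # importance magnitude per metric; specialization measured as deviation
  # of the variance ratio from 1 (either direction)
  out$rank_mahalanobis <- rank(-abs(out$mahalanobis), ties.method = "first",
                               na.last = TRUE)
  out$rank_marginality <- rank(-abs(out$marginality), ties.method = "first",
                               na.last = TRUE)
  out$rank_specialization <- rank(-abs(log(out$specialization)),
                                  ties.method = "first", na.last = TRUE)
  out$rank_rf_mda <- rank(-out$rf_mda, ties.method = "first", na.last = TRUE)
  class(out) <- c("ews_importance", "data.frame")
  out
}

#' Select the union of the top-k features per importance metric
#'
#' @param scores an `ews_importance`
#' @param k top size per metric (the union has between k and 4k members)
#' @return character vector of selected feature names (stable name order
#'   breaks rank ties)
#' @export
select_top_union <- function(scores, k = 125) {
  stopifnot(k <= nrow(scores))
  sel <- unique(unlist(lapply(
    c("rank_mahalanobis", "rank_marginality", "rank_specialization", "rank_rf_mda"),
    function(rc) scores$feature[order(scores[[rc]], scores$feature)][seq_len(k)])))
  sort(sel)
}

#' Two-stage principal component reduction
#'
#' Stage 1: one PCA per main feature class over its selected features,
#' keeping components until the pooled retained variance reaches
#' `var_target`; single-feature classes pass through unchanged. Stage 2: a
#' second PCA over the pooled stage-1 scores. Missing entries are imputed
#' at the training column mean.
#'
#' @param mat data.frame/matrix of selected feature columns (training rows)
#' @param classes named character vector mapping column -> main class
#' @param var_target total retained variance in stage 1
#' @return an `ews_pcstack` with a `predict` method
#' @export
fit_pc_stack <- function(mat, classes, var_target = 0.95) {
  mat <- as.data.frame(mat)
  stopifnot(length(unique(classes[names(mat)])) >= 1)
  mu <- vapply(mat, function(v) mean(v, na.rm = TRUE), 0)
  mu[!is.finite(mu)] <- 0
  for (j in seq_along(mat)) mat[[j]][!is.finite(mat[[j]])] <- mu[j]
  stage1 <- list(); scores <- list(); kept <- integer()
  for (cl in unique(classes[names(mat)])) {
    cols <- names(mat)[classes[names(mat)] == cl]
    sub <- mat[, cols, drop = FALSE]
    if (length(cols) == 1) {
      stage1[[cl]] <- list(passthrough = TRUE, cols = cols)
      scores[[cl]] <- as.matrix(sub)
      colnames(scores[[cl]]) <- paste0(cl, "_PC1")
      kept[cl] <- 1L
      next
    }
    sds <- vapply(sub, stats::sd, 0)
    cols <- cols[sds > 1e-10]
    sub <- sub[, cols, drop = FALSE]
    p <- stats::prcomp(sub, center = TRUE, scale. = TRUE)
    cum <- cumsum(p$sdev^2) / sum(p$sdev^2)
    nc <- which(cum >= var_target)[1]
    stage1[[cl]] <- list(passthrough = FALSE, cols = cols, pca = p, ncomp = nc)
    sc <- p$x[, seq_len(nc), drop = FALSE]
    colnames(sc) <- paste0(cl, "_", colnames(sc))
    scores[[cl]] <- sc
    kept[cl] <- nc
  }
  pooled <- do.call(cbind, scores)
  p2 <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
  structure(list(stage1 = stage1, stage2 = p2, train_mu = mu,
                 n_components = ncol(p2$x), kept_per_class = kept,
                 var_target = var_target),
            class = "ews_pcstack")
}

#' @export
print.ews_pcstack <- function(x, ...) {
  cat(sprintf("<ews_pcstack: %s stage-1 components -> %d stage-2>\n",
              paste(x$kept_per_class, collapse = "+"), x$n_components))
  invisible(x)
}

#' Project new rows through a fitted PC stack
#' @param object an `ews_pcstack`
#' @param newdata data.frame containing the training feature columns
#' @param ... unused
#' @return matrix of stage-2 scores
#' @export
predict.ews_pcstack <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  scores <- list()
  for (cl in names(object$stage1)) {
    s1 <- object$stage1[[cl]]
    sub <- newdata[, s1$cols, drop = FALSE]
    for (j in seq_along(sub))
      sub[[j]][!is.finite(sub[[j]])] <- object$train_mu[[s1$cols[j]]]
    if (isTRUE(s1$passthrough)) {
      sc <- as.matrix(sub)
      colnames(sc) <- paste0(cl, "_PC1")
    } else {
      sc <- stats::predict(s1$pca, sub)[, seq_len(s1$ncomp), drop = FALSE]
      colnames(sc) <- paste0(cl, "_", colnames(sc))
    }
    scores[[cl]] <- sc
  }
  stats::predict(object$stage2, do.call(cbind, scores))
}

#' Per-species unsupervised clustering of the reduced feature space
#'
#' @param scores matrix of stage-2 component scores
#' @param species species per row
#' @param n clusters per species
#' @param n_components components used
#' @param seed k-means seed
#' @return an `ews_clusters`: per-species k-means models and per-row
#'   assignments (`"<species>.<cluster>"`)
#' @export
unsupervised_clusters <- function(scores, species, n = 25, n_components = 12,
                                  seed = 1) {
  nc <- min(n_components, ncol(scores))
  models <- list()
  assign <- character(nrow(scores))
  with_seed(derive_seed(seed, "kmeans"), {
    for (sp in unique(species)) {
      r <- which(species == sp)
      x <- scores[r, seq_len(nc), drop = FALSE]
      k <- min(n, max(1, nrow(unique(x)) - 1))
      if (k <= 1) {
        assign[r] <- paste0(sp, ".1")
        models[[sp]] <- NULL
        next
      }
      km <- stats::kmeans(x, centers = k, nstart = 5, iter.max = 50)
      models[[sp]] <- km
      assign[r] <- paste0(sp, ".", km$cluster)
    }
  })
  structure(list(models = models, assignment = assign, n_components = nc),
            class = "ews_clusters")
}

#' Assign new rows to fitted clusters
#' @param object an `ews_clusters`
#' @param scores stage-2 scores of the new rows
#' @param species species per row
#' @param ... unused
#' @return character cluster ids
#' @export
predict.ews_clusters <- function(object, scores, species, ...) {
  out <- character(nrow(scores))
  nc <- object$n_components
  for (sp in unique(species)) {
    r <- which(species == sp)
    km <- object$models[[sp]]
    if (is.null(km)) { out[r] <- paste0(sp, ".1"); next }
    d <- as.matrix(stats::dist(rbind(km$centers,
                                     scores[r, seq_len(nc), drop = FALSE])))
    k <- nrow(km$centers)
    dd <- d[-(seq_len(k)), seq_len(k), drop = FALSE]
    out[r] <- paste0(sp, ".", max.col(-dd))
  }
  out
}
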