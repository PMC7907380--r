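#' Behavior-classifier specification
#'
#' Hyperparameters and pipeline settings for the per-animal response
#' classifier. Defaults follow the selected values of the original model
#' search: RBF-kernel C-classification SVM with gamma 10^-3.2 and cost
#' 10^-2.2 on the first 8 stage-2 principal components
#' (undisturbed-response), gamma 10^-2.0 / cost 10^-1.5 / 12 components
#' (flight-regroup), equal class weights, species-specific models, and a
#' centred moving-window maximum (15 min on both sides) over the SVM
#' probabilities.
#'
#' @param gamma,cost RBF kernel width and regularization
#' @param n_components stage-2 principal components fed to the SVM
#' @param gamma_fr,cost_fr,n_components_fr flight-regroup model settings
#' @param per_species fit one model per species (else pooled)
#' @param smooth_window window half-size in minutes
#' @param smooth_quantile quantile computed by the window (1 = maximum)
#' @param top_k top size per importance metric for feature selection
#' @param var_target stage-1 PCA retained variance
#' @param undisturbed_keep fraction of qualifying undisturbed rows kept
#' @param exclude_dist_m undisturbed training rows must be farther than
#'   this from the intruder
#' @param intensities response intensities included in training (2 =
#'   medium, 3 = high)
#' @param n_clusters unsupervised clusters per species
#' @param rf_rows,rf_ntree random-forest importance settings
#' @param seed seed for subsampling
#' @return a `behavior_spec` list
#' @export
behavior_spec <- function(gamma = 10^-3.2, cost = 10^-2.2, n_components = 8,
                          gamma_fr = 10^-2.0, cost_fr = 10^-1.5,
                          n_components_fr = 12,
                          per_species = TRUE, smooth_window = 15,
                          smooth_quantile = 1, top_k = 125, var_target = 0.95,
                          undisturbed_keep = 0.1, exclude_dist_m = 1000,
                          intensities = c(2, 3), n_clusters = 25,
                          rf_rows = 2000, rf_ntree = 200, seed = 1) {
  structure(as.list(environment()), class = "behavior_spec")
}

#' Construct the behavior-classifier training rows
#'
#' Training uses intrusion-period segments only. Undisturbed rows must be
#' separated by more than `exclude_dist_m` from the intruder, and 90% of
#' them are removed (seeded) to balance the classes; response rows are
#' restricted to the configured intensities (default medium and high).
#'
#' @param features an `ews_features`
#' @param segments segment table
#' @param spec a [behavior_spec()]
#' @param use_intrusions intrusion ids to draw training rows from
#' @return integer row indices into `features`
#' @export
build_training_set <- function(features, segments, spec,
                               use_intrusions = unique(segments$intrusion_id)) {
  seg_ok <- segments$segment_id[segments$truth == "intrusion" &
                                  segments$intrusion_id %in% use_intrusions]
  in_seg <- features$segment_id %in% seg_ok
  far <- is.na(features$dist_intruder) | features$dist_intruder > spec$exclude_dist_m
  und <- which(in_seg & features$label == 0 & far)
  resp <- which(in_seg & features$label > 0 &
                  features$intensity %in% spec$intensities)
  if (length(resp) == 0) stop("no response rows available for training")
  keep_n <- max(1, round(length(und) * spec$undisturbed_keep))
  und <- with_seed(derive_seed(spec$seed, "train-undisturbed"),
                   sort(sample(und, keep_n)))
  sort(c(und, resp))
}

#' Fit the kernel behavior classifier
#'
#' RBF-kernel C-classification SVM with probability output (Platt-type
#' score-to-probability mapping fitted on the training data) and equal
#' class weights.
#'
#' @param x matrix of component scores (first `n` columns are used)
#' @param y binary factor/vector (positive class last level)
#' @param gamma,cost hyperparameters
#' @param n_components columns of `x` used
#' @return an `e1071::svm` fit
#' @export
fit_behavior_model <- function(x, y, gamma = 10^-3.2, cost = 10^-2.2,
                               n_components = 8) {
  x <- as.matrix(x)[, seq_len(min(n_components, ncol(x))), drop = FALSE]
  if (any(!is.finite(x))) stop("non-finite inputs to fit_behavior_model")
  y <- factor(y)
  stopifnot(nlevels(y) == 2)
  w <- stats::setNames(c(1, 1), levels(y))
  e1071::svm(x, y, kernel = "radial", gamma = gamma, cost = cost,
             probability = TRUE, class.weights = w, scale = FALSE)
}

svm_prob <- function(model, x, n_components, positive) {
  x <- as.matrix(x)[, seq_len(min(n_components, ncol(x))), drop = FALSE]
  x[!is.finite(x)] <- 0
  pr <- stats::predict(model, x, probability = TRUE)
  attr(pr, "probabilities")[, positive]
}

#' Moving-window quantile smoother for probability series
#'
#' Centred window of `window` minutes on both sides; the default quantile
#' of 1 is the running maximum. Edges use the available support.
#'
#' @param p probability series (regular 1-min)
#' @param window half-size (minutes)
#' @param quantile window quantile (1 = max)
#' @param align `"center"` (default), `"left"`, or `"right"`
#' @return smoothed series, same length
#' @export
smooth_probabilities <- function(p, window = 15, quantile = 1,
                                 align = "center") {
  if (length(p) == 0) return(p)
  width <- if (align == "center") 2 * window + 1 else window + 1
  f <- if (quantile >= 1) max else function(v) stats::quantile(v, quantile, names = FALSE)
  zoo::rollapply(p, width, f, align = align, partial = TRUE)
}

#' Precision-recall curve, average precision, and the max-F1 boundary
#'
#' @param probs predicted probabilities
#' @param labels 0/1 truth
#' @return an `ews_pr`: `curve` (threshold, precision, recall, f1), `ap`
#'   (area under the precision-recall curve, step-wise), `max_f1`,
#'   `boundary_f1` (probability threshold attaining it), `prevalence`
#' @export
precision_recall_curve <- function(probs, labels) {
  stopifnot(length(unique(labels)) == 2)
  o <- order(probs, decreasing = TRUE)
  y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  pos <- sum(y)
  precision <- tp / (tp + fp)
  recall <- tp / pos
  # step-wise AP: sum over increments in recall of the precision there
  ap <- sum(diff(c(0, recall)) * precision)
  f1 <- 2 * precision * recall / (precision + recall + 1e-12)
  best <- which.max(f1)
  structure(list(
    curve = data.frame(threshold = probs[o], precision = precision,
                       recall = recall, f1 = f1),
    ap = ap, max_f1 = f1[best], boundary_f1 = probs[o][best],
    prevalence = mean(labels)
  ), class = "ews_pr")
}

#' @export
print.ews_pr <- function(x, ...) {
  cat(sprintf("<ews_pr AP %.3f, max F1 %.3f at %.3f (prevalence %.3f)>\n",
              x$ap, x$max_f1, x$boundary_f1, x$prevalence))
  invisible(x)
}

#' Leave-one-intrusion-out cross-validation of the behavior classifier
#'
#' For each intrusion, the standardization references, winsorization
#' quantiles, ordinal bins, feature importance, selection, PC stack,
#' clustering and SVMs are fitted on the remaining intrusions only, then
#' that intrusion's segments (intrusion and matched control) are predicted
#' out of fold. Average precision of the least occurring class (response)
#' is reported pooled and per fold, plus subgroup breakdowns by species,
#' intrusion mode and time of day.
#'
#' @param fbase output of [prepare_features()]
#' @param segments segment table
#' @param spec a [behavior_spec()]
#' @param verbose print fold progress
#' @return an `ews_loio`: `predictions` (per animal-minute: out-of-fold raw
#'   and smoothed probabilities, cluster assignment, fold id), `ap`
#'   (pooled), `ap_per_fold`, `ap_subgroup`, `pr` (pooled PR curve object),
#'   `fold_audit` (train/test intrusion ids per fold)
#' @export
loio_cross_validate <- function(fbase, segments, spec = behavior_spec(),
                                verbose = FALSE) {
  intr_ids <- unique(segments$intrusion_id)
  stopifnot(length(intr_ids) >= 2)
  reg <- attr(fbase, "registry")
  preds <- list(); audit <- list()
  for (k in seq_along(intr_ids)) {
    hold <- intr_ids[k]
    train_intr <- setdiff(intr_ids, hold)
    train_seg <- segments$segment_id[segments$intrusion_id %in% train_intr]
    test_seg <- segments$segment_id[segments$intrusion_id == hold]
    if (verbose) message("fold ", k, "/", length(intr_ids), ": hold ", hold)
    fold <- fit_behavior_fold(fbase, segments, spec, train_intr, train_seg)
    test_rows <- which(fbase$segment_id %in% test_seg)
    p <- predict_behavior_fold(fold, fold$features[test_rows], spec)
    pk <- fold$features[test_rows, .(segment_id, animal_id, species, time,
                                     x, y, label, intensity, dist_intruder)]
    pk[, `:=`(p_raw = p$prob, cluster = p$cluster, fold = hold)]
    data.table::setorder(pk, segment_id, animal_id, time)
    pk[, p_smooth := smooth_probabilities(p_raw, spec$smooth_window,
                                          spec$smooth_quantile),
       by = .(segment_id, animal_id)]
    preds[[k]] <- pk
    audit[[k]] <- list(fold = hold, train = train_intr, test = hold)
  }
  predictions <- data.table::rbindlist(preds)
  # evaluate on intrusion-period rows (response labels only exist there)
  seg_meta <- segments[match(predictions$segment_id, segments$segment_id), ]
  eval_rows <- seg_meta$truth == "intrusion"
  ev <- predictions[eval_rows]
  ev_meta <- seg_meta[eval_rows, ]
  y <- as.integer(ev$label > 0)
  pr <- if (length(unique(y)) == 2) precision_recall_curve(ev$p_smooth, y)
  ap_fold <- ev[, {
    yy <- as.integer(label > 0)
    if (length(unique(yy)) == 2) list(ap = precision_recall_curve(p_smooth, yy)$ap)
    else list(ap = NA_real_)
  }, by = fold]
  sub_ap <- function(g) {
    vapply(split(seq_len(nrow(ev)), g), function(i) {
      yy <- y[i]
      if (length(unique(yy)) < 2) return(NA_real_)
      precision_recall_curve(ev$p_smooth[i], yy)$ap
    }, 0)
  }
  structure(list(
    predictions = predictions,
    ap = if (!is.null(pr)) pr$ap else NA_real_,
    pr = pr,
    ap_per_fold = ap_fold,
    ap_subgroup = list(species = sub_ap(ev$species),
                       mode = sub_ap(ev_meta$mode),
                       tod = sub_ap(ev_meta$tod)),
    fold_audit = audit,
    prevalence = mean(y)
  ), class = "ews_loio")
}

#' @export
print.ews_loio <- function(x, ...) {
  cat(sprintf("<ews_loio: pooled AP %.3f (prevalence %.3f), %d folds>\n",
              x$ap, x$prevalence, length(x$fold_audit)))
  invisible(x)
}

# fit everything reference-dependent on the training intrusions
fit_behavior_fold <- function(fbase, segments, spec, train_intr, train_seg) {
  ref_rows <- fbase$segment_id %in% train_seg & fbase$label == 0
  f <- contextualize_features(fbase, ref_rows = ref_rows,
                              n_bins = spec$n_bins %||% 10, ordinal = FALSE)
  reg <- attr(f, "registry")
  feat_cols <- setdiff(reg$column, reg$column[reg$variant == "ordinal"])
  # importance on proximity labels within training segments
  lab <- rep(NA_integer_, nrow(f))
  seg_meta <- segments[match(f$segment_id, segments$segment_id), ]
  in_train <- f$segment_id %in% train_seg
  near <- in_train & seg_meta$truth == "intrusion" &
    !is.na(f$dist_intruder) & f$dist_intruder <= 1000
  lab[near] <- 1L
  ctl <- which(in_train & seg_meta$truth == "control")
  n1 <- sum(near)
  pick <- with_seed(derive_seed(spec$seed, "fold-controls"),
                    sample(ctl, min(n1, length(ctl))))
  lab[pick] <- 0L
  imp <- suppressWarnings(importance(as.data.frame(f)[, feat_cols],
                                     lab, rf_rows = spec$rf_rows,
                                     ntree = spec$rf_ntree, seed = spec$seed))
  sel <- select_top_union(imp, k = min(spec$top_k, nrow(imp)))
  classes <- stats::setNames(reg$class, reg$column)
  train_rows_all <- which(in_train & seg_meta$truth == "intrusion")
  pcs <- fit_pc_stack(as.data.frame(f)[train_rows_all, sel, drop = FALSE],
                      classes, var_target = spec$var_target)
  sc_train <- predict(pcs, as.data.frame(f)[train_rows_all, sel, drop = FALSE])
  cl <- unsupervised_clusters(sc_train, f$species[train_rows_all],
                              n = spec$n_clusters,
                              n_components = max(spec$n_components, 12),
                              seed = spec$seed)
  # SVM training rows
  tr_idx <- build_training_set(f, segments, spec, use_intrusions = train_intr)
  sc_tr <- predict(pcs, as.data.frame(f)[tr_idx, sel, drop = FALSE])
  y_tr <- as.integer(f$label[tr_idx] > 0)
  models <- list()
  if (spec$per_species) {
    for (sp in unique(f$species[tr_idx])) {
      r <- f$species[tr_idx] == sp
      if (length(unique(y_tr[r])) < 2) next
      models[[sp]] <- fit_behavior_model(sc_tr[r, , drop = FALSE], y_tr[r],
                                         spec$gamma, spec$cost, spec$n_components)
    }
  }
  if (length(unique(y_tr)) == 2)
    models[[".pooled"]] <- fit_behavior_model(sc_tr, y_tr, spec$gamma,
                                              spec$cost, spec$n_components)
  list(features = f, selected = sel, pcstack = pcs, clusters = cl,
       models = models, importance = imp, train_intrusions = train_intr)
}

predict_behavior_fold <- function(fold, frows, spec) {
  sc <- predict(fold$pcstack,
                as.data.frame(frows)[, fold$selected, drop = FALSE])
  prob <- rep(NA_real_, nrow(frows))
  for (sp in unique(frows$species)) {
    r <- frows$species == sp
    m <- fold$models[[sp]]
    if (is.null(m)) m <- fold$models[[".pooled"]]
    if (is.null(m)) { prob[r] <- 0; next }
    prob[r] <- svm_prob(m, sc[r, , drop = FALSE], spec$n_components, "1")
  }
  cluster <- predict(fold$clusters, sc, frows$species)
  list(prob = prob, cluster = cluster)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flight-versus-regroup classifier with grouped cross-validation
#'
#' Same construction as the undisturbed-response model but restricted to
#' response rows, distinguishing flight (label 1) from regroup (label 2).
#'
#' @inheritParams loio_cross_validate
#' @return list with per-row out-of-fold probabilities of regroup and the
#'   pooled AP of the least occurring class
#' @export
flight_regroup_cv <- function(fbase, segments, spec = behavior_spec()) {
  intr_ids <- unique(segments$intrusion_id)
  preds <- list()
  for (hold in intr_ids) {
    train_intr <- setdiff(intr_ids, hold)
    train_seg <- segments$segment_id[segments$intrusion_id %in% train_intr]
    test_seg <- segments$segment_id[segments$intrusion_id == hold]
    ref_rows <- fbase$segment_id %in% train_seg & fbase$label == 0
    f <- contextualize_features(fbase, ref_rows = ref_rows)
    reg <- attr(f, "registry")
    feat_cols <- setdiff(reg$column, reg$column[reg$variant == "ordinal"])
    tr <- which(f$segment_id %in% train_seg & f$label > 0 &
                  f$intensity %in% spec$intensities)
    te <- which(f$segment_id %in% test_seg & f$label > 0)
    if (length(te) == 0 || length(unique(f$label[tr])) < 2) next
    classes <- stats::setNames(reg$class, reg$column)
    pcs <- fit_pc_stack(as.data.frame(f)[tr, feat_cols, drop = FALSE], classes,
                        var_target = spec$var_target)
    m <- fit_behavior_model(predict(pcs, as.data.frame(f)[tr, feat_cols, drop = FALSE]),
                            as.integer(f$label[tr] == 2),
                            spec$gamma_fr, spec$cost_fr, spec$n_components_fr)
    p <- svm_prob(m, predict(pcs, as.data.frame(f)[te, feat_cols, drop = FALSE]),
                  spec$n_components_fr, "1")
    preds[[hold]] <- data.table::data.table(
      f[te, .(segment_id, animal_id, time, label)], p_regroup = p, fold = hold)
  }
  predictions <- data.table::rbindlist(preds)
  y <- as.integer(predictions$label == 2)
  ap <- if (length(unique(y)) == 2) {
    pos <- if (mean(y) <= 0.5) y else 1 - y
    pp <- if (mean(y) <= 0.5) predictions$p_regroup else 1 - predictions$p_regroup
    precision_recall_curve(pp, pos)$ap
  } else NA_real_
  list(predictions = predictions, ap = ap)
}
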