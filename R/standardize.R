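#' Build a reference set for contextual standardization
#'
#' Per-group mean and variance of selected features, computed from
#' undisturbed data only. Groups with too few rows or (near-)zero variance
#' are flagged degenerate and fall back to species-level statistics at
#' transform time.
#'
#' @param features an `ews_features` (or any data.table with the context
#'   key columns)
#' @param kind one of `"species"`, `"area_30m"`, `"timeofday_5wk"`,
#'   `"area_timeofday_5wk"`, `"individual_timeofday_5wk"`
#' @param columns feature columns to build statistics for
#' @param rows logical/integer subset defining the reference pool
#'   (undisturbed rows of the training phase); default: all `label == 0`
#' @param min_n minimum rows per group
#' @return an `ews_reference`
#' @export
build_reference <- function(features, kind, columns,
                            rows = features$label == 0, min_n = 5) {
  keys <- reference_keys(kind)
  pool <- data.table::as.data.table(features)[rows]
  stats_dt <- pool[, c(
    list(.n = .N),
    unlist(lapply(.SD, function(v) {
      list(m = mean(v, na.rm = TRUE), v = stats::var(v, na.rm = TRUE))
    }), recursive = FALSE)
  ), by = keys, .SDcols = columns]
  fallback <- pool[, c(
    list(.n = .N),
    unlist(lapply(.SD, function(v) {
      list(m = mean(v, na.rm = TRUE), v = stats::var(v, na.rm = TRUE))
    }), recursive = FALSE)
  ), by = "species", .SDcols = columns]
  structure(list(kind = kind, keys = keys, columns = columns,
                 stats = stats_dt, fallback = fallback, min_n = min_n),
            class = "ews_reference")
}

reference_keys <- function(kind) {
  switch(kind,
    species = "species",
    area_30m = c("species", "area30"),
    timeofday_5wk = c("species", "tod", "period"),
    area_timeofday_5wk = c("species", "area30", "tod", "period"),
    individual_timeofday_5wk = c("animal_id", "tod", "period"),
    stop("unknown reference kind: ", kind))
}

#' @export
print.ews_reference <- function(x, ...) {
  cat(sprintf("<ews_reference %s: %d groups x %d features>\n",
              x$kind, nrow(x$stats), length(x$columns)))
  invisible(x)
}

#' Standardize features against a reference set
#'
#' Adds one z-variant column per reference feature: the deviation from the
#' group mean divided by the group standard deviation (default) or, taken
#' literally, the group variance (`divide = "variance"`). Degenerate or
#' unseen groups fall back to species-level statistics; missing inputs are
#' imputed at the group mean (z = 0).
#'
#' @param features an `ews_features`
#' @param reference an `ews_reference`
#' @param suffix variant tag appended as `<feature>__<suffix>`
#' @param divide `"sd"` (unit-variance outcome) or `"variance"` (literal)
#' @return the features table with z-columns added (registry updated)
#' @export
standardize <- function(features, reference, suffix = paste0("z_", reference$kind),
                        divide = c("sd", "variance")) {
  divide <- match.arg(divide)
  dt <- data.table::as.data.table(features)
  keys <- reference$keys
  st <- merge(dt[, keys, with = FALSE], reference$stats, by = keys,
              all.x = TRUE, sort = FALSE)
  fb <- merge(dt[, "species"], reference$fallback, by = "species",
              all.x = TRUE, sort = FALSE)
  n_fallback <- 0L
  for (cl in reference$columns) {
    m <- st[[paste0(cl, ".m")]]; v <- st[[paste0(cl, ".v")]]
    bad <- is.na(m) | is.na(v) | v < 1e-12 | st$.n < reference$min_n
    n_fallback <- n_fallback + sum(bad)
    m[bad] <- fb[[paste0(cl, ".m")]][bad]
    v[bad] <- fb[[paste0(cl, ".v")]][bad]
    v[!is.finite(v) | v < 1e-12] <- 1
    z <- (dt[[cl]] - m) / if (divide == "sd") sqrt(v) else v
    z[!is.finite(z)] <- 0
    data.table::set(dt, j = paste0(cl, "__", suffix), value = z)
  }
  reg <- attr(features, "registry")
  base_reg <- reg[match(reference$columns, reg$column), ]
  add <- data.frame(column = paste0(reference$columns, "__", suffix),
                    base = base_reg$base, class = base_reg$class,
                    variant = suffix, stringsAsFactors = FALSE)
  data.table::setattr(dt, "registry", rbind(reg, add))
  data.table::setattr(dt, "class", class(features))
  attr(dt, "n_fallback") <- n_fallback
  dt
}

#' Invert a standardization given its reference statistics
#'
#' @param z z-values
#' @param reference the `ews_reference` used
#' @param group one-row data.frame with the group key values
#' @param column base feature name
#' @param divide as in [standardize()]
#' @return original-scale values
#' @export
unstandardize <- function(z, reference, group, column, divide = "sd") {
  st <- merge(data.table::as.data.table(group), reference$stats,
              by = reference$keys)
  m <- st[[paste0(column, ".m")]]; v <- st[[paste0(column, ".v")]]
  z * (if (divide == "sd") sqrt(v) else v) + m
}

#' Moving-window feature variants
#'
#' For each designated base feature and each (segment, animal) series:
#' 5-min centred mean and SD, 10- and 20-min lagging means, and the
#' differences 5-min centred minus 10-/20-min lagging. Rows without
#' sufficient history are missing.
#'
#' @param features an `ews_features` (regular 1-min rows per animal)
#' @param columns base features to window (default [window_feature_set()])
#' @return the features table with window-variant columns added
#' @export
window_features <- function(features, columns = intersect(window_feature_set(),
                                                          names(features))) {
  dt <- data.table::as.data.table(features)
  data.table::setorder(dt, segment_id, animal_id, time)
  reg <- attr(features, "registry")
  adds <- list()
  for (cl in columns) {
    v5m <- v5s <- v10 <- v20 <- NULL
    dt[, c(paste0(cl, "__win_5c_mean"), paste0(cl, "__win_5c_sd"),
           paste0(cl, "__win_10l_mean"), paste0(cl, "__win_20l_mean")) := {
      v <- get(cl)
      m5 <- data.table::frollmean(v, 5, align = "center", na.rm = TRUE)
      s5 <- sqrt(pmax(data.table::frollmean(v^2, 5, align = "center", na.rm = TRUE) - m5^2, 0))
      m10 <- data.table::frollmean(v, 10, align = "right", na.rm = TRUE)
      m20 <- data.table::frollmean(v, 20, align = "right", na.rm = TRUE)
      # insufficient-history rows stay missing
      m10[seq_len(min(9, .N))] <- NA; m20[seq_len(min(19, .N))] <- NA
      list(m5, s5, m10, m20)
    }, by = .(segment_id, animal_id)]
    dt[, paste0(cl, "__win_diff_5c_10l") :=
         get(paste0(cl, "__win_5c_mean")) - get(paste0(cl, "__win_10l_mean"))]
    dt[, paste0(cl, "__win_diff_5c_20l") :=
         get(paste0(cl, "__win_5c_mean")) - get(paste0(cl, "__win_20l_mean"))]
    b <- reg[match(cl, reg$column), ]
    for (s in c("win_5c_mean", "win_5c_sd", "win_10l_mean", "win_20l_mean",
                "win_diff_5c_10l", "win_diff_5c_20l"))
      adds[[paste0(cl, "__", s)]] <- data.frame(
        column = paste0(cl, "__", s), base = cl, class = b$class,
        variant = s, stringsAsFactors = FALSE)
  }
  data.table::setattr(dt, "registry", rbind(reg, do.call(rbind, adds)))
  data.table::setattr(dt, "class", class(features))
  dt
}

#' Log-transform, winsorize, and ordinally discretize features
#'
#' Right-skewed base features are log(1+x)-transformed in place; every
#' feature column is truncated at its per-species 0.001 / 0.999 quantiles
#' (computed on the reference rows); an ordinal variant (quantile bin index
#' in 1..n_bins) is added for every raw base feature. Constant columns
#' collapse to a single bin with a warning.
#'
#' @param features an `ews_features`
#' @param n_bins number of ordinal bins
#' @param rows reference pool for the quantiles (default: all rows)
#' @param log_cols columns to log-transform (default [log_features()])
#' @param winsorize apply the truncation
#' @param ordinal add ordinal variants
#' @return the transformed features table
#' @export
transform_truncate_discretize <- function(features, n_bins = 10,
                                          rows = rep(TRUE, nrow(features)),
                                          log_cols = intersect(log_features(), names(features)),
                                          winsorize = TRUE, ordinal = TRUE) {
  dt <- data.table::as.data.table(features)
  reg <- attr(features, "registry")
  for (cl in log_cols) data.table::set(dt, j = cl, value = log1p(pmax(dt[[cl]], 0)))
  feat_cols <- intersect(reg$column, names(dt))
  sp_all <- dt$species
  pool <- dt[rows]
  for (sp in unique(sp_all)) {
    pr <- pool$species == sp; r <- sp_all == sp
    for (cl in feat_cols) {
      v <- pool[[cl]][pr]
      v <- v[is.finite(v)]
      if (length(v) < 10) next
      if (winsorize) {
        q <- stats::quantile(v, c(0.001, 0.999), na.rm = TRUE, names = FALSE)
        data.table::set(dt, i = which(r), j = cl,
                        value = pmin(pmax(dt[[cl]][r], q[1]), q[2]))
      }
    }
  }
  if (ordinal) {
    raw_cols <- reg$column[reg$variant == "raw"]
    adds <- list()
    for (cl in intersect(raw_cols, names(dt))) {
      binned <- rep(NA_integer_, nrow(dt))
      for (sp in unique(sp_all)) {
        r <- sp_all == sp
        v <- dt[[cl]][r]
        br <- unique(stats::quantile(v[is.finite(v)],
                                     probs = seq(0, 1, length.out = n_bins + 1),
                                     na.rm = TRUE, names = FALSE))
        if (length(br) < 3) {
          warning("constant column collapses to one bin: ", cl)
          binned[r] <- 1L
        } else {
          binned[r] <- findInterval(v, br[-c(1, length(br))]) + 1L
        }
      }
      nm <- paste0(cl, "__ordinal")
      data.table::set(dt, j = nm, value = binned)
      b <- reg[match(cl, reg$column), ]
      adds[[nm]] <- data.frame(column = nm, base = cl, class = b$class,
                               variant = "ordinal", stringsAsFactors = FALSE)
    }
    reg <- rbind(reg, do.call(rbind, adds))
  }
  data.table::setattr(dt, "registry", reg)
  data.table::setattr(dt, "class", class(features))
  dt
}

#' Row-local feature preparation (leakage-free phase)
#'
#' Base features, log transforms and moving-window variants: everything
#' that depends only on each animal's own series, never on pooled
#' statistics. The reference-dependent phase ([contextualize_features()])
#' is applied afterwards — per training fold inside cross-validation.
#'
#' @param minutes `minutes` table of an `ews_study`
#' @param landscape the study landscape
#' @return an `ews_features` with raw and window-variant columns
#' @export
prepare_features <- function(minutes, landscape) {
  f <- compute_base_features(minutes, landscape)
  f <- transform_truncate_discretize(f, rows = rep(TRUE, nrow(f)),
                                     winsorize = FALSE, ordinal = FALSE)
  window_features(f)
}

#' Reference-dependent feature phase
#'
#' Winsorization quantiles, the five z-variant families and ordinal bins,
#' all computed from a stated reference pool (the undisturbed rows of the
#' training phase) and applied to every row.
#'
#' @param f output of [prepare_features()]
#' @param ref_rows logical vector: reference pool
#' @param n_bins ordinal bins
#' @param ordinal add the ordinal variants (skippable inside model-fitting
#'   folds, where only continuous variants are consumed)
#' @return an `ews_features` with all variant columns
#' @export
contextualize_features <- function(f, ref_rows = f$label == 0, n_bins = 10,
                                   ordinal = TRUE) {
  f <- transform_truncate_discretize(f, n_bins = n_bins, rows = ref_rows,
                                     log_cols = character(),
                                     winsorize = TRUE, ordinal = FALSE)
  f <- contextual_standardize(f, ref_rows = ref_rows)
  if (!ordinal) return(f)
  transform_truncate_discretize(f, n_bins = n_bins, rows = ref_rows,
                                log_cols = character(),
                                winsorize = FALSE, ordinal = TRUE)
}

#' Full feature matrix without cross-validation
#'
#' Convenience wrapper: [prepare_features()] then
#' [contextualize_features()] with all undisturbed rows as reference.
#' @param study an `ews_study`
#' @param n_bins ordinal bins
#' @return an `ews_features`
#' @export
build_feature_matrix <- function(study, n_bins = 10) {
  f <- prepare_features(study$minutes, study$landscape)
  contextualize_features(f, ref_rows = f$label == 0, n_bins = n_bins)
}

# apply the five z-variant families (species-level on every feature column,
# four contextual references on the designated subset)
contextual_standardize <- function(f, ref_rows) {
  reg <- attr(f, "registry")
  all_cols <- reg$column
  ref_sp <- build_reference(f, "species", all_cols, rows = ref_rows)
  f <- standardize(f, ref_sp, suffix = "z_species")
  ctx <- intersect(context_features(), names(f))
  for (kind in c("area_30m", "timeofday_5wk", "area_timeofday_5wk",
                 "individual_timeofday_5wk")) {
    rf <- build_reference(f, kind, ctx, rows = ref_rows)
    f <- standardize(f, rf, suffix = paste0("z_", kind))
  }
  f
}
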