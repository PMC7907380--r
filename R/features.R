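#' Individual-geometry movement features for one regular track
#'
#' Per minute: step speed, absolute turning angle, directional persistence
#' (mean cosine of turns over a trailing window), net-gross distance ratio,
#' log-log mean-squared-displacement fit (slope and intercept over lags
#' 1..5 min in a trailing window), and the variance of log first-passage
#' times through configured radii. Zero-length steps yield missing turning
#' angles (imputed later at standardization).
#'
#' @param track data.frame with `time` (60-s regular), `x`, `y`
#' @param window trailing window length in minutes for the windowed stats
#' @param fpt_radii radii (m) for first-passage-time features
#' @param fpt_horizon_min censoring horizon for first passage (min)
#' @return data.frame of features aligned with `track` rows
#' @export
individual_geometry <- function(track, window = 10, fpt_radii = c(50, 100, 250),
                                fpt_horizon_min = 45) {
  n <- nrow(track)
  dx <- c(NA, diff(track$x)); dy <- c(NA, diff(track$y))
  step <- sqrt(dx^2 + dy^2)
  speed <- step / 60
  heading <- atan2(dy, dx)
  heading[which(step <= 1e-6)] <- NA
  turn <- c(NA, wrap_angle(diff(heading)))
  turn_abs <- abs(turn)
  persistence <- zoo::rollapplyr(cos(turn), 5, function(v) {
    v <- v[is.finite(v)]; if (length(v) < 2) NA_real_ else mean(v)
  }, fill = NA, partial = FALSE)
  # net-gross ratio over the trailing window
  net <- rep(NA_real_, n); gross <- rep(NA_real_, n)
  if (n > window) {
    i <- (window + 1):n
    net[i] <- sqrt((track$x[i] - track$x[i - window])^2 +
                     (track$y[i] - track$y[i - window])^2)
    gross <- zoo::rollsumr(ifelse(is.na(step), 0, step), window, fill = NA)
  }
  net_gross <- ifelse(gross > 1e-6, net / gross, NA)
  # MSD log-log fit over lags 1..5 within the trailing window
  lags <- 1:5
  sq <- sapply(lags, function(L) {
    v <- rep(NA_real_, n)
    v[(L + 1):n] <- (track$x[(L + 1):n] - track$x[1:(n - L)])^2 +
      (track$y[(L + 1):n] - track$y[1:(n - L)])^2
    zoo::rollmeanr(v, window, fill = NA)
  })
  lx <- log(lags * 60); lxc <- lx - mean(lx)
  lsq <- log(pmax(sq, 1e-9))
  msd_slope <- as.vector(lsq %*% lxc) / sum(lxc^2)
  msd_icept <- rowMeans(lsq)
  out <- data.frame(speed = speed, turn_abs = turn_abs,
                    persistence = persistence, net_gross = net_gross,
                    msd_slope = msd_slope, msd_icept = msd_icept)
  # first passage times
  fpt <- first_passage_times(track$x, track$y, fpt_radii, fpt_horizon_min)
  for (k in seq_along(fpt_radii)) {
    lf <- log(fpt[, k])
    out[[paste0("fpt_logvar_", fpt_radii[k])]] <- zoo::rollapplyr(lf, window,
      function(v) { v <- v[is.finite(v)]; if (length(v) < 3) NA_real_ else stats::var(v) },
      fill = NA)
  }
  out
}

# forward first passage time (minutes) through circles of given radii,
# censored (NA) at the horizon
first_passage_times <- function(x, y, radii, horizon_min) {
  n <- length(x)
  out <- matrix(NA_real_, n, length(radii))
  for (i in seq_len(n)) {
    jmax <- min(n, i + horizon_min)
    if (jmax <= i) next
    d <- sqrt((x[(i + 1):jmax] - x[i])^2 + (y[(i + 1):jmax] - y[i])^2)
    for (k in seq_along(radii)) {
      j <- which(d > radii[k])[1]
      if (!is.na(j)) out[i, k] <- j
    }
  }
  out
}

#' Accelerometer summary features for one regular track
#'
#' Windowed aggregates of the per-step ODBA statistics.
#' @param track data.frame with `odba_mean`, `odba_max`, `odba_var`
#' @param window trailing window (minutes)
#' @return data.frame of features
#' @export
accelerometer_features <- function(track, window = 5) {
  data.frame(
    odba_mean = track$odba_mean,
    odba_max = track$odba_max,
    odba_var = track$odba_var,
    odba_mean_w = zoo::rollmeanr(track$odba_mean, window, fill = NA),
    odba_max_w = zoo::rollapplyr(track$odba_max, window, max, fill = NA)
  )
}

#' Collective movement features for a snapshot of animals
#'
#' Per animal: distance to nearest neighbour, local density (neighbours
#' within `radius`), heading alignment (mean resultant length of neighbour
#' headings), speed synchrony, and distance to the group centroid. With no
#' neighbour inside the radius, alignment is missing and density 0.
#'
#' @param snap data.frame of simultaneous animals: `x`, `y`, `heading`,
#'   `speed`
#' @param radius neighbourhood radius (m)
#' @return data.frame of features aligned with `snap` rows
#' @export
collective_features <- function(snap, radius = 150) {
  n <- nrow(snap)
  if (n == 1) {
    return(data.frame(nn_dist = NA_real_, density = 0, align = NA_real_,
                      speed_sync = NA_real_, centroid_dist = 0))
  }
  dx <- outer(snap$x, snap$x, "-"); dy <- outer(snap$y, snap$y, "-")
  d <- sqrt(dx^2 + dy^2); diag(d) <- Inf
  nn_dist <- apply(d, 1, min)
  nb <- d < radius
  density <- rowSums(nb)
  align <- speed_sync <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- which(nb[i, ])
    if (length(j) == 0) next
    hh <- snap$heading[j]; hh <- hh[is.finite(hh)]
    if (length(hh) > 0)
      align[i] <- sqrt(mean(cos(hh))^2 + mean(sin(hh))^2)
    vbar <- mean(snap$speed[j])
    speed_sync[i] <- 1 - abs(snap$speed[i] - vbar) /
      (snap$speed[i] + vbar + 1e-9)
  }
  cx <- mean(snap$x); cy <- mean(snap$y)
  data.frame(nn_dist = nn_dist, density = density, align = align,
             speed_sync = speed_sync,
             centroid_dist = sqrt((snap$x - cx)^2 + (snap$y - cy)^2))
}

#' Space-use features for one regular track
#'
#' Habitat suitability and tree cover at position, elevation change per
#' step, Tobler-implied walking speed for the step's slope, an energetic
#' cost proxy (realized speed over Tobler speed), and the suitability
#' gradient along the heading.
#'
#' @param track data.frame with `time`, `x`, `y` (60-s regular)
#' @param landscape an `ews_landscape`
#' @param species species name (suitability layer)
#' @param tod time-of-day bin
#' @return data.frame of features
#' @export
space_use_features <- function(track, landscape, species, tod) {
  n <- nrow(track)
  suit <- landscape_value(landscape, "suitability", track$x, track$y,
                          species = species, tod = tod)
  tree <- landscape_value(landscape, "tree_cover", track$x, track$y)
  elev <- landscape_value(landscape, "elevation", track$x, track$y)
  dx <- c(NA, diff(track$x)); dy <- c(NA, diff(track$y))
  step <- sqrt(dx^2 + dy^2)
  dz <- c(NA, diff(elev))
  slope <- ifelse(step > 1, dz / step, 0)
  tobler_ms <- tobler_speed(slope) / 3.6
  speed <- step / 60
  cost <- speed / tobler_ms
  hx <- dx / pmax(step, 1e-9); hy <- dy / pmax(step, 1e-9)
  suit_ahead <- landscape_value(landscape, "suitability",
                                track$x + 30 * hx, track$y + 30 * hy,
                                species = species, tod = tod)
  data.frame(suitability = suit, tree_cover = tree, elev_change = dz,
             tobler_ms = tobler_ms, cost_tobler = cost,
             suit_gradient = (suit_ahead - suit) / 30)
}

# feature class registry: base feature -> main class
feature_classes <- function() {
  c(speed = "individual_geometry", turn_abs = "individual_geometry",
    persistence = "individual_geometry", net_gross = "individual_geometry",
    msd_slope = "individual_geometry", msd_icept = "individual_geometry",
    fpt_logvar_50 = "individual_geometry", fpt_logvar_100 = "individual_geometry",
    fpt_logvar_250 = "individual_geometry",
    odba_mean = "accelerometer", odba_max = "accelerometer",
    odba_var = "accelerometer", odba_mean_w = "accelerometer",
    odba_max_w = "accelerometer",
    nn_dist = "collective", density = "collective", align = "collective",
    speed_sync = "collective", centroid_dist = "collective",
    suitability = "space_use", tree_cover = "space_use",
    elev_change = "space_use", tobler_ms = "space_use",
    cost_tobler = "space_use", suit_gradient = "space_use")
}

# features receiving contextual (area / time-of-day / individual) z-variants
context_features <- function() {
  c("speed", "turn_abs", "persistence", "net_gross", "odba_mean", "align",
    "nn_dist", "suitability", "cost_tobler", "suit_gradient")
}

# features receiving moving-window variants
window_feature_set <- function() {
  c("speed", "turn_abs", "persistence", "net_gross", "odba_mean", "align",
    "nn_dist", "suitability", "cost_tobler", "speed_sync")
}

# log-transformed base features (right-skewed)
log_features <- function() {
  c("speed", "odba_mean", "odba_max", "odba_var", "odba_mean_w", "odba_max_w",
    "nn_dist", "centroid_dist", "cost_tobler")
}

#' Compute the base feature matrix for a study's animal-minutes
#'
#' Runs the four feature classes over every (segment, animal) track and
#' every (segment, minute, species) snapshot and returns the minutes table
#' extended with base feature columns plus context keys (time-of-day bin,
#' 5-week period, 30-m area cell). No feature depends on absolute
#' coordinates or absolute time.
#'
#' @param minutes the `minutes` data.table of an `ews_study`
#' @param landscape the study landscape
#' @param collective_radius neighbourhood radius (m)
#' @return an `ews_features` data.table; `attr(, "registry")` describes
#'   every feature column (base, class, variant)
#' @export
compute_base_features <- function(minutes, landscape, collective_radius = 150) {
  dt <- data.table::as.data.table(minutes)
  data.table::setorder(dt, segment_id, animal_id, time)
  dt[, tod := vapply(time[1], time_of_day_bin, ""), by = segment_id]
  t0 <- min(dt$time)
  dt[, period := floor((time - t0) / (35 * 86400))]
  dt[, area30 := paste0(floor(x / 30), "_", floor(y / 30))]

  geo <- dt[, individual_geometry(.SD), by = .(segment_id, animal_id),
            .SDcols = c("time", "x", "y")]
  acc <- dt[, accelerometer_features(.SD), by = .(segment_id, animal_id),
            .SDcols = c("odba_mean", "odba_max", "odba_var")]
  spu <- dt[, space_use_features(.SD, landscape, species[1], tod[1]),
            by = .(segment_id, animal_id),
            .SDcols = c("time", "x", "y", "species", "tod")]
  # collective: per segment-minute within species (herd topology)
  dt[, heading := {
    s <- sqrt(diff(x)^2 + diff(y)^2)
    h <- atan2(diff(y), diff(x)); h[s <= 1e-6] <- NA
    c(NA, h)
  }, by = .(segment_id, animal_id)]
  dt[, speed_tmp := c(NA, sqrt(diff(x)^2 + diff(y)^2) / 60),
     by = .(segment_id, animal_id)]
  col <- dt[, {
    cf <- collective_features(
      data.frame(x = x, y = y, heading = heading, speed = speed_tmp),
      radius = collective_radius)
    cbind(animal_id = animal_id, cf)
  }, by = .(segment_id, time, species)]
  data.table::setorder(col, segment_id, animal_id, time)

  out <- cbind(dt[, .(segment_id, animal_id, species, time, x, y, label,
                      intensity, dist_intruder, tod, period, area30)],
               geo[, -c("segment_id", "animal_id")],
               acc[, -c("segment_id", "animal_id")],
               col[, .(nn_dist, density, align, speed_sync, centroid_dist)],
               spu[, -c("segment_id", "animal_id")])
  cls <- feature_classes()
  reg <- data.frame(column = names(cls), base = names(cls), class = unname(cls),
                    variant = "raw", stringsAsFactors = FALSE)
  data.table::setattr(out, "registry", reg)
  data.table::setattr(out, "class", c("ews_features", class(out)))
  out
}

#' Total number of engineered feature columns
#' @param features an `ews_features`
#' @return integer count (reported, not asserted against any external tally)
#' @export
feature_count <- function(features) nrow(attr(features, "registry"))
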