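#' Preprocessing options
#'
#' Thresholds for the five-step trajectory reconstruction. Defaults:
#' hard speed cap 30 m/s for gross-error filtering; spike criteria
#' displacement > 500 m on both legs, neighbour gap < 100 m, turning angle
#' > 150 degrees; ODBA stationarity threshold on the windowed mean;
#' X-spline weights 1.0 (observed) / 0.3 (ODBA-interpolated).
#'
#' @param bbox_margin_m inflation of the study bounding box (m)
#' @param speed_cap_ms hard speed cap (m/s)
#' @param spike_leg_m,spike_gap_m,spike_turn_deg spike criteria
#' @param stationary_threshold windowed mean ODBA below which the animal is
#'   treated as stationary
#' @param spline_weight_interp X-spline weight for interpolated points
#' @param kalman_floor_q,kalman_floor_r variance floors for degenerate
#'   likelihood fits (process: (m/s^2)^2 per s; observation: m^2)
#' @return list of options
#' @export
prep_options <- function(bbox_margin_m = 500, speed_cap_ms = 30,
                         spike_leg_m = 500, spike_gap_m = 100,
                         spike_turn_deg = 150, stationary_threshold = 0.08,
                         spline_weight_interp = 0.3,
                         kalman_floor_q = 1e-6, kalman_floor_r = 1) {
  as.list(environment())
}

#' Step 1: filter gross positional errors
#'
#' Removes fixes outside the inflated study bounding box, then fixes that
#' imply a speed above the hard cap from the previous retained fix.
#'
#' @param st an `ews_sensor_track`
#' @param bbox an `ews_bbox`
#' @param opts [prep_options()]
#' @return the track with offending fixes removed; `attr(,"n_removed")`
#'   holds the count; an all-removed track signals via `attr(,"empty")`
#' @export
filter_gross_errors <- function(st, bbox, opts = prep_options()) {
  f <- st$fixes
  keep <- bbox_contains(bbox, f$x, f$y, margin = opts$bbox_margin_m)
  f <- f[keep, , drop = FALSE]
  if (nrow(f) > 1) {
    ok <- logical(nrow(f)); ok[1] <- TRUE; last <- 1
    for (i in 2:nrow(f)) {
      v <- sqrt((f$x[i] - f$x[last])^2 + (f$y[i] - f$y[last])^2) /
        (f$time[i] - f$time[last])
      if (v <= opts$speed_cap_ms) { ok[i] <- TRUE; last <- i }
    }
    f <- f[ok, , drop = FALSE]
  }
  out <- st
  out$fixes <- f
  attr(out, "n_removed") <- nrow(st$fixes) - nrow(f)
  attr(out, "empty") <- nrow(f) == 0
  out
}

#' Step 2: detect and correct spike outliers
#'
#' A fix is a spike when (a) the displacement to and away from it exceeds
#' `spike_leg_m` on both legs, (b) its neighbours are close together
#' (< `spike_gap_m`), and (c) the turning angle at it approaches 180
#' degrees (> `spike_turn_deg`). Flagged fixes are shifted towards the
#' midpoint of their neighbours; the spikier the geometry, the closer to
#' the midpoint the corrected fix lands (shift fraction in [0.5, 1),
#' monotone in the spikiness score). First/last fixes are never flagged.
#'
#' @inheritParams filter_gross_errors
#' @return list: `track` (corrected `ews_sensor_track`) and `diagnostics`
#'   (one row per flagged fix: legs, gap, turn, score, applied shift)
#' @export
correct_spikes <- function(st, opts = prep_options()) {
  f <- st$fixes
  n <- nrow(f)
  diag_df <- data.frame(fix = integer(), d_in = numeric(), d_out = numeric(),
                        gap = numeric(), turn = numeric(), score = numeric(),
                        shift = numeric())
  if (n < 3) return(list(track = st, diagnostics = diag_df))
  i <- 2:(n - 1)
  d_in <- sqrt((f$x[i] - f$x[i - 1])^2 + (f$y[i] - f$y[i - 1])^2)
  d_out <- sqrt((f$x[i + 1] - f$x[i])^2 + (f$y[i + 1] - f$y[i])^2)
  gap <- sqrt((f$x[i + 1] - f$x[i - 1])^2 + (f$y[i + 1] - f$y[i - 1])^2)
  h_in <- atan2(f$y[i] - f$y[i - 1], f$x[i] - f$x[i - 1])
  h_out <- atan2(f$y[i + 1] - f$y[i], f$x[i + 1] - f$x[i])
  turn <- abs(wrap_angle(h_out - h_in))
  flag <- pmin(d_in, d_out) > opts$spike_leg_m & gap < opts$spike_gap_m &
    turn > opts$spike_turn_deg * pi / 180
  if (any(flag)) {
    k <- i[flag]
    score <- pmin((pmin(d_in, d_out)[flag] / pmax(gap[flag], 1)) /
                    pmax(1 - turn[flag] / pi, 1e-3) / 100, 100)
    frac <- 1 - 0.5 * exp(-score / 5)
    mx <- (f$x[k - 1] + f$x[k + 1]) / 2; my <- (f$y[k - 1] + f$y[k + 1]) / 2
    shift <- frac * sqrt((mx - f$x[k])^2 + (my - f$y[k])^2)
    f$x[k] <- f$x[k] + frac * (mx - f$x[k])
    f$y[k] <- f$y[k] + frac * (my - f$y[k])
    diag_df <- data.frame(fix = k, d_in = d_in[flag], d_out = d_out[flag],
                          gap = gap[flag], turn = turn[flag], score = score,
                          shift = shift)
  }
  out <- st; out$fixes <- f
  list(track = out, diagnostics = diag_df)
}

#' Step 3: Kalman-smooth the fix coordinates
#'
#' Per-coordinate continuous-time local-linear-trend dynamic linear model
#' (position + velocity state) at the original, irregular timestamps.
#' Process and observation variances are estimated by maximum likelihood on
#' the joint x/y filter likelihood, then a two-sided RTS smoother replaces
#' the coordinates. Degenerate variance estimates fall back to configured
#' floors with a warning.
#'
#' @inheritParams filter_gross_errors
#' @return the track with smoothed coordinates
#' @export
kalman_smooth <- function(st, opts = prep_options()) {
  f <- st$fixes
  if (nrow(f) < 4) stop("kalman_smooth needs >= 4 fixes")
  nll <- function(par) {
    q <- exp(par[1]); r <- exp(par[2])
    -(kalman_llt_loglik(f$time, f$x, q, r) +
        kalman_llt_loglik(f$time, f$y, q, r))
  }
  fit <- stats::optim(c(log(1e-3), log(100)), nll, method = "Nelder-Mead",
                      control = list(maxit = 200))
  q <- exp(fit$par[1]); r <- exp(fit$par[2])
  if (!is.finite(q) || !is.finite(r) || q <= 0 || r <= 0) {
    warning("degenerate variance estimate; falling back to floors")
    q <- opts$kalman_floor_q; r <- opts$kalman_floor_r
  }
  q <- max(q, opts$kalman_floor_q); r <- max(r, opts$kalman_floor_r)
  out <- st
  out$fixes$x <- kalman_llt_smooth(f$time, f$x, q, r)
  out$fixes$y <- kalman_llt_smooth(f$time, f$y, q, r)
  attr(out, "kalman_q") <- q
  attr(out, "kalman_r") <- r
  out
}

#' Step 4: ODBA-informed densification to 10-s resolution
#'
#' Linear interpolation between consecutive fixes where the displacement is
#' distributed only over the 10-s slots whose windowed mean ODBA exceeds
#' the stationarity threshold; stationary slots repeat the previous
#' position. Gaps with no ODBA coverage fall back to plain linear
#' interpolation and are flagged.
#'
#' @inheritParams filter_gross_errors
#' @return data.frame `time`, `x`, `y`, `kind` ("observed"/"interpolated"),
#'   `odba_gap` flag
#' @export
odba_interpolate <- function(st, opts = prep_options()) {
  f <- st$fixes
  ow <- st$odba_windows
  odba_at <- function(tt) {
    # windowed mean ODBA covering each time
    idx <- findInterval(tt, ow$window_start)
    v <- rep(NA_real_, length(tt))
    inside <- idx >= 1 & idx <= nrow(ow) & tt < ow$window_start[pmin(idx + 1, nrow(ow))] + 15
    v[inside] <- ow$mean[idx[inside]]
    v
  }
  pieces <- list(data.frame(time = f$time[1], x = f$x[1], y = f$y[1],
                            kind = "observed", odba_gap = FALSE))
  if (nrow(f) > 1) for (i in 2:nrow(f)) {
    t0 <- f$time[i - 1]; t1 <- f$time[i]
    slots <- seq(t0, t1, by = 10)
    inner <- slots[-1]
    if (length(inner) > 1) {
      mid <- utils::head(inner, -1)
      act <- odba_at(mid - 5)
      gap_flag <- anyNA(act)
      w <- if (gap_flag) rep(1, length(mid)) else
        ifelse(act > opts$stationary_threshold, pmax(act - 0.05, 0), 0)
      # terminal sub-step always carries any residual displacement
      w <- c(w, if (gap_flag) 1 else max(mean(w), 1e-12))
      cw <- cumsum(w) / sum(w)
      xs <- f$x[i - 1] + cw * (f$x[i] - f$x[i - 1])
      ys <- f$y[i - 1] + cw * (f$y[i] - f$y[i - 1])
      pieces[[length(pieces) + 1]] <- data.frame(
        time = inner, x = xs, y = ys,
        kind = c(rep("interpolated", length(mid)), "observed"),
        odba_gap = gap_flag)
    } else {
      pieces[[length(pieces) + 1]] <- data.frame(time = t1, x = f$x[i], y = f$y[i],
                                                 kind = "observed", odba_gap = FALSE)
    }
  }
  out <- do.call(rbind, pieces)
  out[!duplicated(out$time), , drop = FALSE]
}

# evaluate an X-spline through (t, v) on a null device; per-point shape
# encodes the observed/interpolated weighting
xspline_eval <- function(t, v, w, xout) {
  shape <- -0.5 * w + 0.8 * (1 - w)
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  graphics::plot.new()
  graphics::plot.window(range(t), range(v) + c(-1, 1))
  p <- graphics::xspline(t, v, shape = shape, draw = FALSE)
  ok <- !duplicated(p$x)
  stats::approx(p$x[ok], p$y[ok], xout = xout, rule = 2)$y
}

#' Step 5: X-spline fit and regular 1-min resampling
#'
#' Fits an X-spline through the densified coordinates, giving the
#' ODBA-interpolated points a smaller weight than observed ones, and
#' samples the curve on the regular 60-s grid. Per-step ODBA statistics
#' are averaged onto the steps (mean of window means, max of maxima, mean
#' of variances).
#'
#' @param densified output of [odba_interpolate()]
#' @param odba_windows the sensor track's 15-s ODBA windows
#' @param opts [prep_options()]
#' @param animal_id identifier carried through
#' @return an `ews_regular_track` data.frame: `time` (multiples of 60 s),
#'   `x`, `y`, `odba_mean`, `odba_max`, `odba_var`, `provenance`
#' @export
xspline_resample <- function(densified, odba_windows, opts = prep_options(),
                             animal_id = "animal") {
  d <- densified
  if (nrow(d) < 4) stop("xspline_resample needs >= 4 points")
  t0 <- ceiling(min(d$time) / 60) * 60
  t1 <- floor(max(d$time) / 60) * 60
  if (t1 - t0 < 120) stop("coverage shorter than 2 min")
  grid <- seq(t0, t1, by = 60)
  w <- ifelse(d$kind == "observed", 1, opts$spline_weight_interp)
  x <- xspline_eval(d$time, d$x, w, grid)
  y <- xspline_eval(d$time, d$y, w, grid)
  prov <- d$kind[pmax(findInterval(grid, d$time), 1)]
  ow <- odba_windows
  stepi <- findInterval(ow$window_start, grid)
  agg <- data.table::data.table(i = stepi, m = ow$mean, mx = ow$max, v = ow$variance)[
    i >= 1 & i <= length(grid),
    .(om = mean(m), ox = max(mx), ov = mean(v)), by = i]
  odba_mean <- odba_max <- odba_var <- rep(NA_real_, length(grid))
  odba_mean[agg$i] <- agg$om; odba_max[agg$i] <- agg$ox; odba_var[agg$i] <- agg$ov
  structure(data.frame(animal_id = animal_id, time = grid, x = x, y = y,
                       odba_mean = odba_mean, odba_max = odba_max,
                       odba_var = odba_var, provenance = prov,
                       stringsAsFactors = FALSE),
            class = c("ews_regular_track", "data.frame"))
}

#' Full five-step reconstruction of one sensor track
#'
#' @param st an `ews_sensor_track`
#' @param bbox study bounding box
#' @param opts [prep_options()]
#' @return an `ews_regular_track` (or `NULL` with a warning when the track
#'   is too short to reconstruct)
#' @export
preprocess_track <- function(st, bbox, opts = prep_options()) {
  st1 <- filter_gross_errors(st, bbox, opts)
  if (isTRUE(attr(st1, "empty")) || nrow(st1$fixes) < 4) {
    warning("track too short after filtering: ", st$animal_id)
    return(NULL)
  }
  st2 <- correct_spikes(st1, opts)$track
  st3 <- kalman_smooth(st2, opts)
  dens <- odba_interpolate(st3, opts)
  out <- tryCatch(xspline_resample(dens, st$odba_windows, opts, st$animal_id),
                  error = function(e) NULL)
  if (is.null(out)) warning("coverage too short: ", st$animal_id)
  out
}

#' Decimate a high-resolution intrusion route to 1-min resolution
#'
#' Intruder GPS is accurate and dense, so reconstruction is a plain subset.
#' @param intrusion an `ews_intrusion`
#' @return data.frame time (multiples of 60), x, y
#' @export
decimate_intrusion <- function(intrusion) {
  r <- intrusion$route
  grid <- seq(ceiling(min(r$time) / 60) * 60, floor(max(r$time) / 60) * 60, by = 60)
  data.frame(time = grid,
             x = stats::approx(r$time, r$x, grid)$y,
             y = stats::approx(r$time, r$y, grid)$y)
}
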