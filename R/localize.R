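#' Wrapped normal probability density
#'
#' Density on the circle of a normal distribution with the given
#' (unwrapped) standard deviation wrapped onto (-pi, pi]; the series is
#' truncated at `wraps` wraps (default 10, relative truncation error far
#' below 1e-12 for sd up to ~3 rad). Large sd approaches the circular
#' uniform density 1/(2 pi).
#'
#' @param theta angle(s), radians
#' @param mean circular mean, radians
#' @param sd unwrapped standard deviation (> 0)
#' @param wraps series truncation
#' @return density values
#' @export
dwrapnorm <- function(theta, mean = 0, sd = 1, wraps = 10) {
  if (any(sd <= 0)) stop("sd must be positive")
  d <- wrap_angle(theta - mean)
  # enough wraps to cover ~6 sd so the truncation error stays negligible
  K <- max(wraps, ceiling(6 * max(sd) / (2 * pi)))
  out <- 0
  for (k in -K:K) out <- out + stats::dnorm(d + 2 * pi * k, 0, sd)
  out
}

#' Localization geometry parameters
#'
#' Response geometry (distance lognormal, heading wrapped normal) as
#' 3rd-order polynomials in t_s — minutes since the predicted response
#' onset, truncated at `ts_max` (45 min) — and constant null geometry for
#' undisturbed animals (fitted against randomly placed intrusion points to
#' absorb the study-area shape).
#'
#' @param mu1_poly,logsigma1_poly,logrho1_poly length-4 coefficient vectors
#'   (intercept, t, t^2, t^3) for the response log-mean distance, log
#'   log-sd, and log wrapped-normal sd
#' @param mu0,sigma0,rho0 null lognormal meanlog / sdlog and wrapped-normal
#'   sd
#' @param ts_max truncation of t_s (minutes)
#' @return a `geometry_params` object
#' @export
geometry_params <- function(mu1_poly = c(5.3, 0.09, -1e-3, 0),
                            logsigma1_poly = c(log(0.5), 0, 0, 0),
                            logrho1_poly = c(log(0.5), 0, 0, 0),
                            mu0 = 7.2, sigma0 = 0.6, rho0 = 10,
                            ts_max = 45) {
  stopifnot(length(mu1_poly) == 4, length(logsigma1_poly) == 4,
            length(logrho1_poly) == 4, sigma0 > 0, rho0 > 0)
  structure(list(mu1_poly = mu1_poly, logsigma1_poly = logsigma1_poly,
                 logrho1_poly = logrho1_poly, mu0 = mu0, sigma0 = sigma0,
                 rho0 = rho0, ts_max = ts_max),
            class = "geometry_params")
}

#' @export
print.geometry_params <- function(x, ...) {
  cat(sprintf("<geometry_params: mu1(0)=%.2f mu1(%d)=%.2f | null mu0=%.2f sigma0=%.2f rho0=%.2f>\n",
              eval_poly(x$mu1_poly, 0), x$ts_max,
              eval_poly(x$mu1_poly, x$ts_max), x$mu0, x$sigma0, x$rho0))
  invisible(x)
}

eval_poly <- function(b, t) b[1] + b[2] * t + b[3] * t^2 + b[4] * t^3

#' Evaluate the response geometry at a clamped t_s
#' @param params a `geometry_params`
#' @param t_s minutes since response onset (clamped to `[0, ts_max]`)
#' @return list mu1, sigma1, rho1
#' @export
response_geometry <- function(params, t_s) {
  t_s <- pmin(pmax(t_s, 0), params$ts_max)
  list(mu1 = eval_poly(params$mu1_poly, t_s),
       sigma1 = exp(eval_poly(params$logsigma1_poly, t_s)),
       rho1 = exp(eval_poly(params$logrho1_poly, t_s)))
}

#' Odds ratio of intrusion presence at candidate cells for one sentinel
#'
#' For each candidate location i: theta is the direction from i to the
#' animal, gamma the distance. The default reading mixes the
#' response-weighted and undisturbed-weighted joint densities in the
#' numerator (two-state mixture; the undisturbed directional term uses the
#' null wrapped-normal sd rho0):
#' `O = (p * f_wn(theta; mu_j, rho1) * f_ln(gamma; mu1, sigma1) +
#'      (1 - p) * f_wn(theta; mu_j, rho0) * f_ln(gamma; mu0, sigma0)) /
#'      (f_wn(theta; mu_j, rho0) * f_ln(gamma; mu0, sigma0))`,
#' so an undisturbed animal (p = 0) is uninformative (O = 1). The
#' `"additive"` reading replaces the numerator's undisturbed weight by 1
#' (O = 1 + p * likelihood-ratio).
#'
#' @param cell_x,cell_y candidate location coordinates (vectors)
#' @param animal one-row list/data.frame: `x`, `y`, `mu` (movement
#'   direction, rad), `p` (response probability), `t_s`
#' @param params a `geometry_params`
#' @param numerator `"mixture"` (default) or `"additive"`
#' @param odds_ceiling value assigned where the null density underflows
#' @return numeric vector of O_i over the candidate cells
#' @export
odds_surface <- function(cell_x, cell_y, animal, params,
                         numerator = c("mixture", "additive"),
                         odds_ceiling = 1e6) {
  numerator <- match.arg(numerator)
  dx <- animal$x - cell_x; dy <- animal$y - cell_y
  gamma <- sqrt(dx^2 + dy^2)
  gamma <- pmax(gamma, 1e-6)
  theta <- atan2(dy, dx)
  g <- response_geometry(params, if (is.null(animal$t_s) || is.na(animal$t_s)) 0 else animal$t_s)
  mu_j <- animal$mu
  f_resp <- dwrapnorm(theta, mu_j, g$rho1) * stats::dlnorm(gamma, g$mu1, g$sigma1)
  f_null <- dwrapnorm(theta, mu_j, params$rho0) *
    stats::dlnorm(gamma, params$mu0, params$sigma0)
  p <- animal$p
  num <- if (numerator == "mixture") p * f_resp + (1 - p) * f_null
  else f_null + p * f_resp
  o <- num / f_null
  o[!is.finite(o) | f_null < 1e-300] <- odds_ceiling
  o
}

#' Intruder-location probability surface
#'
#' P_i is the normalized cellwise sum of the per-animal odds ratios over a
#' regular grid spanning the bounding box; the normalization constant
#' alpha makes P_i integrate to 1 over the box. Animals without a defined
#' movement direction are excluded (logged in the result).
#'
#' @param snapshot data.frame of sentinels: `x`, `y`, `mu` (movement
#'   direction), `p`, `t_s`
#' @param params a `geometry_params`
#' @param bbox an `ews_bbox`
#' @param cell_m grid resolution (m)
#' @param numerator see [odds_surface()]
#' @return an `ews_surface`: `grid_x`, `grid_y`, `P` matrix (x by y),
#'   `alpha`, `peak` (x, y), `condensation_m2` (area holding the top 5%
#'   probability mass), `n_animals`, `n_excluded`
#' @export
probability_surface <- function(snapshot, params, bbox, cell_m = 50,
                                numerator = "mixture") {
  ok <- is.finite(snapshot$mu) & is.finite(snapshot$p)
  n_excluded <- sum(!ok)
  snapshot <- snapshot[ok, , drop = FALSE]
  stopifnot(nrow(snapshot) >= 1)
  gx <- seq(bbox$xmin + cell_m / 2, bbox$xmax - cell_m / 2, by = cell_m)
  gy <- seq(bbox$ymin + cell_m / 2, bbox$ymax - cell_m / 2, by = cell_m)
  cells <- expand.grid(x = gx, y = gy)
  S <- 0
  for (j in seq_len(nrow(snapshot)))
    S <- S + odds_surface(cells$x, cells$y, snapshot[j, ], params,
                          numerator = numerator)
  area <- cell_m^2
  alpha <- 1 / (sum(S) * area)
  P <- matrix(alpha * S, nrow = length(gx))
  pk <- arrayInd(which.max(P), dim(P))
  mass <- sort(as.vector(P) * area, decreasing = TRUE)
  ncell_top <- which(cumsum(mass) >= 0.05)[1]
  flat <- abs(max(P) - min(P)) < 1e-15
  structure(list(grid_x = gx, grid_y = gy, P = P, alpha = alpha,
                 cell_m = cell_m,
                 peak = if (flat) c(x = NA_real_, y = NA_real_)
                        else c(x = gx[pk[1]], y = gy[pk[2]]),
                 condensation_m2 = ncell_top * area,
                 n_animals = nrow(snapshot), n_excluded = n_excluded),
            class = "ews_surface")
}

#' @export
print.ews_surface <- function(x, ...) {
  cat(sprintf("<ews_surface %dx%d @%gm: peak (%.0f, %.0f), top-5%% area %.2f km2>\n",
              length(x$grid_x), length(x$grid_y), x$cell_m,
              x$peak[1], x$peak[2], x$condensation_m2 / 1e6))
  invisible(x)
}

#' Numerical integral of a probability surface over its bounding box
#' @param surface an `ews_surface`
#' @return scalar (1 up to numerical tolerance)
#' @export
surface_integral <- function(surface) sum(surface$P) * surface$cell_m^2

#' Fit localization geometry parameters from training observations
#'
#' Response observations (predicted responders with known intruder
#' position) provide per-t_s-bin maximum-likelihood lognormal fits of the
#' intruder-animal distance and wrapped-normal fits of the angular residual
#' between the animal's movement direction and the intruder-to-animal
#' direction; 3rd-order polynomials in t_s are then fitted through mu1,
#' log sigma1 and log rho1 (bins pooled when underpopulated). Null
#' observations (controls against randomly generated intrusion locations)
#' give the constant null parameters.
#'
#' @param resp data.frame: `t_s` (min), `dist` (m), `delta` (angular
#'   residual, rad)
#' @param null data.frame: `dist`, `delta`
#' @param ts_max truncation (min)
#' @param bin_min bin width (min)
#' @param min_per_bin minimum observations per bin before pooling
#' @return a `geometry_params`
#' @export
fit_geometry <- function(resp, null, ts_max = 45, bin_min = 5,
                         min_per_bin = 20) {
  resp <- resp[is.finite(resp$t_s) & is.finite(resp$dist) & resp$dist > 0, ]
  resp$t_s <- pmin(pmax(resp$t_s, 0), ts_max)
  # polynomial conditional mean of log distance
  fit_mu <- stats::lm(log(dist) ~ poly(t_s, 3, raw = TRUE), data = resp)
  mu1_poly <- unname(stats::coef(fit_mu))
  mu1_poly[is.na(mu1_poly)] <- 0
  # per-bin residual log-sd and circular sd, pooled when thin
  bins <- floor(resp$t_s / bin_min)
  tab <- table(bins)
  small <- as.numeric(names(tab))[tab < min_per_bin]
  if (length(small) > 0) {
    message("pooling ", length(small), " underpopulated t_s bins")
    bins[bins %in% small] <- -1
  }
  bdf <- data.frame(t_s = resp$t_s, r = stats::resid(fit_mu),
                    delta = resp$delta, bin = bins)
  agg <- do.call(rbind, lapply(split(bdf, bdf$bin), function(d) {
    data.frame(t_mid = mean(d$t_s), n = nrow(d),
               lsd = log(max(stats::sd(d$r), 1e-3)),
               lrho = log(max(circular_sd(d$delta), 1e-3)))
  }))
  polyfit <- function(yv) {
    if (nrow(agg) >= 4) {
      unname(stats::coef(stats::lm(yv ~ poly(t_mid, 3, raw = TRUE),
                                   data = agg, weights = agg$n)))
    } else c(stats::weighted.mean(yv, agg$n), 0, 0, 0)
  }
  ls_poly <- polyfit(agg$lsd); lr_poly <- polyfit(agg$lrho)
  ls_poly[is.na(ls_poly)] <- 0; lr_poly[is.na(lr_poly)] <- 0
  geometry_params(
    mu1_poly = mu1_poly, logsigma1_poly = ls_poly, logrho1_poly = lr_poly,
    mu0 = mean(log(null$dist[null$dist > 0])),
    sigma0 = stats::sd(log(null$dist[null$dist > 0])),
    rho0 = max(circular_sd(null$delta), 1e-3),
    ts_max = ts_max)
}

#' Evaluate localization accuracy over surfaces
#'
#' Each surface is reduced to its peak; per intrusion, the `n_best` most
#' condensed surfaces (smallest top-5% area) are selected and the mean
#' Euclidean peak-to-truth distance reported, plus dataset-level fractions
#' of intrusions localized within the given thresholds.
#'
#' @param surfaces data.frame: `intrusion_id`, `peak_x`, `peak_y`,
#'   `condensation_m2`, `truth_x`, `truth_y`
#' @param n_best surfaces kept per intrusion (all, flagged, when fewer)
#' @param thresholds error thresholds (m)
#' @return an `ews_localization_eval`: per-intrusion table and summary
#'   fractions
#' @export
evaluate_localization <- function(surfaces, n_best = 10,
                                  thresholds = c(100, 300, 500)) {
  per <- do.call(rbind, lapply(split(surfaces, surfaces$intrusion_id), function(d) {
    d <- d[is.finite(d$condensation_m2) & is.finite(d$peak_x), ]
    flagged <- nrow(d) < n_best
    d <- d[order(d$condensation_m2), ][seq_len(min(n_best, nrow(d))), ]
    err <- sqrt((d$peak_x - d$truth_x)^2 + (d$peak_y - d$truth_y)^2)
    data.frame(intrusion_id = d$intrusion_id[1], mean_error_m = mean(err),
               n_surfaces = nrow(d), flagged_short = flagged)
  }))
  rownames(per) <- NULL
  fr <- vapply(thresholds, function(th) mean(per$mean_error_m <= th), 0)
  structure(list(per_intrusion = per,
                 fraction_within = stats::setNames(fr, paste0(thresholds, "m")),
                 thresholds = thresholds),
            class = "ews_localization_eval")
}

#' @export
print.ews_localization_eval <- function(x, ...) {
  cat("<ews_localization_eval>\n  fractions within:",
      paste(sprintf("%s %.1f%%", names(x$fraction_within),
                    100 * x$fraction_within), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a sentinel snapshot from known geometry parameters
#'
#' Responders are placed around the intruder at lognormal distances and
#' wrapped-normal headings drawn from the response geometry at their t_s;
#' non-responders are uniform over the box with uniform headings.
#'
#' @param params a `geometry_params`
#' @param n_respond,n_null animal counts
#' @param intruder c(x, y)
#' @param bbox an `ews_bbox`
#' @param seed seed
#' @param t_s response clock of the responders (min; recycled)
#' @param p_respond,p_null response probabilities assigned (recycled)
#' @return data.frame snapshot: `x`, `y`, `mu`, `p`, `t_s`, `responder`
#' @export
simulate_snapshot <- function(params, n_respond = 10, n_null = 10,
                              intruder = c(1500, 1500),
                              bbox = ews_bbox(0, 3000, 0, 3000), seed = 1,
                              t_s = 10, p_respond = 0.9, p_null = 0.05) {
  with_seed(derive_seed(seed, "snapshot"), {
    ts_r <- rep_len(t_s, n_respond)
    g <- response_geometry(params, ts_r)
    d <- stats::rlnorm(n_respond, g$mu1, g$sigma1)
    phi <- stats::runif(n_respond, -pi, pi)
    x1 <- intruder[1] + d * cos(phi); y1 <- intruder[2] + d * sin(phi)
    mu1 <- wrap_angle(phi + stats::rnorm(n_respond, 0, g$rho1))
    x0 <- stats::runif(n_null, bbox$xmin, bbox$xmax)
    y0 <- stats::runif(n_null, bbox$ymin, bbox$ymax)
    mu0 <- stats::runif(n_null, -pi, pi)
    data.frame(
      x = c(x1, x0), y = c(y1, y0), mu = c(mu1, mu0),
      p = c(rep_len(p_respond, n_respond), rep_len(p_null, n_null)),
      t_s = c(ts_r, rep(0, n_null)),
      responder = rep(c(TRUE, FALSE), c(n_respond, n_null)))
  })
}

#' Extract per-minute sentinel snapshots from behavior predictions
#'
#' Movement direction comes from the reconstructed step into each minute;
#' t_s counts minutes since the start of the current above-boundary run of
#' the smoothed response probability (clamped downstream).
#'
#' @param predictions out-of-fold predictions with `x`, `y`, `p_smooth`
#' @param boundary response decision boundary (max-F1)
#' @return data.table with `segment_id`, `time`, `animal_id`, `x`, `y`,
#'   `mu`, `p`, `t_s`
#' @export
sentinel_snapshots <- function(predictions, boundary) {
  dt <- data.table::as.data.table(predictions)
  data.table::setorder(dt, segment_id, animal_id, time)
  dt[, mu := {
    s <- sqrt(diff(x)^2 + diff(y)^2)
    h <- atan2(diff(y), diff(x)); h[s <= 1e-6] <- NA
    c(NA, h)
  }, by = .(segment_id, animal_id)]
  dt[, t_s := {
    above <- p_smooth >= boundary
    r <- rle(above)
    starts <- rep(cumsum(c(1, utils::head(r$lengths, -1))), r$lengths)
    ts <- (seq_len(.N) - starts)
    ts[!above] <- 0
    ts
  }, by = .(segment_id, animal_id)]
  dt[, .(segment_id, time, animal_id, x, y, mu, p = p_smooth, t_s)]
}

#' Fit geometry parameters from out-of-fold predictions and truth
#'
#' @param predictions out-of-fold predictions (with `x`, `y`, `p_smooth`)
#' @param study the `ews_study` (intrusion routes and segment metadata)
#' @param boundary response decision boundary
#' @param n_null_points random intrusion locations for the null fit
#' @param seed seed for the random null locations
#' @return a `geometry_params`
#' @export
fit_geometry_from_predictions <- function(predictions, study, boundary,
                                          n_null_points = 2000, seed = 1) {
  snaps <- sentinel_snapshots(predictions, boundary)
  segs <- study$segments
  truth <- segs$truth[match(snaps$segment_id, segs$segment_id)]
  # response observations: responders during intrusions, with truth position
  resp_rows <- which(truth == "intrusion" & snaps$p >= boundary & snaps$t_s >= 0 &
                       is.finite(snaps$mu))
  rs <- snaps[resp_rows]
  resp <- data.table::rbindlist(lapply(split(rs, rs$segment_id), function(d) {
    intr <- study$intrusions[[d$segment_id[1]]]
    if (is.null(intr)) return(NULL)
    ip <- intrusion_at(intr, d$time)
    ok <- is.finite(ip$x)
    d <- d[ok]; ip <- ip[ok, ]
    data.table::data.table(
      t_s = d$t_s,
      dist = sqrt((d$x - ip$x)^2 + (d$y - ip$y)^2),
      delta = wrap_angle(atan2(d$y - ip$y, d$x - ip$x) - d$mu))
  }))
  # null observations: control rows against random intrusion locations
  ns <- snaps[truth == "control" & is.finite(snaps$mu)]
  bb <- study$landscape$bbox
  with_seed(derive_seed(seed, "null-points"), {
    idx <- sample(nrow(ns), min(n_null_points, nrow(ns)))
    px <- stats::runif(length(idx), bb$xmin, bb$xmax)
    py <- stats::runif(length(idx), bb$ymin, bb$ymax)
  })
  nn <- ns[idx]
  null <- data.frame(dist = sqrt((nn$x - px)^2 + (nn$y - py)^2),
                     delta = wrap_angle(atan2(nn$y - py, nn$x - px) - nn$mu))
  fit_geometry(as.data.frame(resp), null)
}

#' Localize intrusions: one surface per minute of each intrusion segment
#'
#' @param predictions out-of-fold predictions
#' @param study the `ews_study`
#' @param params fitted `geometry_params`
#' @param boundary response decision boundary
#' @param cell_m grid resolution
#' @param segment_ids intrusion segments to localize (default: all
#'   detected, i.e. every intrusion segment)
#' @param every_min localize every k-th minute (cadence)
#' @return data.frame of per-surface peaks, condensation and truth
#' @export
localize_study <- function(predictions, study, params, boundary,
                           cell_m = 50, segment_ids = NULL, every_min = 1) {
  snaps <- sentinel_snapshots(predictions, boundary)
  segs <- study$segments
  if (is.null(segment_ids))
    segment_ids <- intersect(names(study$intrusions), unique(snaps$segment_id))
  out <- list()
  for (sid in segment_ids) {
    intr <- study$intrusions[[sid]]
    d <- snaps[segment_id == sid]
    tms <- sort(unique(d$time))
    tms <- tms[seq(1, length(tms), by = every_min)]
    ip <- intrusion_at(intr, tms)
    for (k in seq_along(tms)) {
      if (!is.finite(ip$x[k])) next
      sn <- d[time == tms[k] & is.finite(mu)]
      if (nrow(sn) < 1) next
      su <- probability_surface(as.data.frame(sn)[, c("x", "y", "mu", "p", "t_s")],
                                params, study$landscape$bbox, cell_m = cell_m)
      out[[length(out) + 1]] <- data.frame(
        intrusion_id = segs$intrusion_id[segs$segment_id == sid],
        segment_id = sid, time = tms[k],
        peak_x = su$peak[1], peak_y = su$peak[2],
        condensation_m2 = su$condensation_m2,
        integral = surface_integral(su),
        truth_x = ip$x[k], truth_y = ip$y[k])
    }
  }
  do.call(rbind, out)
}
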