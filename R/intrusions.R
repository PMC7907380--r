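#' Generate an experimental-intrusion route
#'
#' A correlated walk through the study area at foot (~1.2 m/s) or vehicle
#' (~5 m/s) speed, positions every 5 s, lasting about two hours, reflected
#' at the landscape bounding box.
#'
#' @param landscape an `ews_landscape`
#' @param seed integer seed
#' @param start_time UTC seconds of the route start
#' @param mode `"foot"` or `"vehicle"`
#' @param duration_s route duration (s), default ca. 2 h
#' @param group_size number of people in the intruding group
#' @param intrusion_id identifier
#' @return an `ews_intrusion`: route data.frame (time, x, y), metadata
#' @export
generate_intrusion <- function(landscape, seed, start_time = 6 * 3600,
                               mode = c("foot", "vehicle"),
                               duration_s = 7200, group_size = 2,
                               intrusion_id = "intr_01") {
  mode <- match.arg(mode)
  speed <- if (mode == "foot") 1.2 else 5
  bb <- landscape$bbox
  tms <- seq(0, duration_s, by = 5)
  with_seed(derive_seed(seed, paste0("intrusion-", intrusion_id)), {
    x <- stats::runif(1, bb$xmin + 200, bb$xmax - 200)
    y <- stats::runif(1, bb$ymin + 200, bb$ymax - 200)
    h <- stats::runif(1, -pi, pi)
    xs <- numeric(length(tms)); ys <- numeric(length(tms))
    xs[1] <- x; ys[1] <- y
    for (k in 2:length(tms)) {
      h <- wrap_angle(h + stats::rnorm(1, 0, 0.15))
      x <- x + speed * 5 * cos(h); y <- y + speed * 5 * sin(h)
      if (x < bb$xmin || x > bb$xmax) { h <- wrap_angle(pi - h); x <- min(max(x, bb$xmin), bb$xmax) }
      if (y < bb$ymin || y > bb$ymax) { h <- wrap_angle(-h); y <- min(max(y, bb$ymin), bb$ymax) }
      xs[k] <- x; ys[k] <- y
    }
  })
  structure(list(
    intrusion_id = intrusion_id, mode = mode, group_size = group_size,
    start_time = start_time, end_time = start_time + duration_s,
    tod = time_of_day_bin(start_time),
    route = data.frame(time = start_time + tms, x = xs, y = ys)
  ), class = "ews_intrusion")
}

#' @export
print.ews_intrusion <- function(x, ...) {
  cat(sprintf("<ews_intrusion %s (%s, n=%d) %ds>\n", x$intrusion_id, x$mode,
              x$group_size, as.integer(x$end_time - x$start_time)))
  invisible(x)
}

# per-second intruder position over a simulation window; active flag marks
# seconds inside the route's time coverage
intruder_positions <- function(intrusion, start_time, duration_s) {
  tt <- start_time + seq_len(duration_s) - 1
  r <- intrusion$route
  active <- tt >= min(r$time) & tt <= max(r$time)
  x <- stats::approx(r$time, r$x, xout = tt, rule = 2)$y
  y <- stats::approx(r$time, r$y, xout = tt, rule = 2)$y
  list(x = x, y = y, active = active)
}

#' Interpolate an intrusion route at arbitrary times
#' @param intrusion an `ews_intrusion`
#' @param times UTC seconds
#' @return data.frame time, x, y (NA outside route coverage)
#' @export
intrusion_at <- function(intrusion, times) {
  r <- intrusion$route
  inside <- times >= min(r$time) & times <= max(r$time)
  x <- stats::approx(r$time, r$x, xout = times, rule = 2)$y
  y <- stats::approx(r$time, r$y, xout = times, rule = 2)$y
  x[!inside] <- NA_real_; y[!inside] <- NA_real_
  data.frame(time = times, x = x, y = y)
}

#' Write / read an intrusion route as GPX
#'
#' Minimal GPX 1.1 track with positions as `lat`/`lon` holding the projected
#' metre coordinates scaled by 1e-4 (the synthetic world is not georeferenced;
#' the scaling keeps values in a plausible degree range and round-trips
#' exactly within float precision).
#' @param intrusion an `ews_intrusion`
#' @param path output path
#' @export
write_intrusion_gpx <- function(intrusion, path) {
  r <- intrusion$route
  pts <- sprintf(
    '      <trkpt lat="%.9f" lon="%.9f"><time>%s</time></trkpt>',
    r$y * 1e-4, r$x * 1e-4,
    format(as.POSIXct(r$time, origin = "1970-01-01", tz = "UTC"),
           "%Y-%m-%dT%H:%M:%SZ"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gpx version="1.1" creator="sentinelews" xmlns="http://www.topografix.com/GPX/1/1">',
    sprintf('  <trk><name>%s</name><trkseg>', intrusion$intrusion_id),
    pts, "  </trkseg></trk>", "</gpx>"), path)
  invisible(path)
}

#' @rdname write_intrusion_gpx
#' @export
read_intrusion_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  tm <- as.numeric(as.POSIXct(xml2::xml_text(xml2::xml_find_all(pts, "time")),
                              format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  data.frame(
    time = tm,
    x = as.numeric(xml2::xml_attr(pts, "lon")) * 1e4,
    y = as.numeric(xml2::xml_attr(pts, "lat")) * 1e4
  )
}
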