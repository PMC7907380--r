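#' Generate a synthetic savanna landscape
#'
#' Builds spatially autocorrelated tree-cover and elevation rasters on a
#' shared grid by Fourier-domain Gaussian smoothing of white noise, and
#' derives a deterministic habitat-suitability layer per species and
#' time-of-day bin from tree cover and terrain slope. All layers share the
#' same grid; tree cover and suitability live in [0, 1].
#'
#' @param seed integer seed
#' @param extent_m extent of the square study area (m)
#' @param cell_m raster cell size (m)
#' @param species character vector of species to build suitability for
#' @param autocorr_range_m smoothing range of the random fields (m)
#' @return an `ews_landscape`: grid metadata, `tree_cover` and `elevation`
#'   matrices (rows index x, cols index y), `slope` magnitude, and
#'   `suitability[[species]][[tod]]` matrices
#' @export
generate_landscape <- function(seed, extent_m = 3000, cell_m = 10,
                               species = c("zebra", "wildebeest", "eland", "impala"),
                               autocorr_range_m = 250) {
  if (extent_m <= 0 || cell_m <= 0) stop("extent_m and cell_m must be positive")
  n <- as.integer(round(extent_m / cell_m))
  with_seed(derive_seed(seed, "landscape"), {
    tree <- gaussian_field(n, autocorr_range_m / cell_m)
    elev <- gaussian_field(n, 2 * autocorr_range_m / cell_m)
  })
  tree_cover <- stats::plogis(1.2 * tree)           # fraction in (0,1)
  elevation <- 1300 + 60 * elev                     # m a.s.l., gentle relief
  slope <- slope_magnitude(elevation, cell_m)

  tod_bins <- c("morning", "midday", "afternoon")
  # grass-preferring grazers prefer low tree cover; browsers tolerate more
  pref <- c(zebra = 0.25, wildebeest = 0.2, eland = 0.45, impala = 0.35)
  tod_shift <- c(morning = 0, midday = 0.08, afternoon = 0.03) # midday: shade
  suitability <- lapply(species, function(sp) {
    out <- lapply(tod_bins, function(tb) {
      s <- exp(-((tree_cover - (pref[[sp]] + tod_shift[[tb]]))^2) / (2 * 0.3^2)) *
        exp(-(slope / 0.20)^2)
      s / max(s)
    })
    names(out) <- tod_bins
    out
  })
  names(suitability) <- species

  structure(list(
    origin = c(x = 0, y = 0), cell_m = cell_m, n = n,
    bbox = ews_bbox(0, n * cell_m, 0, n * cell_m),
    tree_cover = tree_cover, elevation = elevation, slope = slope,
    suitability = suitability, species = species, tod_bins = tod_bins
  ), class = "ews_landscape")
}

# spatially autocorrelated standard-normal field via FFT smoothing
gaussian_field <- function(n, range_cells) {
  z <- matrix(stats::rnorm(n * n), n, n)
  d <- c(0:(n %/% 2), -((n - (n %/% 2 + 1)):1))
  k2 <- outer(d^2, d^2, "+")
  filt <- exp(-k2 * (pi * range_cells / n)^2)
  f <- Re(stats::fft(stats::fft(z) * filt, inverse = TRUE)) / (n * n)
  (f - mean(f)) / stats::sd(f)
}

slope_magnitude <- function(elev, cell_m) {
  n <- nrow(elev)
  gx <- (elev[c(2:n, n), ] - elev[c(1, 1:(n - 1)), ]) / (2 * cell_m)
  gy <- (elev[, c(2:n, n)] - elev[, c(1, 1:(n - 1))]) / (2 * cell_m)
  sqrt(gx^2 + gy^2)
}

#' @export
print.ews_landscape <- function(x, ...) {
  cat(sprintf("<ews_landscape %dx%d cells of %g m; species: %s>\n",
              x$n, x$n, x$cell_m, paste(x$species, collapse = ", ")))
  invisible(x)
}

# clamp continuous coordinates to cell indices
cell_index <- function(landscape, x, y) {
  i <- pmin(pmax(floor((x - landscape$origin[["x"]]) / landscape$cell_m) + 1, 1), landscape$n)
  j <- pmin(pmax(floor((y - landscape$origin[["y"]]) / landscape$cell_m) + 1, 1), landscape$n)
  cbind(i, j)
}

#' Look up a landscape layer at continuous coordinates
#'
#' Off-grid positions are clamped to the nearest cell.
#'
#' @param landscape an `ews_landscape`
#' @param layer one of `"tree_cover"`, `"elevation"`, `"slope"`, or
#'   `"suitability"` (then `species` and `tod` are required)
#' @param x,y coordinates (m)
#' @param species,tod suitability selectors
#' @return numeric vector of layer values
#' @export
landscape_value <- function(landscape, layer, x, y, species = NULL, tod = NULL) {
  ij <- cell_index(landscape, x, y)
  m <- if (layer == "suitability") {
    landscape$suitability[[species]][[tod]]
  } else landscape[[layer]]
  m[ij]
}

#' Tobler's hiking function
#'
#' Predicted walking speed on an incline: `6 * exp(-3.5 * |slope + 0.05|)`
#' km/h; maximal (6 km/h) on a gentle downhill slope of -0.05.
#'
#' @param slope rise over run (dimensionless, signed)
#' @return speed in km/h
#' @export
tobler_speed <- function(slope) 6 * exp(-3.5 * abs(slope + 0.05))

#' Write / read a landscape layer as gridded plain-text CSV
#'
#' The grid metadata travels in `#`-prefixed header comments so the file is
#' self-describing and text-only.
#' @param landscape an `ews_landscape`
#' @param layer layer name (see [landscape_value()])
#' @param path output path
#' @export
write_landscape_layer <- function(landscape, layer, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# layer: %s", layer), con)
  writeLines(sprintf("# origin_x: %g origin_y: %g cell_m: %g n: %d",
                     landscape$origin[["x"]], landscape$origin[["y"]],
                     landscape$cell_m, landscape$n), con)
  utils::write.table(landscape[[layer]], con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape_layer
#' @export
read_landscape_layer <- function(path) {
  hdr <- readLines(path, n = 2)
  meta <- as.numeric(regmatches(hdr[2], gregexpr("[-0-9.]+", hdr[2]))[[1]])
  m <- as.matrix(utils::read.csv(path, header = FALSE, comment.char = "#"))
  dimnames(m) <- NULL
  list(values = m, origin = c(x = meta[1], y = meta[2]), cell_m = meta[3])
}
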