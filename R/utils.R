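#' @useDynLib sentinelews, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# Quiet R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  ".", ".N", ".SD", "animal_id", "species", "minute", "segment_id", "herd_id",
  "label", "intensity", "x", "y", "time", "odba_mean", "cluster", "prob",
  "prob_smooth", "block", "truth", "t_s", "dist_m"
))

#' Wrap an angle to (-pi, pi]
#' @param a angle(s) in radians
#' @return wrapped angle(s)
#' @export
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w <= -pi] <- pi
  w
}

#' Derive a reproducible sub-seed from a master seed and a stage tag
#'
#' One master seed in the configuration fans out to independent per-stage
#' seeds so that any stage can be re-run in isolation with identical
#' randomness.
#'
#' @param seed master integer seed
#' @param tag character stage tag
#' @return integer seed in `[1, 2^31 - 2]`
#' @export
derive_seed <- function(seed, tag) {
  h <- rlang::hash(paste0(as.integer(seed), "::", tag))
  # fold the first 12 hex digits into a positive 31-bit integer
  v <- strtoi(substr(h, 1, 6), 16L) * 4096 + strtoi(substr(h, 7, 9), 16L)
  as.integer(v %% 2147483646L + 1L)
}

#' Axis-aligned bounding box constructor
#' @param xmin,xmax,ymin,ymax extent in projected metres
#' @return an `ews_bbox` list
#' @export
ews_bbox <- function(xmin, xmax, ymin, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  structure(list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
            class = "ews_bbox")
}

#' @export
print.ews_bbox <- function(x, ...) {
  cat(sprintf("<bbox [%g, %g] x [%g, %g] m>\n", x$xmin, x$xmax, x$ymin, x$ymax))
  invisible(x)
}

bbox_contains <- function(bbox, x, y, margin = 0) {
  x >= bbox$xmin - margin & x <= bbox$xmax + margin &
    y >= bbox$ymin - margin & y <= bbox$ymax + margin
}

bbox_area <- function(bbox) (bbox$xmax - bbox$xmin) * (bbox$ymax - bbox$ymin)

#' Heading of successive steps of a trajectory
#'
#' @param x,y coordinate vectors
#' @return headings in radians (atan2 convention, length `length(x)`, last
#'   value repeated); `NA` for zero-length steps
#' @export
step_headings <- function(x, y) {
  n <- length(x)
  if (n < 2) return(rep(NA_real_, n))
  dx <- diff(x); dy <- diff(y)
  h <- atan2(dy, dx)
  h[sqrt(dx^2 + dy^2) <= 1e-6] <- NA_real_
  c(h, h[n - 1])
}

#' Circular standard deviation from a sample of angles
#'
#' Uses the mean resultant length R: sd = sqrt(-2 log R), the standard
#' wrapped-normal moment estimator.
#' @param a angles in radians
#' @return non-negative scalar (Inf when R ~ 0)
#' @export
circular_sd <- function(a) {
  a <- a[is.finite(a)]
  if (length(a) == 0) return(NA_real_)
  R <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  R <- min(max(R, 1e-12), 1 - 1e-12)
  sqrt(-2 * log(R))
}

# stable seeded RNG scope
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
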