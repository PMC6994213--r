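#' Construct a behavior observation
#'
#' One droplet experiment is summarized as a two-dimensional behavior
#' observation: the mean droplet speed (mm/s) and the mean number of droplets
#' in the dish over the experiment.
#'
#' @param mean_speed mean droplet speed in mm/s, finite and non-negative
#' @param mean_droplet_count mean droplet count (dimensionless), finite and
#'   non-negative
#' @return a named numeric vector of class `behavior_observation`
#' @export
behavior_observation <- function(mean_speed, mean_droplet_count) {
  obs <- c(mean_speed = as.numeric(mean_speed),
           mean_droplet_count = as.numeric(mean_droplet_count))
  if (anyNA(obs) || any(!is.finite(obs)) || any(obs < 0)) {
    stop("invalid observation: speed and count must be finite and >= 0",
         call. = FALSE)
  }
  class(obs) <- "behavior_observation"
  obs
}

#' Observation-space bounds
#'
#' Per-dimension (low, high) bounds used to map raw observations into the unit
#' square, where goals are sampled and distances computed. The defaults
#' (speed 0-10 mm/s, count 0-10) cover the range of behaviors the synthetic
#' environment produces; they are configurable because real systems can
#' surprise.
#'
#' @param speed numeric `c(low, high)` for mean speed, mm/s
#' @param count numeric `c(low, high)` for mean droplet count
#' @return an object of class `observation_bounds`
#' @export
observation_bounds <- function(speed = c(0, 10), count = c(0, 10)) {
  b <- rbind(speed = as.numeric(speed), count = as.numeric(count))
  colnames(b) <- c("low", "high")
  if (any(!is.finite(b)) || any(b[, "low"] >= b[, "high"])) {
    stop("invalid bounds: need finite low < high on each dimension",
         call. = FALSE)
  }
  class(b) <- c("observation_bounds", class(b))
  b
}

#' Map an observation into normalized goal space
#'
#' Affine map per dimension onto `[0, 1]`; values outside the bounds are
#' clipped, not rejected. Monotone per dimension and idempotent after
#' clipping.
#'
#' @param obs a [behavior_observation()], or a numeric matrix with one
#'   observation per row (columns speed, count)
#' @param bounds an [observation_bounds()]
#' @return a 2-vector in the unit square (or an n x 2 matrix for matrix input)
#' @export
observation_to_goalspace <- function(obs, bounds) {
  stopifnot(inherits(bounds, "observation_bounds"))
  m <- if (is.matrix(obs)) obs else matrix(unclass(obs), nrow = 1L)
  lo <- unclass(bounds)[, "low"]
  hi <- unclass(bounds)[, "high"]
  u <- sweep(sweep(m, 2L, lo, "-"), 2L, hi - lo, "/")
  u[u < 0] <- 0
  u[u > 1] <- 1
  colnames(u) <- c("speed", "count")
  if (is.matrix(obs)) u else drop(u)
}
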