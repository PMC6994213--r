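#' Occupied cells of the behavior-space coverage grid
#'
#' Observations are mapped to the unit square via the bounds and binned on a
#' `G x G` grid; the occupied set is returned as sorted unique cell ids
#' `i * G + j` (0-based).
#'
#' @param ds an [exploration_dataset()]
#' @param bounds an [observation_bounds()]
#' @param G grid resolution per dimension (>= 2)
#' @return integer vector of occupied cell ids
#' @export
coverage_cells <- function(ds, bounds = observation_bounds(), G = 20L) {
  stopifnot(G >= 2L)
  if (n_records(ds) == 0L) return(integer(0))
  u <- observation_to_goalspace(dataset_observations(ds), bounds)
  ci <- pmin(G - 1L, floor(u[, 1L] * G))
  cj <- pmin(G - 1L, floor(u[, 2L] * G))
  sort(unique(as.integer(ci * G + cj)))
}

#' Behavior-space coverage of an exploration run
#'
#' Fraction of the observable behavior space occupied by a run's
#' observations. "Observable" is made concrete by normalizing against the
#' pooled occupied-cell union of all runs under comparison (`reference`);
#' with no reference the run itself is the reference and the fraction is 1
#' for any non-empty run. Also returns the per-prefix coverage curve, which
#' is non-decreasing.
#'
#' @param ds an [exploration_dataset()]
#' @param bounds an [observation_bounds()]
#' @param G grid resolution per dimension
#' @param reference list of datasets defining the pooled reference cell set
#'   (the run itself is always included)
#' @return list with `fraction`, `n_occupied`, `n_reference` and `curve`
#'   (numeric vector, one entry per experiment prefix)
#' @export
coverage <- function(ds, bounds = observation_bounds(), G = 20L,
                     reference = NULL) {
  stopifnot(G >= 2L)
  own <- coverage_cells(ds, bounds, G)
  ref <- own
  for (other in reference) {
    ref <- union(ref, coverage_cells(other, bounds, G))
  }
  denom <- max(length(ref), 1L)
  if (n_records(ds) == 0L) {
    return(list(fraction = 0, n_occupied = 0L, n_reference = length(ref),
                curve = numeric(0)))
  }
  u <- observation_to_goalspace(dataset_observations(ds), bounds)
  ci <- pmin(G - 1L, floor(u[, 1L] * G))
  cj <- pmin(G - 1L, floor(u[, 2L] * G))
  ids <- as.integer(ci * G + cj)
  curve <- cumsum(!duplicated(ids)) / denom
  list(fraction = length(own) / denom, n_occupied = length(own),
       n_reference = length(ref), curve = curve)
}

#' Count active droplet experiments
#'
#' An experiment is active when its mean droplet speed strictly exceeds the
#' threshold (3 mm/s by default).
#'
#' @param ds an [exploration_dataset()]
#' @param speed_threshold activity threshold, mm/s
#' @return integer count
#' @export
count_active <- function(ds, speed_threshold = 3) {
  sum(ds$records$mean_speed_mm_s > speed_threshold)
}

#' Welch's unequal-variance t test
#'
#' Two-sided test with the Welch-Satterthwaite degrees of freedom. When both
#' groups have zero variance and equal means, `t = 0` and `p = 1` by
#' convention.
#'
#' @param group_a,group_b numeric samples of size >= 2
#' @return list with `t`, `df` and two-sided `p`
#' @export
welch_t_test <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  na <- length(group_a); nb <- length(group_b)
  va <- stats::var(group_a) / na
  vb <- stats::var(group_b) / nb
  denom <- va + vb
  if (denom == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = na + nb - 2, p = 1))
    }
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = na + nb - 2, p = 0))
  }
  t_stat <- (mean(group_a) - mean(group_b)) / sqrt(denom)
  df <- denom^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  list(t = t_stat, df = df, p = p)
}

#' Fold change between two group means
#'
#' The reporting convention used for headline contrasts: the ratio of two
#' group means, rounded to the display precision appropriate for the
#' quantity (one decimal for small folds, whole numbers for large ones).
#'
#' @param mean_a,mean_b group means (`mean_a` is the numerator)
#' @param digits decimal places for rounding; `NULL` returns the raw ratio
#' @return the (rounded) fold change `mean_a / mean_b`
#' @export
fold_change <- function(mean_a, mean_b, digits = NULL) {
  stopifnot(mean_b != 0)
  ratio <- mean_a / mean_b
  if (is.null(digits)) ratio else round(ratio, digits)
}

#' Infer temperature from droplet behavior
#'
#' Distance-weighted k-nearest-neighbor regression in normalized observation
#' space (`k = min(5, n)`): for a fixed formulation the behavior observation
#' is a reproducible function of temperature, so behavior alone identifies
#' the ambient temperature. A query coinciding exactly with a training
#' observation returns that pair's temperature.
#'
#' @param train data frame with columns `mean_speed`, `mean_droplet_count`,
#'   `temperature_C` (>= 1 row)
#' @param query a [behavior_observation()]
#' @param bounds an [observation_bounds()]
#' @param k neighborhood size cap
#' @return the inferred temperature, degrees Celsius
#' @export
infer_temperature <- function(train, query, bounds = observation_bounds(),
                              k = 5L) {
  stopifnot(is.data.frame(train), nrow(train) >= 1L)
  m <- as.matrix(train[, c("mean_speed", "mean_droplet_count")])
  colnames(m) <- c("speed", "count")
  u_train <- observation_to_goalspace(m, bounds)
  u_q <- observation_to_goalspace(query, bounds)
  d <- sqrt((u_train[, 1L] - u_q[[1L]])^2 + (u_train[, 2L] - u_q[[2L]])^2)
  if (min(d) < 1e-12) {
    return(train$temperature_C[which.min(d)])
  }
  kk <- min(as.integer(k), nrow(train))
  nn <- order(d)[seq_len(kk)]
  w <- 1 / d[nn]^2
  sum(w * train$temperature_C[nn]) / sum(w)
}
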