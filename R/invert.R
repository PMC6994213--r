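#' Goal inversion: find the formulation predicted to realize a goal
#'
#' Minimizes the squared goal-space distance between the forward model's
#' prediction and a target observation,
#' `c(x) = || goalspace(lwr_predict(ds, normalize(x))) - goal ||^2`,
#' by CMA-ES search in the unit box with candidate renormalization onto the
#' mixture simplex. The best CMA-ES candidate is audited against a fixed
#' 4-level-per-axis box grid, so the achieved cost is never worse than the
#' best audit-grid point. Bit-reproducible for a fixed `inv_cfg$seed`.
#'
#' @param ds an [exploration_dataset()] with at least `fm_cfg$min_points`
#'   records
#' @param goal 2-vector in the unit square
#' @param fm_cfg a [forward_model_config()]
#' @param inv_cfg an [inversion_config()]
#' @param bounds an [observation_bounds()]
#' @return the best-found [oil_formulation()], with attributes `cost` and
#'   `evaluations`
#' @export
invert_goal <- function(ds, goal, fm_cfg = forward_model_config(),
                        inv_cfg = inversion_config(),
                        bounds = observation_bounds()) {
  stopifnot(inherits(ds, "exploration_dataset"), length(goal) == 2L)
  if (n_records(ds) < fm_cfg$min_points) {
    stop("model unavailable: need at least ", fm_cfg$min_points,
         " records, have ", n_records(ds), call. = FALSE)
  }
  x <- dataset_formulations(ds)
  y <- dataset_observations(ds)
  cost_fn <- function(cand) {
    cand <- normalize_rows(cand)
    pred <- lwr_predict_matrix(x, y, cand, fm_cfg)
    u <- observation_to_goalspace(pred, bounds)
    (u[, 1L] - goal[1L])^2 + (u[, 2L] - goal[2L])^2
  }
  stream <- rng_stream(inv_cfg$seed)
  best <- NULL
  for (r in 0:inv_cfg$restarts) {
    x0 <- if (r == 0L) rep(0.25, 4L) else stream_draw(stream, stats::runif, 4L)
    res <- cma_es_min(cost_fn, x0 = x0, sigma0 = inv_cfg$sigma0,
                      lower = rep(0, 4L), upper = rep(1, 4L),
                      popsize = inv_cfg$population_size,
                      max_evaluations = inv_cfg$max_evaluations,
                      stream = stream)
    if (is.null(best) || res$value < best$value) best <- res
  }
  # fixed 4-level-per-axis audit grid over the unit box
  lv <- c(0, 1 / 3, 2 / 3, 1)
  grid <- as.matrix(expand.grid(lv, lv, lv, lv))
  grid <- grid[rowSums(grid) > 0, ]
  gc_costs <- cost_fn(grid)
  gi <- which.min(gc_costs)
  evals <- best$evaluations + nrow(grid)
  if (gc_costs[gi] < best$value) {
    best <- list(par = grid[gi, ], value = gc_costs[gi])
  }
  f <- oil_formulation(normalize_rows(matrix(best$par, nrow = 1L))[1L, ])
  attr(f, "cost") <- best$value
  attr(f, "evaluations") <- evals
  f
}

#' Enumerate the simplex lattice of a given resolution
#'
#' All 4-part compositions of `resolution - 1`, scaled to sum to 1, in
#' lexicographic order of the ratio vector.
#'
#' @param resolution number of levels per axis (>= 2)
#' @return a matrix with one lattice point per row
#' @export
simplex_lattice <- function(resolution) {
  stopifnot(resolution >= 2L)
  m <- as.integer(resolution) - 1L
  pts <- list()
  for (a in 0:m) for (b in 0:(m - a)) for (cc in 0:(m - a - b)) {
    pts[[length(pts) + 1L]] <- c(a, b, cc, m - a - b - cc)
  }
  do.call(rbind, pts) / m
}

#' Exhaustive simplex-grid goal-inversion oracle
#'
#' Exact argmin of the same inversion cost over the simplex lattice of the
#' given resolution; ties broken by lexicographic order of the ratio vector
#' (the enumeration order). Intended as a test oracle for [invert_goal()].
#'
#' @inheritParams invert_goal
#' @param resolution lattice resolution (levels per axis, >= 2)
#' @return the lattice [oil_formulation()] with minimal cost, with attribute
#'   `cost`
#' @export
grid_invert_oracle <- function(ds, goal, fm_cfg = forward_model_config(),
                               bounds = observation_bounds(),
                               resolution = 5L) {
  stopifnot(inherits(ds, "exploration_dataset"))
  if (n_records(ds) == 0L) {
    stop("model unavailable: empty dataset", call. = FALSE)
  }
  x <- dataset_formulations(ds)
  y <- dataset_observations(ds)
  lattice <- simplex_lattice(resolution)
  pred <- lwr_predict_matrix(x, y, lattice, fm_cfg)
  u <- observation_to_goalspace(pred, bounds)
  costs <- (u[, 1L] - goal[1L])^2 + (u[, 2L] - goal[2L])^2
  # the lattice is enumerated in lexicographic order and which.min returns
  # the first minimum, so ties resolve to the lexicographically-first point
  best <- which.min(costs)
  f <- oil_formulation(lattice[best, ])
  attr(f, "cost") <- costs[[best]]
  f
}
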