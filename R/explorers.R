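#' Draw a formulation uniformly at random from the mixture simplex
#'
#' Flat Dirichlet sampling (normalized unit-rate exponentials), so each
#' component has marginal mean 1/4.
#'
#' @param stream an [rng_stream()]
#' @return an [oil_formulation()]
#' @export
sample_random_formulation <- function(stream) {
  e <- stream_draw(stream, stats::rexp, 4L)
  oil_formulation(e / sum(e))
}

#' Draw a temporary goal uniformly over the normalized observation space
#'
#' @param stream an [rng_stream()]
#' @param bounds an [observation_bounds()] (the goal lives in the unit square
#'   regardless; bounds define its physical meaning)
#' @return a 2-vector in the unit square
#' @export
sample_goal <- function(stream, bounds = observation_bounds()) {
  stream_draw(stream, stats::runif, 2L)
}

#' Choose the next experiment
#'
#' Random parameter search always picks a uniform random formulation and
#' never emits a goal. The curiosity algorithm (random goal exploration)
#' first runs `n_bootstrap` random experiments; afterwards each iteration
#' samples a fresh temporary goal uniformly over the observation space and
#' inverts it through the learned forward model. A failed inversion (model
#' unavailable) falls back to a random pick with a warning, consuming the
#' iteration.
#'
#' @param ds the current [exploration_dataset()]
#' @param cfg an [explorer_config()]
#' @param goal_stream,param_stream named [rng_stream()]s for goal sampling
#'   and random formulation sampling
#' @param inv_seed seed for this iteration's optimizer stream
#' @return list with `formulation` and `goal` (`NULL` when none was used)
#' @export
next_experiment <- function(ds, cfg, goal_stream, param_stream,
                            inv_seed = cfg$inv_cfg$seed) {
  if (cfg$algorithm == "random" || n_records(ds) < cfg$n_bootstrap) {
    return(list(formulation = sample_random_formulation(param_stream),
                goal = NULL))
  }
  goal <- sample_goal(goal_stream, cfg$bounds)
  inv_cfg <- cfg$inv_cfg
  inv_cfg$seed <- as.integer(inv_seed)
  f <- tryCatch(
    invert_goal(ds, goal, fm_cfg = cfg$fm_cfg, inv_cfg = inv_cfg,
                bounds = cfg$bounds),
    error = function(e) {
      warning("goal inversion unavailable (", conditionMessage(e),
              "); falling back to a random pick", call. = FALSE)
      NULL
    })
  if (is.null(f)) {
    return(list(formulation = sample_random_formulation(param_stream),
                goal = NULL))
  }
  list(formulation = f, goal = goal)
}

#' Run a closed-loop exploration
#'
#' Alternates strategy -> environment -> dataset for exactly `budget`
#' experiments. Fully reproducible from the run seed: goal sampling,
#' bootstrap/random picks, per-experiment environment noise and the
#' optimizer each draw from named child streams of `cfg$seed`.
#'
#' @param env_cfg an [env_config()]
#' @param cfg an [explorer_config()]
#' @param env_fn environment to query: `function(formulation, env_cfg)`
#'   returning a [behavior_observation()]. Defaults to
#'   [simulate_experiment()] with a per-experiment noise seed derived from
#'   the run seed.
#' @return an [exploration_dataset()] of exactly `cfg$budget` records with
#'   metadata describing the run
#' @export
run_exploration <- function(env_cfg, cfg, env_fn = NULL) {
  stopifnot(inherits(cfg, "explorer_config"))
  validate_env_config(env_cfg)
  goal_stream <- rng_stream(child_seed(cfg$seed, "goal"))
  param_stream <- rng_stream(child_seed(cfg$seed, "param"))
  opt_seed_base <- child_seed(cfg$seed, "opt")
  bounds_m <- unclass(cfg$bounds)
  ds <- exploration_dataset(metadata = list(
    algorithm = cfg$algorithm, budget = cfg$budget,
    n_bootstrap = cfg$n_bootstrap, seed = cfg$seed,
    temperature_C = env_cfg$temperature_C, env_seed = env_cfg$seed,
    bounds = list(speed = as.numeric(bounds_m["speed", ]),
                  count = as.numeric(bounds_m["count", ])),
    bandwidth_h = cfg$fm_cfg$bandwidth_h,
    duration_s = cfg$duration_s))
  if (cfg$budget == 0L) return(ds)
  for (i in seq_len(cfg$budget)) {
    pick <- next_experiment(ds, cfg, goal_stream, param_stream,
                            inv_seed = (opt_seed_base + i) %% 2147483629)
    obs <- if (is.null(env_fn)) {
      simulate_experiment(pick$formulation, env_cfg)
    } else {
      env_fn(pick$formulation, env_cfg)
    }
    ds <- add_record(ds, pick$formulation, obs,
                     temperature_C = env_cfg$temperature_C,
                     goal = pick$goal, seed = env_cfg$seed,
                     duration_s = cfg$duration_s)
  }
  ds
}
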