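#' Synthetic droplet-environment configuration
#'
#' Parameters of the synthetic stand-in for the physical droplet experiment.
#' The formulation-to-behavior map places a small number of localized
#' high-activity modes on the mixture simplex, gated by a sharp logistic
#' temperature regime shift, so that active droplet behavior is a rare event
#' at default settings and essentially disappears below the regime midpoint.
#'
#' @param temperature_C ambient temperature, degrees Celsius (15-35)
#' @param noise_speed_sd observation noise SD on mean speed, mm/s
#' @param noise_count_sd observation noise SD on mean droplet count
#' @param n_active_modes number of localized high-activity regions in
#'   formulation space
#' @param mode_width squared-exponential kernel length scale on the simplex
#' @param regime_shift_midpoint_C logistic temperature gate midpoint, deg C
#' @param regime_shift_steepness logistic gate steepness, 1/deg C
#' @param arena_radius_mm petri-dish arena radius, mm (32-mm dish -> 16)
#' @param n_droplets_initial droplets placed at the start of an experiment
#' @param seed integer seed controlling the mode landscape and observation
#'   noise
#' @return an object of class `env_config`
#' @export
env_config <- function(temperature_C = 27,
                       noise_speed_sd = 0.3,
                       noise_count_sd = 0.5,
                       n_active_modes = 3L,
                       mode_width = 0.10,
                       regime_shift_midpoint_C = 24.8,
                       regime_shift_steepness = 1.5,
                       arena_radius_mm = 16,
                       n_droplets_initial = 4L,
                       seed = 7L) {
  cfg <- list(temperature_C = as.numeric(temperature_C),
              noise_speed_sd = as.numeric(noise_speed_sd),
              noise_count_sd = as.numeric(noise_count_sd),
              n_active_modes = as.integer(n_active_modes),
              mode_width = as.numeric(mode_width),
              regime_shift_midpoint_C = as.numeric(regime_shift_midpoint_C),
              regime_shift_steepness = as.numeric(regime_shift_steepness),
              arena_radius_mm = as.numeric(arena_radius_mm),
              n_droplets_initial = as.integer(n_droplets_initial),
              seed = as.integer(seed))
  validate_env_config(cfg)
  class(cfg) <- "env_config"
  cfg
}

validate_env_config <- function(cfg) {
  ok <- cfg$temperature_C >= 15 && cfg$temperature_C <= 35 &&
    cfg$noise_speed_sd >= 0 && cfg$noise_count_sd >= 0 &&
    cfg$n_active_modes >= 1L && cfg$mode_width > 0 &&
    cfg$regime_shift_steepness > 0 && cfg$arena_radius_mm > 0 &&
    cfg$n_droplets_initial >= 1L
  if (!ok) stop("invalid environment config", call. = FALSE)
  invisible(cfg)
}

#' Forward-model (locally weighted linear regression) configuration
#'
#' @param bandwidth_h Gaussian kernel width in raw ratio space
#' @param ridge_lambda ridge regularization on the local slope coefficients
#' @param min_points effective-support threshold below which prediction falls
#'   back to the kernel-weighted mean of stored observations
#' @return an object of class `forward_model_config`
#' @export
forward_model_config <- function(bandwidth_h = 0.1, ridge_lambda = 1e-6,
                                 min_points = 5L) {
  stopifnot(bandwidth_h > 0, ridge_lambda >= 0, min_points >= 1L)
  structure(list(bandwidth_h = as.numeric(bandwidth_h),
                 ridge_lambda = as.numeric(ridge_lambda),
                 min_points = as.integer(min_points)),
            class = "forward_model_config")
}

#' Goal-inversion (CMA-ES) configuration
#'
#' @param sigma0 initial step size in the unit box
#' @param max_evaluations total cost-function evaluation budget per restart
#' @param population_size offspring per generation, or `NULL` for the
#'   standard `4 + floor(3 log d)` default
#' @param restarts additional independent restarts (>= 0)
#' @param seed integer seed for the optimizer stream
#' @return an object of class `inversion_config`
#' @export
inversion_config <- function(sigma0 = 0.3, max_evaluations = 400L,
                             population_size = NULL, restarts = 1L,
                             seed = 1L) {
  pop <- if (is.null(population_size)) 4L + as.integer(3 * log(4)) else
    as.integer(population_size)
  stopifnot(sigma0 > 0, max_evaluations >= pop, restarts >= 0L)
  structure(list(sigma0 = as.numeric(sigma0),
                 max_evaluations = as.integer(max_evaluations),
                 population_size = pop,
                 restarts = as.integer(restarts),
                 seed = as.integer(seed)),
            class = "inversion_config")
}

#' Explorer configuration
#'
#' @param algorithm `"CA"` (random goal exploration) or `"random"`
#'   (random parameter search)
#' @param budget total number of experiments
#' @param n_bootstrap initial random experiments before the forward model is
#'   first used (CA only); must not exceed the budget
#' @param seed run seed; goal/parameter/environment/optimizer streams are
#'   derived from it via [child_seed()]
#' @param fm_cfg a [forward_model_config()]
#' @param inv_cfg an [inversion_config()]
#' @param bounds an [observation_bounds()]
#' @param duration_s nominal experiment duration recorded in the log, seconds
#' @return an object of class `explorer_config`
#' @export
explorer_config <- function(algorithm = c("CA", "random"), budget = 1000L,
                            n_bootstrap = 10L, seed = 1L,
                            fm_cfg = forward_model_config(),
                            inv_cfg = inversion_config(),
                            bounds = observation_bounds(),
                            duration_s = 90) {
  algorithm <- match.arg(algorithm)
  budget <- as.integer(budget)
  # bootstrap picks can never exceed the budget
  n_bootstrap <- min(as.integer(n_bootstrap), budget)
  stopifnot(budget >= 0L, n_bootstrap >= 0L)
  structure(list(algorithm = algorithm, budget = budget,
                 n_bootstrap = n_bootstrap, seed = as.integer(seed),
                 fm_cfg = fm_cfg, inv_cfg = inv_cfg, bounds = bounds,
                 duration_s = as.numeric(duration_s)),
            class = "explorer_config")
}

#' Read a YAML configuration file
#'
#' Recognized top-level sections: `env`, `explorer`, `forward_model`,
#' `inversion`, `bounds`, `tracking`. Each section overrides the
#' corresponding constructor defaults; absent sections fall back to defaults.
#'
#' @param path YAML file path
#' @return a named list with elements `env`, `explorer`, `fm_cfg`, `inv_cfg`,
#'   `bounds`, `tracking`
#' @export
read_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  bounds <- do.call(observation_bounds, as.list(raw$bounds))
  fm_cfg <- do.call(forward_model_config, as.list(raw$forward_model))
  inv_cfg <- do.call(inversion_config, as.list(raw$inversion))
  env <- do.call(env_config, as.list(raw$env))
  exp_args <- as.list(raw$explorer)
  exp_args$fm_cfg <- fm_cfg
  exp_args$inv_cfg <- inv_cfg
  exp_args$bounds <- bounds
  explorer <- do.call(explorer_config, exp_args)
  tracking <- as.list(raw$tracking)
  list(env = env, explorer = explorer, fm_cfg = fm_cfg, inv_cfg = inv_cfg,
       bounds = bounds, tracking = tracking)
}

#' Write a configuration list to YAML
#'
#' @param cfg a named list of sections (as nested plain lists)
#' @param path output YAML path
#' @return `path`, invisibly
#' @export
write_config <- function(cfg, path) {
  plain <- lapply(cfg, function(x) {
    if (inherits(x, "observation_bounds")) {
      list(speed = as.numeric(unclass(x)["speed", ]),
           count = as.numeric(unclass(x)["count", ]))
    } else {
      lapply(unclass(x), function(v) if (is.matrix(v)) as.numeric(v) else v)
    }
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}
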