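#' Matched curiosity-vs-random exploration benchmark
#'
#' Runs matched seed pairs of the curiosity algorithm and random parameter
#' search against the same synthetic environment at one or more
#' temperatures, and reports per-run behavior-space coverage (normalized by
#' the pooled occupied-cell union of all runs at the same temperature) and
#' active-experiment counts (mean speed > 3 mm/s).
#'
#' @param seed master seed; environment landscape and all run seeds derive
#'   from it
#' @param n_pairs matched seed pairs per temperature
#' @param budget experiments per run
#' @param temperatures named or unnamed vector of temperatures, deg C
#' @param n_bootstrap CA bootstrap experiments
#' @param G coverage grid resolution
#' @param inv_cfg inversion configuration for the CA runs
#' @param bounds an [observation_bounds()]
#' @return list with `runs` (data frame: temperature, algorithm, pair,
#'   coverage, n_active, n_occupied) and `datasets` (nested list keyed by
#'   temperature and algorithm)
#' @export
run_benchmark <- function(seed = 1L, n_pairs = 5L, budget = 300L,
                          temperatures = c(hot = 27, cold = 22.6),
                          n_bootstrap = 10L,
                          G = 20L,
                          inv_cfg = inversion_config(max_evaluations = 240L,
                                                     restarts = 0L),
                          bounds = observation_bounds()) {
  env_seed <- child_seed(seed, "env-landscape")
  runs <- list()
  datasets <- list()
  for (ti in seq_along(temperatures)) {
    temp <- temperatures[[ti]]
    tname <- names(temperatures)[ti]
    if (is.null(tname) || !nzchar(tname)) tname <- as.character(temp)
    env_cfg <- env_config(temperature_C = temp, seed = env_seed)
    ds_list <- list()
    for (pair in seq_len(n_pairs)) {
      run_seed <- child_seed(seed, paste0("pair-", pair, "-", tname))
      for (alg in c("CA", "random")) {
        cfg <- explorer_config(algorithm = alg, budget = budget,
                               n_bootstrap = n_bootstrap, seed = run_seed,
                               inv_cfg = inv_cfg, bounds = bounds)
        ds_list[[paste(alg, pair, sep = "-")]] <-
          run_exploration(env_cfg, cfg)
      }
    }
    pooled <- unname(ds_list)
    for (pair in seq_len(n_pairs)) {
      for (alg in c("CA", "random")) {
        ds <- ds_list[[paste(alg, pair, sep = "-")]]
        cov <- coverage(ds, bounds, G, reference = pooled)
        runs[[length(runs) + 1L]] <- data.frame(
          temperature = temp, condition = tname, algorithm = alg,
          pair = pair, coverage = cov$fraction,
          n_occupied = cov$n_occupied, n_active = count_active(ds))
      }
    }
    datasets[[tname]] <- ds_list
  }
  list(runs = do.call(rbind, runs), datasets = datasets)
}

#' Summarize a benchmark into per-condition group means
#'
#' @param bench result of [run_benchmark()]
#' @return data frame with one row per (condition, algorithm): mean/SD of
#'   coverage (as a percentage) and of the active-experiment count
#' @export
summarize_benchmark <- function(bench) {
  runs <- bench$runs
  out <- list()
  for (cond in unique(runs$condition)) {
    for (alg in unique(runs$algorithm)) {
      sub <- runs[runs$condition == cond & runs$algorithm == alg, ]
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, algorithm = alg, n_runs = nrow(sub),
        coverage_pct_mean = 100 * mean(sub$coverage),
        coverage_pct_sd = 100 * stats::sd(sub$coverage),
        active_mean = mean(sub$n_active),
        active_sd = stats::sd(sub$n_active))
    }
  }
  do.call(rbind, out)
}

#' Simulate a time-temperature phase-diagram campaign
#'
#' Long droplet experiments at temperatures evenly distributed over a range,
#' for the focus recipe, ready for [build_phase_diagram()].
#'
#' @param n_experiments number of experiments
#' @param temp_range temperature range, deg C
#' @param duration_s experiment duration, seconds
#' @param dt trajectory sampling interval, seconds
#' @param formulation the recipe used throughout (defaults to the focus
#'   recipe 1.9/47.9/13.5/36.7)
#' @param seed master seed for per-experiment trajectory noise
#' @return list of experiments, each with `temperature_C`, `trajs` and
#'   `truth` (the noise-free envelope boundary times)
#' @export
simulate_phase_campaign <- function(n_experiments = 60L,
                                    temp_range = c(20, 30),
                                    duration_s = 900, dt = 0.05,
                                    formulation =
                                      normalize_formulation(
                                        c(1.9, 47.9, 13.5, 36.7)),
                                    seed = 1L) {
  temps <- seq(temp_range[1L] + 0.05, temp_range[2L] - 0.05,
               length.out = n_experiments)
  lapply(seq_len(n_experiments), function(i) {
    cfg <- env_config(temperature_C = temps[i],
                      seed = child_seed(seed, "campaign", offset = i))
    trajs <- simulate_trajectories(formulation, cfg,
                                   duration_s = duration_s, dt = dt)
    list(temperature_C = temps[i], trajs = trajs,
         truth = trajs$boundaries)
  })
}

#' Temperature-sensor evaluation on synthetic data
#'
#' Generates behavior observations for a fixed active recipe across a
#' temperature range, fits the k-nearest-neighbor temperature regressor on a
#' training split and reports signed prediction errors on a held-out test
#' split.
#'
#' @param n_train,n_test split sizes
#' @param temp_range temperature range, deg C
#' @param seed master seed
#' @param env_seed environment landscape seed (the recipe is placed at a
#'   speed-mode center of this landscape)
#' @return list with `errors` (test-set signed errors, deg C), `mean_error`
#'   and `sd_error`
#' @export
evaluate_temperature_sensor <- function(n_train = 200L, n_test = 100L,
                                        temp_range = c(20, 30), seed = 1L,
                                        env_seed = 7L) {
  base_cfg <- env_config(seed = env_seed)
  modes <- env_modes(base_cfg)
  recipe <- oil_formulation(modes$speed_centers[1L, ] /
                              sum(modes$speed_centers[1L, ]))
  temp_stream <- rng_stream(child_seed(seed, "sensor-temps"))
  n_total <- n_train + n_test
  temps <- stream_draw(temp_stream, stats::runif, n_total,
                       temp_range[1L], temp_range[2L])
  obs <- t(vapply(seq_len(n_total), function(i) {
    cfg <- env_config(temperature_C = temps[i], seed = env_seed)
    unclass(simulate_experiment(recipe, cfg))
  }, numeric(2L)))
  df <- data.frame(mean_speed = obs[, 1L], mean_droplet_count = obs[, 2L],
                   temperature_C = temps)
  train <- df[seq_len(n_train), ]
  test <- df[n_train + seq_len(n_test), ]
  preds <- vapply(seq_len(n_test), function(i) {
    infer_temperature(train,
                      behavior_observation(test$mean_speed[i],
                                           test$mean_droplet_count[i]))
  }, numeric(1L))
  errors <- preds - test$temperature_C
  list(errors = errors, mean_error = mean(errors),
       sd_error = stats::sd(errors), recipe = recipe)
}
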