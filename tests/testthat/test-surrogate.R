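test_that("a single-record dataset predicts its own observation everywhere", {
  ds <- add_record(exploration_dataset(), oil_formulation(c(0.1, 0.2, 0.3, 0.4)),
                   behavior_observation(4.2, 1.7))
  st <- rng_stream(1)
  for (i in 1:5) {
    q <- sample_random_formulation(st)
    expect_equal(unname(unclass(lwr_predict(ds, q))), c(4.2, 1.7))
  }
  expect_error(lwr_predict(exploration_dataset(),
                           oil_formulation(rep(0.25, 4))),
               "model unavailable")
})

test_that("LWR recovers an exact linear map and matches the WLS oracle", {
  ds <- linear_map_dataset(50, seed = 2)
  cfg <- forward_model_config(bandwidth_h = 0.6, ridge_lambda = 1e-9)
  st <- rng_stream(3)
  for (i in 1:20) {
    q <- sample_random_formulation(st)
    pred <- unclass(lwr_predict(ds, q, cfg))
    # linear functions are inside the local model class: exact recovery
    expect_equal(unname(pred), c(10 * q[[4]], 10 * q[[2]]), tolerance = 1e-6)
    # and agreement with the closed-form weighted least-squares oracle
    expect_equal(unname(pred), unname(wls_oracle(ds, q, 0.6, 1e-9)),
                 tolerance = 1e-8)
  }
})

test_that("LWR with huge bandwidth equals global ridge regression", {
  st <- rng_stream(9)
  ds <- exploration_dataset()
  for (i in 1:40) {
    f <- sample_random_formulation(st)
    ds <- add_record(ds, f,
                     behavior_observation(stream_draw(st, runif, 1, 0, 8),
                                          stream_draw(st, runif, 1, 0, 8)))
  }
  cfg <- forward_model_config(bandwidth_h = 1e6, ridge_lambda = 1e-4)
  for (i in 1:10) {
    q <- sample_random_formulation(st)
    expect_equal(unname(unclass(lwr_predict(ds, q, cfg))),
                 unname(wls_oracle(ds, q, 1e6, 1e-4)), tolerance = 1e-8)
  }
})

test_that("LWR is invariant to record order and nearest-neighbor in the h -> 0 limit", {
  ds <- linear_map_dataset(30, seed = 4)
  perm <- ds
  set.seed(1)
  perm$records <- perm$records[sample(nrow(perm$records)), ]
  perm$records$index <- seq_len(nrow(perm$records)) - 1L
  q <- normalize_formulation(c(2, 1, 1, 1))
  expect_equal(unclass(lwr_predict(ds, q)), unclass(lwr_predict(perm, q)),
               tolerance = 1e-12)
  # at a stored formulation, a tiny bandwidth recovers that record exactly
  stored <- oil_formulation(as.numeric(
    ds$records[5, c("r_octanoic", "r_dep", "r_octanol", "r_pentanol")]))
  tiny <- forward_model_config(bandwidth_h = 1e-3)
  expect_equal(unname(unclass(lwr_predict(ds, stored, tiny))),
               as.numeric(ds$records[5, c("mean_speed_mm_s",
                                          "mean_droplet_count")]),
               tolerance = 1e-9)
})

test_that("goal inversion recovers the analytic inverse of a simple map", {
  # speed = 10 r_pentanol, count = 10 r_dep: goal (0.5, 0.3) inverts to
  # r_pentanol = 0.5, r_dep = 0.3
  ds <- linear_map_dataset(80, seed = 6)
  fm <- forward_model_config(bandwidth_h = 0.5, ridge_lambda = 1e-9)
  f <- invert_goal(ds, c(0.5, 0.3), fm_cfg = fm,
                   inv_cfg = inversion_config(seed = 10))
  expect_equal(f[["pentanol"]], 0.5, tolerance = 0.02)
  expect_equal(f[["dep"]], 0.3, tolerance = 0.02)
  expect_error(invert_goal(linear_map_dataset(3), c(0.5, 0.5)),
               "model unavailable")
})

test_that("unreachable goals return the cost minimizer", {
  ds <- linear_map_dataset(80, seed = 8)
  fm <- forward_model_config(bandwidth_h = 0.5, ridge_lambda = 1e-9)
  bounds <- observation_bounds()
  f <- invert_goal(ds, c(1, 1), fm_cfg = fm,
                   inv_cfg = inversion_config(seed = 12))
  achieved <- attr(f, "cost")
  # brute-force audit over a large uniform simplex sample
  st <- rng_stream(77)
  audit <- t(vapply(1:10000, function(i) {
    e <- stream_draw(st, rexp, 4L)
    e / sum(e)
  }, numeric(4L)))
  pred <- curiodrop:::lwr_predict_matrix(
    curiodrop:::dataset_formulations(ds),
    curiodrop:::dataset_observations(ds), audit, fm)
  u <- observation_to_goalspace(pred, bounds)
  costs <- (u[, 1] - 1)^2 + (u[, 2] - 1)^2
  expect_lte(achieved, min(costs) + 1e-9)
})

test_that("CMA-ES inversion beats the simplex-lattice oracle", {
  cfg <- env_config(temperature_C = 27)
  ds <- run_exploration(cfg, explorer_config(algorithm = "random",
                                             budget = 60, seed = 5))
  st <- rng_stream(21)
  for (i in 1:20) {
    goal <- stream_draw(st, runif, 2)
    f <- invert_goal(ds, goal, inv_cfg = inversion_config(seed = 100 + i))
    oracle <- grid_invert_oracle(ds, goal, resolution = 5)
    expect_lte(attr(f, "cost"), attr(oracle, "cost") + 1e-3)
  }
})

test_that("the lattice oracle honors resolution and tie-break rules", {
  # all observations identical: every lattice point ties, so the
  # lexicographically-first point (the pure-pentanol vertex) is returned
  ds <- exploration_dataset()
  for (i in 1:6) {
    ds <- add_record(ds, oil_formulation(rep(0.25, 4)),
                     behavior_observation(2, 2))
  }
  tie <- grid_invert_oracle(ds, c(0.9, 0.9), resolution = 2)
  expect_equal(as.numeric(unclass(tie)), c(0, 0, 0, 1))
  # resolution 2 enumerates only the four vertices; with a map favoring
  # pentanol for speed, a pure-speed goal selects the pentanol vertex
  ds2 <- linear_map_dataset(60, seed = 14)
  fm <- forward_model_config(bandwidth_h = 0.5, ridge_lambda = 1e-9)
  vert <- grid_invert_oracle(ds2, c(1, 0), fm_cfg = fm, resolution = 2)
  expect_equal(as.numeric(unclass(vert)), c(0, 0, 0, 1))
  expect_equal(nrow(simplex_lattice(2)), 4L)
  expect_equal(nrow(simplex_lattice(5)), choose(4 + 3 - 1 + 1, 3))
})

test_that("inversion is seed-reproducible and monotone in its budget", {
  ds <- linear_map_dataset(50, seed = 16)
  goal <- c(0.6, 0.2)
  f1 <- invert_goal(ds, goal, inv_cfg = inversion_config(seed = 33))
  f2 <- invert_goal(ds, goal, inv_cfg = inversion_config(seed = 33))
  expect_identical(unclass(f1), unclass(f2))
  expect_identical(attr(f1, "cost"), attr(f2, "cost"))
  # a longer run with the same seed replays the same prefix of evaluations,
  # so the best-found cost can only improve
  short <- invert_goal(ds, goal,
                       inv_cfg = inversion_config(seed = 34,
                                                  max_evaluations = 160,
                                                  restarts = 0))
  long <- invert_goal(ds, goal,
                      inv_cfg = inversion_config(seed = 34,
                                                 max_evaluations = 480,
                                                 restarts = 0))
  expect_lte(attr(long, "cost"), attr(short, "cost"))
})
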