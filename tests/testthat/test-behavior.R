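test_that("coverage equals the brute-force cell enumeration oracle", {
  bounds <- observation_bounds()
  expect_equal(coverage(exploration_dataset(), bounds)$fraction, 0)

  # all observations identical occupy exactly one cell
  ds1 <- exploration_dataset()
  for (i in 1:5) {
    ds1 <- add_record(ds1, oil_formulation(rep(0.25, 4)),
                      behavior_observation(4.35, 7.12))
  }
  expect_equal(coverage(ds1, bounds, G = 20)$n_occupied, 1L)
  expect_equal(coverage(ds1, bounds, G = 20)$fraction, 1)

  # arbitrary dataset: exact agreement with direct set enumeration
  st <- rng_stream(31)
  ds <- exploration_dataset()
  for (i in 1:200) {
    ds <- add_record(ds, sample_random_formulation(st),
                     behavior_observation(stream_draw(st, runif, 1, 0, 12),
                                          stream_draw(st, runif, 1, 0, 12)))
  }
  G <- 20L
  # independent enumeration: count grid cells containing >= 1 observation
  obs <- ds$records[, c("mean_speed_mm_s", "mean_droplet_count")]
  n_occ <- 0L
  for (i in 0:(G - 1L)) for (j in 0:(G - 1L)) {
    u1 <- pmin(pmax(obs[[1]] / 10, 0), 1)
    u2 <- pmin(pmax(obs[[2]] / 10, 0), 1)
    c1 <- pmin(G - 1L, floor(u1 * G))
    c2 <- pmin(G - 1L, floor(u2 * G))
    if (any(c1 == i & c2 == j)) n_occ <- n_occ + 1L
  }
  cov <- coverage(ds, bounds, G)
  expect_identical(cov$n_occupied, n_occ)
  # prefix curve is non-decreasing and ends at the final fraction
  expect_true(all(diff(cov$curve) >= 0))
  expect_equal(cov$curve[length(cov$curve)], cov$fraction)
  # pooled-reference normalization: a subset covers a fraction of the union
  half <- ds
  half$records <- half$records[1:100, ]
  cov_half <- coverage(half, bounds, G, reference = list(ds))
  expect_lte(cov_half$fraction, 1)
  expect_equal(cov_half$n_reference, cov$n_occupied)
})

test_that("count_active uses a strict speed threshold", {
  ds <- exploration_dataset()
  for (v in c(2.9, 3.0, 3.1)) {
    ds <- add_record(ds, oil_formulation(rep(0.25, 4)),
                     behavior_observation(v, 1))
  }
  expect_equal(count_active(ds), 1L)
  expect_equal(count_active(exploration_dataset()), 0L)
  expect_equal(count_active(ds, speed_threshold = 0), 3L)
})

test_that("welch_t_test matches the textbook formula oracle", {
  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, df = 4, p = 1))
  sep <- welch_t_test(c(1, 2, 3), c(11.01, 12, 12.99))
  expect_lt(sep$p, 0.01)
  # zero variance in both groups with equal means: p = 1 by convention
  expect_equal(welch_t_test(c(2, 2), c(2, 2))$p, 1)

  st <- rng_stream(404)
  for (i in 1:100) {
    a <- stream_draw(st, rnorm, 5, 0, 1)
    b <- stream_draw(st, rnorm, 7, 0.5, 2)
    got <- welch_t_test(a, b)
    want <- welch_oracle(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("fold_change reproduces printed headline ratios", {
  expect_equal(fold_change(73.4, 22.5, digits = 1), 3.3)
  expect_equal(fold_change(395.0, 28.7, digits = 0), 14)
  expect_equal(fold_change(93, 19.3, digits = 0), 5)
  expect_equal(fold_change(10, 4), 2.5)
})

test_that("temperature inference recovers the ambient temperature", {
  train1 <- data.frame(mean_speed = 4, mean_droplet_count = 2,
                       temperature_C = 24.2)
  expect_equal(infer_temperature(train1, behavior_observation(9, 9)), 24.2)

  train <- data.frame(mean_speed = c(1, 4, 7), mean_droplet_count = c(1, 3, 5),
                      temperature_C = c(21, 25, 29))
  # a query exactly at a training observation returns that temperature
  expect_equal(infer_temperature(train, behavior_observation(4, 3)), 25)

  sensor <- evaluate_temperature_sensor(n_train = 200, n_test = 100,
                                        seed = 17)
  expect_lt(abs(sensor$mean_error), 0.3)
  expect_lte(sensor$sd_error, 1.5)
})

test_that("speed and acceleration profiles match analytic derivatives", {
  # constant-speed straight track: acceleration ~ 0
  t <- seq(0, 30, by = 0.1)
  const <- data.frame(droplet_id = 1L, t_s = t, x_mm = 0.5 * t, y_mm = 0)
  prof <- speed_acceleration_profiles(const, window_s = 1, dt = 0.1)
  mid <- !is.na(prof$accel)
  expect_lt(max(abs(prof$accel[mid])), 1e-9)
  expect_equal(mean(prof$speed), 0.5, tolerance = 1e-9)

  # linear speed ramp v = 0.1 t -> a = 0.1 mm/s^2 away from the ends
  ramp <- data.frame(droplet_id = 1L, t_s = t, x_mm = 0.05 * t^2, y_mm = 0)
  prof <- speed_acceleration_profiles(ramp, window_s = 1, dt = 0.1)
  inner <- which(prof$t_s > 2 & prof$t_s < 28)
  expect_equal(max(abs(prof$accel[inner] - 0.1)), 0, tolerance = 1e-6)

  expect_error(speed_acceleration_profiles(
    data.frame(droplet_id = 1L, t_s = c(0, 1), x_mm = c(0, 1),
               y_mm = c(0, 0)), dt = 1), "invalid input")
})

test_that("the two-peak envelope yields exactly two speed maxima", {
  f <- normalize_formulation(c(1.9, 47.9, 13.5, 36.7))
  cfg <- env_config(temperature_C = 26)
  trajs <- simulate_trajectories(f, cfg, duration_s = 900, dt = 0.05)
  prof <- speed_acceleration_profiles(trajs)
  peaks <- curiodrop:::find_speed_peaks(prof$speed)
  expect_equal(length(peaks), 2L)
})

test_that("transition detection finds characteristic points, never fabricates", {
  f <- normalize_formulation(c(1.9, 47.9, 13.5, 36.7))
  cfg <- env_config(temperature_C = 25)
  trajs <- simulate_trajectories(f, cfg, duration_s = 900, dt = 0.05)
  det <- detect_phase_transitions(speed_acceleration_profiles(trajs))
  truth <- ground_truth(f, cfg)$boundaries
  expect_true(all(abs(det - truth) < 2))

  # monotonically decreasing speed: no transitions at all
  t <- seq(0, 100, by = 0.25)
  down <- data.frame(droplet_id = 1L, t_s = t,
                     x_mm = 10 * (1 - exp(-t / 20)), y_mm = 0)
  prof_down <- speed_acceleration_profiles(down, dt = 0.25)
  expect_true(all(is.na(detect_phase_transitions(prof_down))))

  # single-peak envelope: the second-peak transitions are absent
  par1 <- speed_envelope_params(25)
  par1$A2 <- 0
  trajs1 <- simulate_trajectories(f, cfg, duration_s = 400, dt = 0.05,
                                  envelope = par1)
  det1 <- detect_phase_transitions(speed_acceleration_profiles(trajs1))
  expect_true(is.na(det1[["P4_P5"]]))
  expect_true(is.na(det1[["P5_P6"]]))
  expect_false(is.na(det1[["P3_P4"]]))
})

test_that("the phase diagram recovers linear generator boundaries", {
  camp <- simulate_phase_campaign(n_experiments = 24, temp_range = c(21, 29),
                                  duration_s = 900, dt = 0.05, seed = 19)
  pd <- build_phase_diagram(camp)
  expect_s3_class(pd, "phase_diagram")
  expect_equal(nrow(pd$boundaries), 5L)
  for (bn in pd$boundaries$boundary) {
    sub <- pd$transitions[pd$transitions$boundary == bn &
                            !is.na(pd$transitions$time_s), ]
    truth <- vapply(sub$bin_center, function(tc) {
      envelope_boundaries(speed_envelope_params(tc))[[bn]]
    }, numeric(1))
    fit <- stats::lm(truth ~ sub$bin_center)
    est <- pd$boundaries[pd$boundaries$boundary == bn, ]
    expect_equal(est$slope, unname(coef(fit)[2]), tolerance = 0.15)
    # boundary time at the mid-range temperature within 5 s of truth
    expect_lt(abs((est$intercept + 25 * est$slope) -
                    (coef(fit)[1] + 25 * coef(fit)[2])), 5)
  }
  # serialization round-trip sanity
  dir <- withr::local_tempdir()
  p <- file.path(dir, "pd.json")
  save_phase_diagram(pd, p)
  expect_true(file.exists(p))
})

test_that("a temperature-independent fixture yields near-zero slopes", {
  f <- normalize_formulation(c(1.9, 47.9, 13.5, 36.7))
  fixed <- speed_envelope_params(25)
  experiments <- lapply(seq(21.2, 28.8, length.out = 12), function(temp) {
    cfg <- env_config(temperature_C = temp,
                      seed = child_seed(55, "null-case",
                                        offset = round(temp * 100)))
    list(temperature_C = temp,
         trajs = simulate_trajectories(f, cfg, duration_s = 700, dt = 0.05,
                                       envelope = fixed))
  })
  pd <- build_phase_diagram(experiments)
  expect_true(all(abs(pd$boundaries$slope) < 0.5))
})

test_that("classify_phase partitions time into the ordered six phases", {
  camp <- simulate_phase_campaign(n_experiments = 24, temp_range = c(21, 29),
                                  duration_s = 900, dt = 0.05, seed = 19)
  pd <- build_phase_diagram(camp)
  expect_equal(classify_phase(0, 25, pd), "initiation")
  expect_equal(classify_phase(890, 25, pd), "saturation")
  expect_error(classify_phase(10, 35, pd), "outside the diagram range")
  # along time at fixed temperature the labels are an ordered walk P1 -> P6
  labels <- vapply(seq(0, 899, by = 1), classify_phase, character(1),
                   temperature_C = 24.6, pd = pd)
  idx <- match(labels, PHASE_LABELS)
  expect_true(all(diff(idx) >= 0))
  expect_equal(sort(unique(idx)), 1:6)
  # at each boundary, labels flip consistently between adjacent phases
  times <- pd$boundaries$intercept + pd$boundaries$slope * 24.6
  for (k in seq_along(times)) {
    expect_equal(match(classify_phase(times[k] - 1e-6, 24.6, pd),
                       PHASE_LABELS) + 1L,
                 match(classify_phase(times[k] + 1e-6, 24.6, pd),
                       PHASE_LABELS))
  }
})
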