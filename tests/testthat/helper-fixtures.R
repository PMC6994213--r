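# shared fixture builders -----------------------------------------------

# dataset sampled from an exact linear behavior map obs = A %*% ratios,
# with formulations drawn uniformly on the simplex
linear_map_dataset <- function(n, seed = 1L,
                               A = rbind(speed = c(0, 0, 0, 10),
                                         count = c(0, 10, 0, 0))) {
  st <- rng_stream(seed)
  ds <- exploration_dataset()
  for (i in seq_len(n)) {
    f <- sample_random_formulation(st)
    obs <- as.numeric(A %*% unclass(f))
    ds <- add_record(ds, f, behavior_observation(obs[1L], obs[2L]))
  }
  ds
}

# reachable linear environment spanning the whole unit goal square:
# speed = 10 (r1 + r2), count = 10 (r1 + r3)
reachable_linear_env <- function(f, env_cfg) {
  r <- unclass(f)
  behavior_observation(10 * (r[1L] + r[2L]), 10 * (r[1L] + r[3L]))
}

# trajectory table for a single droplet moving on a circle (constant speed
# radius_mm * omega), sampled at the video frame rate
circle_trajectories <- function(radius_mm = 5, omega = 0.4, duration_s = 20,
                                fps = 20) {
  t <- seq(0, duration_s, by = 1 / fps)
  list(tracks = data.frame(droplet_id = 1L, t_s = t,
                           x_mm = radius_mm * cos(omega * t),
                           y_mm = radius_mm * sin(omega * t)),
       duration_s = duration_s)
}

# stationary droplets at given positions (n x 2, mm)
stationary_trajectories <- function(positions, duration_s = 5) {
  n <- nrow(positions)
  list(tracks = data.frame(
    droplet_id = rep(seq_len(n), each = 2L),
    t_s = rep(c(0, duration_s), n),
    x_mm = rep(positions[, 1L], each = 2L),
    y_mm = rep(positions[, 2L], each = 2L)),
    duration_s = duration_s)
}

# closed-form weighted ridge regression oracle: Gaussian weights around the
# query, design centered at the query, penalty on the slopes only --
# independent of the package's lwr implementation
wls_oracle <- function(ds, query, h, lambda) {
  x <- as.matrix(ds$records[, c("r_octanoic", "r_dep", "r_octanol",
                                "r_pentanol")])
  y <- as.matrix(ds$records[, c("mean_speed_mm_s", "mean_droplet_count")])
  q <- as.numeric(query)
  w <- exp(-colSums((t(x) - q)^2) / (2 * h^2))
  z <- cbind(1, sweep(x, 2L, q, "-"))
  A <- t(z * w) %*% z + diag(c(0, rep(1, 4L))) * lambda
  beta <- solve(A, t(z * w) %*% y)
  pmax(beta[1L, ], 0)
}

# textbook Welch statistic, written independently of the package
welch_oracle <- function(a, b) {
  res <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
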