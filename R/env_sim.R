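#' Synthetic droplet environment
#'
#' The environment maps (formulation, temperature, seed) to a behavior
#' observation — and optionally to full droplet trajectories — with the
#' qualitative phenomenology of the physical system: rare localized
#' high-activity regions in formulation space, a sharp logistic temperature
#' regime shift, and two-peak speed/time trajectories whose peaks occur
#' earlier and larger at higher temperature.
#'
#' @name droplet_env
NULL

# hash a formulation (and optionally the temperature) to an integer offset
# so that observation noise is a pure function of (formulation, config)
formulation_hash <- function(f, temperature_C = 0) {
  v <- floor(as.numeric(f) * 1e7)
  as.integer((sum(v * c(1, 3, 7, 11)) + floor(temperature_C * 1e4) * 13) %%
               2147480009)
}

# draw n points uniformly on the 3-simplex (flat Dirichlet)
runif_simplex <- function(n, stream) {
  e <- matrix(stream_draw(stream, stats::rexp, n * 4L), nrow = n)
  e / rowSums(e)
}

#' Mode landscape of a synthetic environment
#'
#' The high-activity regions are derived deterministically from the
#' environment seed: mode centers uniform on the simplex, speed amplitudes
#' uniform in 6-10 mm/s; the droplet-count response uses a distinct set of
#' mode centers.
#'
#' @param cfg an [env_config()]
#' @return list with `speed_centers`, `speed_amplitudes`, `count_centers`
#' @export
env_modes <- function(cfg) {
  k <- cfg$n_active_modes
  s1 <- rng_stream(child_seed(cfg$seed, "speed-modes"))
  s2 <- rng_stream(child_seed(cfg$seed, "count-modes"))
  list(speed_centers = runif_simplex(k, s1),
       speed_amplitudes = stream_draw(s1, stats::runif, k, 6, 10),
       count_centers = runif_simplex(k, s2))
}

# squared-exponential kernel on the simplex (Euclidean distance in the
# embedding), with a hard floor so responses far from every mode are exactly 0
mode_kernel <- function(x, centers, width, floor_at = 1e-8) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
    2 * tcrossprod(x, centers)
  k <- exp(-pmax(d2, 0) / (2 * width^2))
  k[k < floor_at] <- 0
  k
}

temperature_gate <- function(temperature_C, cfg) {
  1 / (1 + exp(-cfg$regime_shift_steepness *
                 (temperature_C - cfg$regime_shift_midpoint_C)))
}

# noise-free behavior response for an n x 4 matrix of formulations
env_response <- function(x, cfg, modes = env_modes(cfg)) {
  gate <- temperature_gate(cfg$temperature_C, cfg)
  ks <- mode_kernel(x, modes$speed_centers, cfg$mode_width)
  speed <- as.numeric(ks %*% modes$speed_amplitudes) * gate
  kc <- mode_kernel(x, modes$count_centers, cfg$mode_width)
  kc_sum <- pmin(1, rowSums(kc))
  count <- cfg$n_droplets_initial * (0.25 + 1.75 * kc_sum * gate)
  cbind(speed = speed, count = count)
}

#' Run one synthetic droplet experiment
#'
#' Deterministic given (formulation, config incl. seed): the noise stream is
#' seeded from the environment seed and a hash of the formulation, so the
#' same call always returns the identical observation.
#'
#' @param f an [oil_formulation()]
#' @param cfg an [env_config()]
#' @return a [behavior_observation()]
#' @export
simulate_experiment <- function(f, cfg) {
  f <- oil_formulation(f)
  validate_env_config(cfg)
  resp <- env_response(matrix(unclass(f), nrow = 1L), cfg)
  ns <- rng_stream(child_seed(cfg$seed, "obs-noise",
                              offset = formulation_hash(f, cfg$temperature_C)))
  eps <- stream_draw(ns, stats::rnorm, 2L)
  behavior_observation(
    mean_speed = max(0, resp[1L, "speed"] + eps[1L] * cfg$noise_speed_sd),
    mean_droplet_count = max(0, resp[1L, "count"] + eps[2L] * cfg$noise_count_sd))
}

#' Noise-free ground truth for a synthetic experiment
#'
#' Pure function of (formulation, config) with all noise terms removed;
#' serves as the oracle surface for tests. Also reports the speed-envelope
#' parameters and the six-phase segment boundary times at the configured
#' temperature.
#'
#' @inheritParams simulate_experiment
#' @param duration_s horizon over which segment boundaries are computed
#' @return list with `observation` (noise-free [behavior_observation()]),
#'   `envelope` (see [speed_envelope_params()]) and `boundaries`
#'   (named 5-vector of transition times, seconds)
#' @export
ground_truth <- function(f, cfg, duration_s = 900) {
  f <- oil_formulation(f)
  validate_env_config(cfg)
  resp <- env_response(matrix(unclass(f), nrow = 1L), cfg)
  par <- speed_envelope_params(cfg$temperature_C)
  list(observation = behavior_observation(resp[1L, "speed"], resp[1L, "count"]),
       envelope = par,
       boundaries = envelope_boundaries(par, duration_s))
}

#' Temperature-dependent two-peak speed envelope parameters
#'
#' Each droplet's speed magnitude over a long experiment follows a sum of two
#' log-normal-shaped bumps. Peak times decrease linearly with temperature and
#' peak amplitudes increase linearly with temperature, so that at hotter
#' temperatures the peaks occur earlier and with greater magnitude.
#'
#' @param temperature_C temperature in degrees Celsius
#' @return list with peak times `t1`, `t2` (s), amplitudes `A1`, `A2` (mm/s),
#'   log-widths `s1`, `s2`, and the linear peak-time slopes `t1_slope`,
#'   `t2_slope` (s/degC)
#' @export
speed_envelope_params <- function(temperature_C) {
  list(t1 = 140 - 8 * (temperature_C - 25),
       t2 = 480 - 25 * (temperature_C - 25),
       A1 = max(0, 1.5 + 0.12 * (temperature_C - 20)),
       A2 = max(0, 2.0 + 0.20 * (temperature_C - 20)),
       s1 = 0.25, s2 = 0.30,
       t1_slope = -8, t2_slope = -25)
}

#' Evaluate the speed envelope
#' @param t time in seconds (vector ok)
#' @param par envelope parameters from [speed_envelope_params()]
#' @return speed in mm/s
#' @export
envelope_value <- function(t, par) {
  v <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  v[pos] <- par$A1 * exp(-(log(tp / par$t1))^2 / (2 * par$s1^2)) +
    par$A2 * exp(-(log(tp / par$t2))^2 / (2 * par$s2^2))
  v
}

envelope_deriv <- function(t, par, h = 1e-3) {
  (envelope_value(t + h, par) - envelope_value(pmax(t - h, 0), par)) /
    (t + h - pmax(t - h, 0))
}

#' Segment boundary times of the speed envelope
#'
#' The six motion phases (initiation, fluctuation, irregular, deceleration,
#' continuous, saturation) are delimited by five characteristic points of the
#' envelope, located numerically on the analytic curve: the 10%-of-maximum
#' acceleration rise, the first acceleration maximum, the first speed peak,
#' the inter-peak speed trough (acceleration re-crossing to positive), and
#' the second speed peak. Transitions that do not exist (e.g. a zero second
#' peak) are `NA`.
#'
#' @param par envelope parameters from [speed_envelope_params()]
#' @param duration_s horizon in seconds
#' @return named numeric 5-vector `P1_P2 ... P5_P6`, seconds
#' @export
envelope_boundaries <- function(par, duration_s = 900) {
  out <- c(P1_P2 = NA_real_, P2_P3 = NA_real_, P3_P4 = NA_real_,
           P4_P5 = NA_real_, P5_P6 = NA_real_)
  both_zero <- par$A1 <= 0 && par$A2 <= 0
  if (both_zero) return(out)
  # first bump: the earlier of the present peaks
  first_t <- if (par$A1 > 0) par$t1 else par$t2
  p1 <- stats::optimize(function(t) -envelope_value(t, par),
                        c(first_t * 0.7, first_t * 1.3))$minimum
  out["P3_P4"] <- p1
  amax <- stats::optimize(function(t) -envelope_deriv(t, par),
                          c(1e-3, p1))$minimum
  out["P2_P3"] <- amax
  a_at_max <- envelope_deriv(amax, par)
  if (a_at_max > 0) {
    rise <- function(t) envelope_deriv(t, par) - 0.1 * a_at_max
    lo <- first_t * 1e-3
    if (rise(lo) < 0 && rise(amax) > 0) {
      out["P1_P2"] <- stats::uniroot(rise, c(lo, amax))$root
    }
  }
  if (par$A1 > 0 && par$A2 > 0 && par$t2 > par$t1 && par$t2 < duration_s) {
    lo <- p1 * 1.05
    hi <- par$t2 * 0.95
    if (envelope_deriv(lo, par) < 0 && envelope_deriv(hi, par) > 0) {
      out["P4_P5"] <- stats::uniroot(function(t) envelope_deriv(t, par),
                                     c(lo, hi))$root
      out["P5_P6"] <- stats::optimize(function(t) -envelope_value(t, par),
                                      c(par$t2 * 0.7,
                                        min(par$t2 * 1.3, duration_s)))$minimum
    }
  }
  out
}

# phase index (1..6) for times t given the 5-vector of boundary times; a
# missing (NA) boundary leaves its phase unreachable
phase_of_time <- function(t, boundaries) {
  present <- which(!is.na(boundaries))
  ph_full <- rep(1L, length(t))
  for (k in present) {
    ph_full[t >= boundaries[k]] <- k + 1L
  }
  ph_full
}

# per-step heading noise SD (rad, at a 0.05-s reference step) for each of the
# six motion phases: high-variance direction changes during irregular motion,
# persistent heading during continuous motion
PHASE_ANGULAR_NOISE <- c(0.15, 0.35, 1.2, 0.30, 0.05, 0.15)

# advance a point a path length L along heading u inside a circle of radius R,
# reflecting specularly at the boundary; returns list(p, u)
reflect_step <- function(p, u, L, R) {
  for (guard in 1:64) {
    if (L <= 0) break
    pu <- sum(p * u)
    disc <- pu^2 - (sum(p^2) - R^2)
    s <- -pu + sqrt(max(disc, 0))
    if (s >= L) {
      p <- p + L * u
      break
    }
    p <- p + s * u
    n <- p / sqrt(sum(p^2))
    u <- u - 2 * sum(u * n) * n
    L <- L - s
    # nudge inside to avoid re-hitting the same boundary point
    p <- p * (1 - 1e-12)
  }
  list(p = p, u = u)
}

# initial droplet positions: 4 x 4 ul droplets in a Y pattern from the dish
# center (one central droplet, arms at 90/210/330 degrees); extra droplets
# continue around the circle
initial_positions <- function(n, arm_mm = 5) {
  if (n == 1L) return(matrix(0, 1L, 2L))
  angles <- (90 + 120 * (0:(n - 2L))) * pi / 180
  rbind(c(0, 0), cbind(arm_mm * cos(angles), arm_mm * sin(angles)))
}

#' Simulate full droplet trajectories
#'
#' Droplet speed follows the temperature-dependent two-peak envelope; heading
#' dynamics are phase-dependent (high-variance direction changes during the
#' irregular phase, persistent heading with small angular noise during the
#' continuous phase), and positions reflect specularly at the arena boundary.
#'
#' @param f an [oil_formulation()]
#' @param cfg an [env_config()]
#' @param duration_s experiment duration, seconds
#' @param dt sampling interval, seconds (must be < `duration_s`)
#' @param envelope envelope parameter override (default: derived from the
#'   configured temperature via [speed_envelope_params()])
#' @param angular_noise per-phase heading noise SD (rad per 0.05-s step):
#'   a 6-vector, a scalar applied to all phases, or `NULL` for the defaults
#' @return a `trajectory_set`: list with `dt`, `duration_s`, `n_droplets` and
#'   `tracks`, a data frame (droplet_id, t_s, x_mm, y_mm)
#' @export
simulate_trajectories <- function(f, cfg, duration_s = 900, dt = 0.25,
                                  envelope = NULL, angular_noise = NULL) {
  f <- oil_formulation(f)
  validate_env_config(cfg)
  if (!(duration_s > 0) || !(dt > 0) || dt >= duration_s) {
    stop("invalid sampling: need 0 < dt < duration_s", call. = FALSE)
  }
  par <- if (is.null(envelope)) speed_envelope_params(cfg$temperature_C) else
    envelope
  noise <- if (is.null(angular_noise)) PHASE_ANGULAR_NOISE else
    rep_len(as.numeric(angular_noise), 6L)
  bounds <- envelope_boundaries(par, duration_s)
  n <- cfg$n_droplets_initial
  R <- cfg$arena_radius_mm
  times <- seq(0, duration_s, by = dt)
  n_steps <- length(times) - 1L
  pos <- initial_positions(n, arm_mm = min(5, R * 0.4))
  theta <- atan2(pos[, 2L], pos[, 1L])
  at_origin <- pos[, 1L] == 0 & pos[, 2L] == 0
  theta[!is.finite(theta) | at_origin] <-
    seq(0, 2 * pi, length.out = n + 1L)[which(!is.finite(theta) | at_origin)]
  ns <- rng_stream(child_seed(cfg$seed, "traj",
                              offset = formulation_hash(f, cfg$temperature_C)))
  dtheta <- matrix(stream_draw(ns, stats::rnorm, n_steps * n), nrow = n_steps)
  xs <- matrix(NA_real_, n_steps + 1L, n)
  ys <- matrix(NA_real_, n_steps + 1L, n)
  xs[1L, ] <- pos[, 1L]
  ys[1L, ] <- pos[, 2L]
  phases <- phase_of_time(times[-length(times)] + dt / 2, bounds)
  noise_scale <- sqrt(dt / 0.05)
  for (k in seq_len(n_steps)) {
    v <- envelope_value(times[k] + dt / 2, par)
    sd_k <- noise[phases[k]] * noise_scale
    theta <- theta + dtheta[k, ] * sd_k
    if (v > 0) {
      L <- v * dt
      ux <- cos(theta); uy <- sin(theta)
      nx <- xs[k, ] + L * ux
      ny <- ys[k, ] + L * uy
      out <- nx^2 + ny^2 > R^2
      if (any(out)) {
        for (j in which(out)) {
          st <- reflect_step(c(xs[k, j], ys[k, j]), c(ux[j], uy[j]), L, R)
          nx[j] <- st$p[1L]; ny[j] <- st$p[2L]
          theta[j] <- atan2(st$u[2L], st$u[1L])
        }
      }
      xs[k + 1L, ] <- nx
      ys[k + 1L, ] <- ny
    } else {
      xs[k + 1L, ] <- xs[k, ]
      ys[k + 1L, ] <- ys[k, ]
    }
  }
  tracks <- data.frame(
    droplet_id = rep(seq_len(n), each = n_steps + 1L),
    t_s = rep(times, times = n),
    x_mm = as.numeric(xs), y_mm = as.numeric(ys))
  structure(list(dt = dt, duration_s = duration_s, n_droplets = n,
                 tracks = tracks, envelope = par, boundaries = bounds),
            class = "trajectory_set")
}

#' Write a trajectory set as tidy CSV
#' @param trajs a `trajectory_set` from [simulate_trajectories()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
save_trajectories <- function(trajs, path) {
  utils::write.csv(trajs$tracks, path, row.names = FALSE)
  invisible(path)
}
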