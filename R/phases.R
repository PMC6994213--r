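#' The six motion phases, in order
#'
#' Initiation (P1), fluctuation (P2), irregular (P3), deceleration (P4),
#' continuous (P5) and saturation (P6).
#' @export
PHASE_LABELS <- c("initiation", "fluctuation", "irregular", "deceleration",
                  "continuous", "saturation")

BOUNDARY_NAMES <- c("P1_P2", "P2_P3", "P3_P4", "P4_P5", "P5_P6")

# mean-across-droplet raw speed series from a trajectory table
raw_speed_profile <- function(tracks, dt) {
  ids <- unique(tracks$droplet_id)
  speeds <- NULL
  for (id in ids) {
    sub <- tracks[tracks$droplet_id == id, ]
    sub <- sub[order(sub$t_s), ]
    s <- sqrt(diff(sub$x_mm)^2 + diff(sub$y_mm)^2) / dt
    speeds <- if (is.null(speeds)) s else speeds + s
  }
  list(t_s = sort(unique(tracks$t_s))[-1L], speed = speeds / length(ids))
}

#' Mean speed and acceleration profiles of a droplet experiment
#'
#' Instantaneous per-droplet speeds (displacement over the uniform sampling
#' interval) are averaged across droplets, smoothed with a centered sliding
#' window of `window_s` seconds (truncated at the ends), and differentiated
#' by centered first differences to give the acceleration profile.
#'
#' @param trajs a `trajectory_set` from [simulate_trajectories()], or a tidy
#'   data frame (droplet_id, t_s, x_mm, y_mm) with uniform sampling
#' @param window_s sliding window, seconds
#' @param dt sampling interval, required only for plain data frames
#' @return data frame with columns `t_s`, `speed` (mm/s, smoothed) and
#'   `accel` (mm/s^2)
#' @export
speed_acceleration_profiles <- function(trajs, window_s = 2, dt = NULL) {
  if (inherits(trajs, "trajectory_set")) {
    tracks <- trajs$tracks
    dt <- trajs$dt
  } else {
    tracks <- trajs
    if (is.null(dt)) {
      tt <- sort(unique(tracks$t_s))
      if (length(tt) < 2L) stop("invalid input: need >= 3 time points",
                                call. = FALSE)
      dt <- tt[2L] - tt[1L]
    }
  }
  prof <- raw_speed_profile(tracks, dt)
  if (length(prof$speed) < 3L) {
    stop("invalid input: need >= 3 time points", call. = FALSE)
  }
  win <- max(1L, round(window_s / dt))
  smooth <- moving_average(prof$speed, win)
  n <- length(smooth)
  accel <- rep(NA_real_, n)
  accel[2:(n - 1L)] <- (smooth[3:n] - smooth[1:(n - 2L)]) / (2 * dt)
  data.frame(t_s = prof$t_s, speed = smooth, accel = accel)
}

# local maxima of a smoothed speed series, with a prominence rule: adjacent
# peaks whose intervening valley does not drop at least 10% below the lower
# peak are merged (higher wins); peaks below 5% of the series maximum are
# discarded
find_speed_peaks <- function(v, min_height_frac = 0.05,
                             min_drop_frac = 0.1) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  cand <- which(v[2:(n - 1L)] > v[1:(n - 2L)] &
                  v[2:(n - 1L)] >= v[3:n]) + 1L
  cand <- cand[v[cand] >= min_height_frac * max(v)]
  if (length(cand) <= 1L) return(cand)
  repeat {
    merged <- FALSE
    for (k in seq_len(length(cand) - 1L)) {
      i <- cand[k]; j <- cand[k + 1L]
      valley <- min(v[i:j])
      low <- min(v[i], v[j])
      if (valley > (1 - min_drop_frac) * low) {
        drop_idx <- if (v[i] >= v[j]) k + 1L else k
        cand <- cand[-drop_idx]
        merged <- TRUE
        break
      }
    }
    if (!merged || length(cand) <= 1L) break
  }
  cand
}

# refine the time of a local extremum by a least-squares quadratic fit in a
# window around the discrete arg-extremum; robust to sample-level jitter on
# broad peaks. Falls back to the discrete time for degenerate fits.
refine_extremum <- function(t, y, idx, half_window_s = NULL) {
  # broad late extrema need proportionally wider fit windows to average
  # sample-level noise, but too wide a window biases the vertex on skewed
  # bumps; 5% of the extremum time balances the two
  if (is.null(half_window_s)) half_window_s <- max(8, 0.05 * t[idx])
  sel <- which(t >= t[idx] - half_window_s & t <= t[idx] + half_window_s &
                 !is.na(y))
  if (length(sel) < 5L) return(t[idx])
  tc <- t[sel] - t[idx]
  fit <- stats::lm.fit(cbind(1, tc, tc^2), y[sel])
  a2 <- fit$coefficients[3L]
  a1 <- fit$coefficients[2L]
  if (!is.finite(a2) || a2 == 0) return(t[idx])
  vertex <- -a1 / (2 * a2)
  if (abs(vertex) > half_window_s) return(t[idx])
  t[idx] + vertex
}

#' Detect the five phase-transition times in a speed/acceleration profile
#'
#' The transitions are defined by characteristic points of the profiles:
#' P1->P2 at the first time the acceleration exceeds 10% of its first
#' maximum; P2->P3 at the first acceleration maximum; P3->P4 at the first
#' speed maximum (acceleration zero-crossing + to -); P4->P5 at the
#' acceleration re-crossing to positive after its post-peak minimum (the
#' inter-peak speed trough); P5->P6 at the second speed maximum. Transitions
#' that are not present in the profile are returned as `NA`, never
#' fabricated — a monotone profile yields no transitions and a single-peak
#' profile lacks `P4_P5`/`P5_P6`.
#'
#' @param profile data frame from [speed_acceleration_profiles()]
#' @param rise_fraction fraction of the first acceleration maximum defining
#'   the P1->P2 rise point
#' @return named numeric 5-vector (`P1_P2` ... `P5_P6`) of times in seconds,
#'   with `NA` for absent transitions
#' @export
detect_phase_transitions <- function(profile, rise_fraction = 0.1) {
  out <- setNames(rep(NA_real_, 5L), BOUNDARY_NAMES)
  v <- profile$speed
  a <- profile$accel
  t <- profile$t_s
  peaks <- find_speed_peaks(v)
  if (length(peaks) == 0L) return(out)
  i1 <- peaks[1L]
  pre <- which(!is.na(a[seq_len(i1)]))
  if (length(pre)) {
    amax_idx <- pre[which.max(a[pre])]
    if (a[amax_idx] > 0) {
      out["P2_P3"] <- t[amax_idx]
      thr <- rise_fraction * a[amax_idx]
      rise <- which(a[seq_len(amax_idx)] >= thr)
      if (length(rise)) out["P1_P2"] <- t[min(rise)]
    }
  }
  out["P3_P4"] <- refine_extremum(t, v, i1)
  if (length(peaks) >= 2L) {
    i2 <- peaks[2L]
    # the acceleration re-crossing to positive after its post-peak minimum
    # is the inter-peak speed trough; locating the trough directly is robust
    # to small-amplitude acceleration wiggles on noisy profiles
    seg <- (i1 + 1L):(i2 - 1L)
    if (length(seg)) {
      out["P4_P5"] <- refine_extremum(t, v, seg[which.min(v[seg])])
    }
    out["P5_P6"] <- refine_extremum(t, v, i2)
  }
  out
}

#' Build a time-temperature phase diagram from a campaign of experiments
#'
#' Experiments are binned in `bin_width`-degree temperature intervals; the
#' raw mean-speed profiles of all experiments in a bin are averaged before
#' smoothing and transition detection (one detection per bin). Each
#' transition time is then fitted linearly against bin-center temperature by
#' least squares. A transition detected in fewer than two bins is absent
#' from the diagram. The resulting boundary lines must be strictly ordered
#' P1->P6 at every temperature in the diagram's range.
#'
#' @param experiments list of experiments, each a list with `temperature_C`
#'   and `trajs` (a `trajectory_set`)
#' @param bin_width temperature bin width, degrees Celsius
#' @param window_s profile smoothing window, seconds
#' @return an object of class `phase_diagram`: list with `boundaries`
#'   (data frame boundary, slope s/degC, intercept s, n_bins, rss),
#'   `transitions` (per-bin detections), `temp_range` and `bin_width`
#' @export
build_phase_diagram <- function(experiments, bin_width = 1, window_s = 2) {
  stopifnot(length(experiments) >= 2L)
  temps <- vapply(experiments, function(e) e$temperature_C, numeric(1L))
  bin_idx <- floor(temps / bin_width)
  bins <- sort(unique(bin_idx))
  detections <- list()
  for (b in bins) {
    members <- which(bin_idx == b)
    profs <- lapply(experiments[members], function(e) {
      raw_speed_profile(e$trajs$tracks, e$trajs$dt)
    })
    len <- min(vapply(profs, function(p) length(p$speed), integer(1L)))
    avg <- Reduce(`+`, lapply(profs, function(p) p$speed[seq_len(len)])) /
      length(profs)
    dt <- experiments[[members[1L]]]$trajs$dt
    win <- max(1L, round(window_s / dt))
    smooth <- moving_average(avg, win)
    n <- length(smooth)
    accel <- rep(NA_real_, n)
    accel[2:(n - 1L)] <- (smooth[3:n] - smooth[1:(n - 2L)]) / (2 * dt)
    prof <- data.frame(t_s = profs[[1L]]$t_s[seq_len(len)], speed = smooth,
                       accel = accel)
    tt <- detect_phase_transitions(prof)
    detections[[length(detections) + 1L]] <- data.frame(
      bin_center = (b + 0.5) * bin_width,
      boundary = BOUNDARY_NAMES, time_s = as.numeric(tt),
      n_experiments = length(members))
  }
  trans <- do.call(rbind, detections)
  if (sum(!is.na(trans$time_s)) == 0L) {
    stop("no transitions detected in any temperature bin", call. = FALSE)
  }
  fits <- list()
  for (bn in BOUNDARY_NAMES) {
    sub <- trans[trans$boundary == bn & !is.na(trans$time_s), ]
    if (nrow(sub) < 2L) next
    fit <- stats::lm(time_s ~ bin_center, data = sub)
    fits[[bn]] <- data.frame(
      boundary = bn, slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]), n_bins = nrow(sub),
      rss = sum(stats::residuals(fit)^2))
  }
  if (length(fits) < 1L) {
    stop("need transitions detected in >= 2 bins to fit boundaries",
         call. = FALSE)
  }
  boundaries <- do.call(rbind, c(fits, list(make.row.names = FALSE)))
  temp_range <- range(trans$bin_center[!is.na(trans$time_s)])
  pd <- structure(list(boundaries = boundaries, transitions = trans,
                       temp_range = temp_range, bin_width = bin_width),
                  class = "phase_diagram")
  validate_phase_diagram(pd)
  pd
}

boundary_times_at <- function(pd, temperature_C) {
  b <- pd$boundaries
  setNames(b$intercept + b$slope * temperature_C, b$boundary)
}

validate_phase_diagram <- function(pd) {
  for (temp in seq(pd$temp_range[1L], pd$temp_range[2L], length.out = 21L)) {
    times <- boundary_times_at(pd, temp)
    if (any(diff(times) <= 0)) {
      stop("invalid phase diagram: boundary times not strictly increasing ",
           "at ", round(temp, 2), " degC", call. = FALSE)
    }
  }
  invisible(pd)
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("<phase_diagram> ", nrow(x$boundaries), " fitted boundaries, ",
      sprintf("%.1f-%.1f", x$temp_range[1L], x$temp_range[2L]),
      " degC\n", sep = "")
  print(x$boundaries)
  invisible(x)
}

#' Serialize a phase diagram to JSON
#' @param pd a `phase_diagram`
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
save_phase_diagram <- function(pd, path) {
  jsonlite::write_json(
    list(boundaries = pd$boundaries, transitions = pd$transitions,
         temp_range = pd$temp_range, bin_width = pd$bin_width),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Classify the motion phase at a time and temperature
#'
#' @param t_s time since the start of the experiment, seconds
#' @param temperature_C temperature inside the diagram's valid range
#' @param pd a `phase_diagram` from [build_phase_diagram()]
#' @return a phase label (one of [PHASE_LABELS]); times at or beyond a
#'   boundary belong to the later phase
#' @export
classify_phase <- function(t_s, temperature_C, pd) {
  stopifnot(inherits(pd, "phase_diagram"))
  if (temperature_C < pd$temp_range[1L] - 1e-9 ||
        temperature_C > pd$temp_range[2L] + 1e-9) {
    stop("temperature ", temperature_C, " degC outside the diagram range [",
         pd$temp_range[1L], ", ", pd$temp_range[2L], "]", call. = FALSE)
  }
  times <- boundary_times_at(pd, temperature_C)
  full <- setNames(rep(NA_real_, 5L), BOUNDARY_NAMES)
  full[names(times)] <- times
  ph <- phase_of_time(t_s, full)
  PHASE_LABELS[ph]
}
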