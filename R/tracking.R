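#' Otsu threshold of a grayscale frame
#'
#' Thin wrapper over EBImage's Otsu implementation; the frame is clipped to
#' `[0, 1]` first. By convention the threshold is estimated once on the
#' first frame of a video and then held fixed, which makes the downstream
#' speed metrics invariant to a global intensity offset.
#'
#' @param frame numeric matrix in (approximately) `[0, 1]`
#' @return the scalar threshold
#' @export
otsu_threshold <- function(frame) {
  f <- frame
  f[f < 0] <- 0; f[f > 1] <- 1
  EBImage::otsu(EBImage::Image(f))
}

#' Detect droplets in one grayscale frame
#'
#' Connected dark regions below the intensity threshold, inside the arena
#' circle, with area at least `min_area_px2`. The reported centroid is the
#' darkness-weighted area centroid in continuous 0-based pixel coordinates.
#'
#' @param frame numeric matrix (grayscale, light background, dark droplets)
#' @param meta a [video_meta()]
#' @param threshold intensity threshold; `NULL` computes Otsu on this frame
#' @param min_area_px2 minimum blob area in pixels
#' @return data frame with columns `x_px`, `y_px`, `area_px2`; the blob
#'   contours (pixel polygons from EBImage) are attached as attribute
#'   `contours`
#' @export
detect_droplets <- function(frame, meta, threshold = NULL,
                            min_area_px2 = 20) {
  stopifnot(inherits(meta, "video_meta"))
  if (is.null(threshold)) threshold <- otsu_threshold(frame)
  mask <- frame < threshold
  labels <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- EBImage::imageData(labels)
  n_blobs <- max(lab)
  out <- data.frame(x_px = numeric(0), y_px = numeric(0),
                    area_px2 = numeric(0))
  keep <- integer(0)
  if (n_blobs > 0) {
    idx <- which(lab > 0, arr.ind = TRUE)
    blob <- lab[lab > 0]
    # matrix row = y + 1, col = x + 1 in 0-based image coordinates;
    # EBImage stores images transposed relative to plain matrices, but we
    # pass/read plain matrices consistently so row/col semantics are ours
    yy <- idx[, 1L] - 1
    xx <- idx[, 2L] - 1
    w <- pmax(threshold - frame[idx], 1e-6)
    for (b in seq_len(n_blobs)) {
      sel <- blob == b
      area <- sum(sel)
      if (area < min_area_px2) next
      wb <- w[sel]
      cx <- sum(xx[sel] * wb) / sum(wb)
      cy <- sum(yy[sel] * wb) / sum(wb)
      d <- sqrt((cx - meta$arena_center_px[1L])^2 +
                  (cy - meta$arena_center_px[2L])^2)
      if (d > meta$arena_radius_px) next
      out <- rbind(out, data.frame(x_px = cx, y_px = cy, area_px2 = area))
      keep <- c(keep, b)
    }
  }
  contours <- tryCatch(EBImage::ocontour(labels)[keep],
                       error = function(e) NULL)
  attr(out, "contours") <- contours
  out
}

#' Create an empty tracker state
#' @param meta a [video_meta()]
#' @return an object of class `droplet_tracks`
#' @export
new_tracker <- function(meta) {
  structure(list(meta = meta, tracks = list(), next_id = 1L, frame = -1L),
            class = "droplet_tracks")
}

#' Link one frame of detections to existing tracks (proximity rule)
#'
#' Greedy nearest-neighbor assignment in ascending distance between the last
#' positions of active tracks and the new detections; equidistant matches go
#' to the lowest existing track id. Unmatched detections open new tracks
#' (how splits appear); active tracks with no detection within
#' `max_link_distance_px` are closed with a status chosen by geometry:
#' `exited` near the arena rim, `fused` if the track's last position lies
#' within linking distance of a detection matched to another track, `ended`
#' otherwise.
#'
#' @param tracker a `droplet_tracks` state from [new_tracker()]
#' @param detections data frame from [detect_droplets()] for one frame
#' @param frame_index 0-based index of this frame
#' @param max_link_distance_px maximum linking distance, pixels
#' @return the updated tracker state
#' @export
link_detections <- function(tracker, detections, frame_index,
                            max_link_distance_px) {
  stopifnot(inherits(tracker, "droplet_tracks"))
  tracker$frame <- as.integer(frame_index)
  active_ids <- names(tracker$tracks)[vapply(tracker$tracks,
                                             function(tr) tr$status == "active",
                                             logical(1L))]
  active_ids <- active_ids[order(as.integer(active_ids))]
  n_det <- nrow(detections)
  det_assigned <- rep(FALSE, n_det)
  track_matched <- setNames(rep(FALSE, length(active_ids)), active_ids)
  det_of_track <- setNames(rep(NA_integer_, length(active_ids)), active_ids)
  if (length(active_ids) && n_det) {
    last <- t(vapply(tracker$tracks[active_ids], function(tr) {
      k <- length(tr$frames)
      c(tr$x_px[k], tr$y_px[k])
    }, numeric(2L)))
    dmat <- sqrt(outer(last[, 1L], detections$x_px, "-")^2 +
                   outer(last[, 2L], detections$y_px, "-")^2)
    repeat {
      dmin <- min(dmat)
      if (!is.finite(dmin) || dmin > max_link_distance_px) break
      # which() scans column-major, so among equidistant candidates the
      # lowest row (= lowest track id, ids sorted) wins
      pos <- which(dmat == dmin, arr.ind = TRUE)[1L, ]
      ti <- pos[[1L]]; di <- pos[[2L]]
      id <- active_ids[ti]
      tr <- tracker$tracks[[id]]
      tr$frames <- c(tr$frames, tracker$frame)
      tr$x_px <- c(tr$x_px, detections$x_px[di])
      tr$y_px <- c(tr$y_px, detections$y_px[di])
      tracker$tracks[[id]] <- tr
      track_matched[id] <- TRUE
      det_of_track[id] <- di
      det_assigned[di] <- TRUE
      dmat[ti, ] <- Inf
      dmat[, di] <- Inf
    }
  }
  # unmatched detections open new tracks (split semantics)
  for (di in which(!det_assigned)) {
    id <- as.character(tracker$next_id)
    tracker$tracks[[id]] <- list(id = tracker$next_id,
                                 frames = tracker$frame,
                                 x_px = detections$x_px[di],
                                 y_px = detections$y_px[di],
                                 status = "active")
    tracker$next_id <- tracker$next_id + 1L
  }
  # close tracks that found no detection
  meta <- tracker$meta
  for (id in active_ids[!track_matched]) {
    tr <- tracker$tracks[[id]]
    k <- length(tr$frames)
    px <- tr$x_px[k]; py <- tr$y_px[k]
    rim_d <- sqrt((px - meta$arena_center_px[1L])^2 +
                    (py - meta$arena_center_px[2L])^2)
    status <- "ended"
    if (rim_d >= 0.85 * meta$arena_radius_px) {
      status <- "exited"
    } else if (n_det) {
      matched_det <- det_of_track[!is.na(det_of_track)]
      if (length(matched_det)) {
        dd <- sqrt((detections$x_px[matched_det] - px)^2 +
                     (detections$y_px[matched_det] - py)^2)
        if (any(dd <= max_link_distance_px * 2)) status <- "fused"
      }
    }
    tr$status <- status
    tracker$tracks[[id]] <- tr
  }
  tracker
}

#' Track droplets through a whole video
#'
#' Thresholds each frame (Otsu estimated on the first frame, then fixed),
#' extracts detections and links them frame to frame with the proximity
#' rule.
#'
#' @param frames list of grayscale matrices
#' @param meta a [video_meta()]
#' @param threshold fixed intensity threshold, or `NULL` for Otsu on the
#'   first frame
#' @param min_area_px2 minimum blob area
#' @param max_link_speed_mm_s maximum plausible droplet speed; the per-frame
#'   linking radius is `max_link_speed_mm_s / fps` converted to pixels
#' @return a `droplet_tracks` state; see [tracks_table()] for a tidy view
#' @export
track_video <- function(frames, meta, threshold = NULL, min_area_px2 = 20,
                        max_link_speed_mm_s = 12) {
  stopifnot(length(frames) >= 1L)
  if (is.null(threshold)) threshold <- otsu_threshold(frames[[1L]])
  max_link_px <- (max_link_speed_mm_s / meta$fps) / meta$mm_per_px
  tracker <- new_tracker(meta)
  for (k in seq_along(frames)) {
    det <- detect_droplets(frames[[k]], meta, threshold = threshold,
                           min_area_px2 = min_area_px2)
    tracker <- link_detections(tracker, det, frame_index = k - 1L,
                               max_link_distance_px = max_link_px)
  }
  tracker
}

#' Tidy view of tracked droplets
#'
#' @param tracker a `droplet_tracks` state
#' @return data frame (track_id, frame, t_s, x_mm, y_mm, status)
#' @export
tracks_table <- function(tracker) {
  stopifnot(inherits(tracker, "droplet_tracks"))
  meta <- tracker$meta
  rows <- lapply(tracker$tracks, function(tr) {
    mm <- px_to_mm(cbind(tr$x_px, tr$y_px), meta)
    data.frame(track_id = tr$id, frame = tr$frames,
               t_s = tr$frames / meta$fps,
               x_mm = mm[, 1L], y_mm = mm[, 2L], status = tr$status)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(track_id = integer(0), frame = integer(0),
                      t_s = numeric(0), x_mm = numeric(0), y_mm = numeric(0),
                      status = character(0))
  }
  out[order(out$track_id, out$frame), , drop = FALSE]
}

#' Write tracked droplets as tidy CSV
#' @param tracker a `droplet_tracks` state
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
save_tracks <- function(tracker, path) {
  utils::write.csv(tracks_table(tracker), path, row.names = FALSE)
  invisible(path)
}

#' Behavior metrics from tracked droplets
#'
#' Instantaneous speed is the centroid displacement between consecutive
#' observed frames times the frame rate (per unit frame gap), in mm/s.
#' Per-track speed profiles are smoothed with a centered sliding window
#' (truncated at the sequence ends). The experiment's mean speed is the
#' time-average of instantaneous speed over all active tracks, and the mean
#' droplet count is the time-average of the number of tracked droplets
#' present per frame.
#'
#' @param tracker a `droplet_tracks` state or a tidy tracks data frame
#'   (track_id, frame, x_mm, y_mm)
#' @param meta a [video_meta()]; defaults to the tracker's own metadata
#' @param window_s sliding-window length for the speed profiles, seconds
#' @return list with `observation` (a [behavior_observation()]),
#'   `profiles` (per-track data frames t_s, speed_mm_s, speed_smooth) and
#'   `count_series` (per-frame droplet counts)
#' @export
compute_behavior <- function(tracker, meta = NULL, window_s = 2) {
  tab <- if (inherits(tracker, "droplet_tracks")) {
    if (is.null(meta)) meta <- tracker$meta
    tracks_table(tracker)
  } else {
    tracker
  }
  if (is.null(meta)) stop("invalid input: meta required for plain tables",
                          call. = FALSE)
  if (nrow(tab) == 0L) stop("invalid input: no frames processed",
                            call. = FALSE)
  frames <- sort(unique(tab$frame))
  count_series <- as.numeric(table(factor(tab$frame, levels = frames)))
  win <- max(1L, round(window_s * meta$fps))
  profiles <- list()
  all_speeds <- numeric(0)
  for (id in unique(tab$track_id)) {
    sub <- tab[tab$track_id == id, ]
    sub <- sub[order(sub$frame), ]
    if (nrow(sub) < 2L) next
    gap <- diff(sub$frame)
    disp <- sqrt(diff(sub$x_mm)^2 + diff(sub$y_mm)^2)
    speed <- disp * meta$fps / gap
    profiles[[as.character(id)]] <- data.frame(
      t_s = sub$t_s[-1L], speed_mm_s = speed,
      speed_smooth = moving_average(speed, win))
    all_speeds <- c(all_speeds, speed)
  }
  mean_speed <- if (length(all_speeds)) mean(all_speeds) else 0
  list(observation = behavior_observation(mean_speed, mean(count_series)),
       profiles = profiles, count_series = count_series)
}

# centered moving average with windows truncated at the sequence ends
moving_average <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(x)
  half <- floor(k / 2)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
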