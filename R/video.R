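#' Video metadata
#'
#' Geometry and timing of a droplet video. Pixel coordinates are 0-based,
#' origin top-left, x rightward, y downward; centroids live in continuous
#' pixel units and are converted to mm before any speed computation.
#'
#' @param fps frames per second (the platform records at 20 fps)
#' @param mm_per_px physical pixel pitch, mm
#' @param arena_radius_px dish arena radius in pixels
#' @param arena_center_px arena center `c(x, y)` in pixels; defaults to the
#'   frame center
#' @param width_px,height_px frame size; defaults to the arena plus an
#'   8-pixel margin
#' @return an object of class `video_meta`
#' @export
video_meta <- function(fps = 20, mm_per_px = 0.16, arena_radius_px = 100,
                       arena_center_px = NULL, width_px = NULL,
                       height_px = NULL) {
  stopifnot(fps > 0, mm_per_px > 0, arena_radius_px > 0)
  if (is.null(width_px)) width_px <- 2L * ceiling(arena_radius_px) + 16L
  if (is.null(height_px)) height_px <- 2L * ceiling(arena_radius_px) + 16L
  if (is.null(arena_center_px)) {
    arena_center_px <- c((width_px - 1) / 2, (height_px - 1) / 2)
  }
  structure(list(fps = as.numeric(fps), mm_per_px = as.numeric(mm_per_px),
                 arena_radius_px = as.numeric(arena_radius_px),
                 arena_center_px = as.numeric(arena_center_px),
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px)),
            class = "video_meta")
}

mm_to_px <- function(xy_mm, meta) {
  cbind(meta$arena_center_px[1L] + xy_mm[, 1L] / meta$mm_per_px,
        meta$arena_center_px[2L] + xy_mm[, 2L] / meta$mm_per_px)
}

px_to_mm <- function(xy_px, meta) {
  cbind((xy_px[, 1L] - meta$arena_center_px[1L]) * meta$mm_per_px,
        (xy_px[, 2L] - meta$arena_center_px[2L]) * meta$mm_per_px)
}

# render one anti-aliased dark disk into a frame matrix (frame[row=y+1,col=x+1])
render_disk <- function(frame, cx, cy, radius_px, fg, bg) {
  h <- nrow(frame); w <- ncol(frame)
  x0 <- max(0L, floor(cx - radius_px - 2)); x1 <- min(w - 1L, ceiling(cx + radius_px + 2))
  y0 <- max(0L, floor(cy - radius_px - 2)); y1 <- min(h - 1L, ceiling(cy + radius_px + 2))
  if (x0 > x1 || y0 > y1) return(frame)
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  cover <- pmin(pmax(radius_px - d + 0.5, 0), 1)
  sub <- frame[ys + 1L, xs + 1L, drop = FALSE]
  frame[ys + 1L, xs + 1L] <- pmin(sub, bg - cover * (bg - fg))
  frame
}

#' Generate a synthetic droplet video with exact ground truth
#'
#' Renders dark anti-aliased disks (as Sudan-Black-dyed droplets appear on a
#' light background) at the trajectory positions projected into pixel space,
#' plus optional Gaussian pixel noise and scripted split / fuse / exit
#' events. Ground-truth tracks are emitted alongside the frames.
#'
#' Events are lists with fields `type` (`"split"`, `"fuse"` or `"exit"`),
#' `droplet_id`, `t_s`, and for `"fuse"` the droplet `into` which it merges.
#' A split spawns a new droplet separating at 2 mm/s; a fuse steers the
#' droplet onto its partner over the preceding second and removes it; an
#' exit sends the droplet radially outward at 8 mm/s until it leaves the
#' arena.
#'
#' @param trajs a `trajectory_set` (see [simulate_trajectories()]), or any
#'   list with `tracks` (droplet_id, t_s, x_mm, y_mm) and `duration_s`
#' @param meta a [video_meta()]
#' @param droplet_radius_px rendered disk radius, pixels
#' @param noise_sd Gaussian pixel noise SD (intensity units)
#' @param events optional list of scripted events
#' @param seed seed for the pixel-noise stream
#' @return list with `frames` (list of matrices in `[0, 1]`), `truth`
#'   (data frame track_id, frame, t_s, x_mm, y_mm, x_px, y_px), `status`
#'   (data frame track_id, status) and `meta`
#' @export
generate_synthetic_video <- function(trajs, meta, droplet_radius_px = 6,
                                     noise_sd = 0, events = NULL, seed = 1L) {
  stopifnot(inherits(meta, "video_meta"))
  bg <- 0.85; fg <- 0.15
  duration <- trajs$duration_s
  n_frames <- floor(duration * meta$fps) + 1L
  ft <- (seq_len(n_frames) - 1L) / meta$fps
  arena_mm <- meta$arena_radius_px * meta$mm_per_px
  tr <- trajs$tracks
  ids <- sort(unique(tr$droplet_id))
  entities <- list()
  for (id in ids) {
    sub <- tr[tr$droplet_id == id, ]
    if (any(sqrt(sub$x_mm^2 + sub$y_mm^2) > arena_mm + 1e-9)) {
      stop("fixture error: trajectory of droplet ", id,
           " leaves the arena", call. = FALSE)
    }
    x <- stats::approx(sub$t_s, sub$x_mm, xout = ft, rule = 2)$y
    y <- stats::approx(sub$t_s, sub$y_mm, xout = ft, rule = 2)$y
    entities[[as.character(id)]] <- list(id = as.integer(id), x = x, y = y,
                                         alive = rep(TRUE, n_frames),
                                         status = "ended")
  }
  next_id <- if (length(ids)) as.integer(max(ids)) + 1L else 1L
  for (ev in events) {
    key <- as.character(ev$droplet_id)
    ent <- entities[[key]]
    k0 <- max(1L, which.min(abs(ft - ev$t_s)))
    if (identical(ev$type, "exit")) {
      p0 <- c(ent$x[k0], ent$y[k0])
      dir <- if (sum(p0^2) > 1e-12) p0 / sqrt(sum(p0^2)) else c(1, 0)
      for (k in k0:n_frames) {
        d <- 8 * (ft[k] - ft[k0])
        ent$x[k] <- p0[1L] + dir[1L] * d
        ent$y[k] <- p0[2L] + dir[2L] * d
        if (sqrt(ent$x[k]^2 + ent$y[k]^2) >
              arena_mm - droplet_radius_px * meta$mm_per_px) {
          ent$alive[k:n_frames] <- FALSE
          break
        }
      }
      ent$status <- "exited"
    } else if (identical(ev$type, "split")) {
      dir <- c(0, 1)
      child <- list(id = next_id,
                    x = ent$x + dir[1L] * pmax(0, 2 * (ft - ev$t_s)),
                    y = ent$y + dir[2L] * pmax(0, 2 * (ft - ev$t_s)),
                    alive = ft >= ev$t_s, status = "ended")
      r <- sqrt(child$x^2 + child$y^2)
      child$alive <- child$alive & r < arena_mm
      entities[[as.character(next_id)]] <- child
      next_id <- next_id + 1L
    } else if (identical(ev$type, "fuse")) {
      partner <- entities[[as.character(ev$into)]]
      approach <- ft >= ev$t_s - 1 & ft < ev$t_s
      w <- pmin(1, pmax(0, (ft - (ev$t_s - 1)) / 1))
      ent$x[approach] <- (1 - w[approach]) * ent$x[approach] +
        w[approach] * partner$x[approach]
      ent$y[approach] <- (1 - w[approach]) * ent$y[approach] +
        w[approach] * partner$y[approach]
      ent$alive[ft >= ev$t_s] <- FALSE
      ent$status <- "fused"
    } else {
      stop("fixture error: unknown event type ", ev$type, call. = FALSE)
    }
    if (!identical(ev$type, "split")) entities[[key]] <- ent
  }
  noise_stream <- rng_stream(child_seed(seed, "pixel-noise"))
  frames <- vector("list", n_frames)
  truth <- list()
  for (k in seq_len(n_frames)) {
    fr <- matrix(bg, meta$height_px, meta$width_px)
    for (ent in entities) {
      if (!ent$alive[k]) next
      p <- mm_to_px(cbind(ent$x[k], ent$y[k]), meta)
      fr <- render_disk(fr, p[1L], p[2L], droplet_radius_px, fg, bg)
      truth[[length(truth) + 1L]] <- data.frame(
        track_id = ent$id, frame = k - 1L, t_s = ft[k],
        x_mm = ent$x[k], y_mm = ent$y[k], x_px = p[1L], y_px = p[2L])
    }
    if (noise_sd > 0) {
      fr <- fr + matrix(stream_draw(noise_stream, stats::rnorm,
                                    length(fr), 0, noise_sd),
                        nrow(fr), ncol(fr))
      fr[fr < 0] <- 0; fr[fr > 1] <- 1
    }
    frames[[k]] <- fr
  }
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(track_id = integer(0), frame = integer(0), t_s = numeric(0),
               x_mm = numeric(0), y_mm = numeric(0), x_px = numeric(0),
               y_px = numeric(0))
  status_df <- data.frame(
    track_id = vapply(entities, function(e) e$id, integer(1L)),
    status = vapply(entities, function(e) e$status, character(1L)),
    row.names = NULL)
  list(frames = frames, truth = truth_df, status = status_df, meta = meta)
}
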