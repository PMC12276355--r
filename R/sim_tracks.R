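# Synthetic time-lapse scenario: constant-velocity particles, a fraction
# constrained to a straight-segment vessel network, rendered as Gaussian
# spots, with ground-truth tracks for linker and association recovery
# tests.

#' Motion specification for the time-lapse generator
#'
#' @param n_particles number of cells.
#' @param frames number of frames (>= 2).
#' @param dt hours per frame.
#' @param pixel_size micrometres per pixel.
#' @param speed_range min/max cell speed in micrometres per hour.
#' @param vessel_fraction proportion of cells constrained to the dilated
#'   vessel network.
#' @param detection_dropout probability that a (cell, frame) detection is
#'   missing from the emitted detection lists (frames still render the
#'   cell; dropout emulates detector misses).
#' @param jitter_sd positional jitter sd in pixels added to detections.
#' @param width,height frame size in pixels.
#' @param n_vessels straight vessel segments.
#' @param seed integer seed.
#' @export
motion_spec <- function(n_particles = 20L, frames = 50L, dt = 0.25,
                        pixel_size = 2, speed_range = c(5, 20),
                        vessel_fraction = 0.4, detection_dropout = 0,
                        jitter_sd = 0, width = 256L, height = 256L,
                        n_vessels = 4L, seed = 1L) {
  if (frames < 2) stop("frames must be >= 2")
  if (any(speed_range < 0)) stop("speeds must be >= 0")
  if (vessel_fraction < 0 || vessel_fraction > 1 ||
      detection_dropout < 0 || detection_dropout > 1)
    stop("proportions must be in [0, 1]")
  structure(list(n_particles = as.integer(n_particles),
                 frames = as.integer(frames), dt = dt,
                 pixel_size = pixel_size, speed_range = speed_range,
                 vessel_fraction = vessel_fraction,
                 detection_dropout = detection_dropout,
                 jitter_sd = jitter_sd, width = as.integer(width),
                 height = as.integer(height),
                 n_vessels = as.integer(n_vessels),
                 seed = as.integer(seed)),
            class = "motion_spec")
}

#' Generate a synthetic time-lapse movie with ground-truth tracks
#'
#' Particles move with constant velocity: vessel-associated particles
#' travel along straight vessel segments, the rest move on straight free
#' paths; start points are sampled so that no particle leaves the frame
#' (or its segment) during the movie, keeping per-frame displacement
#' exactly speed * dt.
#'
#' @param spec a [motion_spec()].
#' @return list with `frames` (list of intensity matrices), `vessel_mask`
#'   (logical), `detections` (per frame, data.frame x/y after dropout and
#'   jitter), and `truth` (tracks data.frame id/frame/x/y, per-particle
#'   `speed` in um/h and `vessel` flag).
#' @export
gen_tracks_movie <- function(spec) {
  stopifnot(inherits(spec, "motion_spec"))
  h <- spec$height; w <- spec$width
  with_seed(spec$seed, {
    # straight vessel segments spanning the frame
    segs <- lapply(seq_len(spec$n_vessels), function(i) {
      repeat {
        a <- c(stats::runif(1, 5, w - 4), stats::runif(1, 5, h - 4))
        b <- c(stats::runif(1, 5, w - 4), stats::runif(1, 5, h - 4))
        if (sqrt(sum((a - b)^2)) > 0.6 * min(h, w)) break
      }
      list(a = a, b = b, len = sqrt(sum((a - b)^2)),
           dir = (b - a) / sqrt(sum((a - b)^2)))
    })
    vessel_mask <- matrix(FALSE, h, w)
    for (s in segs) {
      tt <- seq(0, s$len, by = 0.5)
      px <- round(s$a[1] + tt * s$dir[1]); py <- round(s$a[2] + tt * s$dir[2])
      ok <- px >= 2 & px <= w - 1 & py >= 2 & py <= h - 1
      for (d in -1:1) for (e in -1:1)
        vessel_mask[cbind(py[ok] + d, px[ok] + e)] <- TRUE
    }

    dvess <- dist_to(vessel_mask)

    n <- spec$n_particles
    n_ves <- round(spec$vessel_fraction * n)
    is_vessel <- c(rep(TRUE, n_ves), rep(FALSE, n - n_ves))
    speed <- stats::runif(n, spec$speed_range[1], spec$speed_range[2])
    step <- speed * spec$dt / spec$pixel_size   # px per frame
    travel <- step * (spec$frames - 1)

    pos <- array(NA_real_, c(n, spec$frames, 2))   # x, y
    for (i in seq_len(n)) {
      if (is_vessel[i]) {
        s <- segs[[sample.int(length(segs), 1)]]
        tv <- travel[i]
        if (tv >= s$len) { s0 <- 0; dirsgn <- 1; tv <- min(tv, s$len) }
        else {
          s0 <- stats::runif(1, 0, s$len - tv); dirsgn <- sample(c(-1, 1), 1)
          if (dirsgn < 0) s0 <- s$len - s0
        }
        along <- s0 + dirsgn * step[i] * (seq_len(spec$frames) - 1)
        along <- pmin(pmax(along, 0), s$len)
        pos[i, , 1] <- s$a[1] + along * s$dir[1]
        pos[i, , 2] <- s$a[2] + along * s$dir[2]
      } else {
        # free cells keep clear of the vessel corridor over their whole
        # path, so that the planted association labels are unambiguous
        placed <- FALSE
        for (try in seq_len(400L)) {
          theta <- stats::runif(1, 0, 2 * pi)
          vx <- step[i] * cos(theta); vy <- step[i] * sin(theta)
          lox <- max(3, 3 - vx * (spec$frames - 1))
          hix <- min(w - 2, w - 2 - vx * (spec$frames - 1))
          loy <- max(3, 3 - vy * (spec$frames - 1))
          hiy <- min(h - 2, h - 2 - vy * (spec$frames - 1))
          if (lox >= hix || loy >= hiy) next
          x0 <- stats::runif(1, lox, hix); y0 <- stats::runif(1, loy, hiy)
          px <- x0 + vx * (seq_len(spec$frames) - 1)
          py <- y0 + vy * (seq_len(spec$frames) - 1)
          dmin <- min(dvess[cbind(pmin(pmax(round(py), 1), h),
                                  pmin(pmax(round(px), 1), w))])
          if (dmin > 12) { placed <- TRUE; break }
        }
        if (!placed)
          stop("could not place a free cell clear of the vessel network")
        pos[i, , 1] <- px; pos[i, , 2] <- py
      }
    }

    # rendered frames: Gaussian spots, small additive noise
    xs <- matrix(seq_len(w), h, w, byrow = TRUE)
    ys <- matrix(seq_len(h), h, w)
    frames_list <- lapply(seq_len(spec$frames), function(f) {
      img <- matrix(stats::rnorm(h * w, 0, 2), h, w)
      for (i in seq_len(n)) {
        cx <- pos[i, f, 1]; cy <- pos[i, f, 2]
        yr <- max(1, floor(cy - 8)):min(h, ceiling(cy + 8))
        xr <- max(1, floor(cx - 8)):min(w, ceiling(cx + 8))
        img[yr, xr] <- img[yr, xr] + 150 *
          exp(-((xs[yr, xr] - cx)^2 + (ys[yr, xr] - cy)^2) / (2 * 2.5^2))
      }
      pmax(img, 0)
    })

    truth_tracks <- data.frame(
      id = rep(seq_len(n), each = spec$frames),
      frame = rep(seq_len(spec$frames), n),
      x = as.vector(t(pos[, , 1])), y = as.vector(t(pos[, , 2])))

    detections <- lapply(seq_len(spec$frames), function(f) {
      keep <- stats::runif(n) >= spec$detection_dropout
      d <- data.frame(x = pos[keep, f, 1], y = pos[keep, f, 2],
                      truth_id = which(keep))
      if (spec$jitter_sd > 0) {
        d$x <- d$x + stats::rnorm(nrow(d), 0, spec$jitter_sd)
        d$y <- d$y + stats::rnorm(nrow(d), 0, spec$jitter_sd)
      }
      d
    })

    list(frames = frames_list, vessel_mask = vessel_mask,
         detections = detections,
         truth = list(tracks = truth_tracks, speed = speed,
                      vessel = is_vessel, step_px = step))
  })
}
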