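# Time-lapse motility: scale-space blob detection, Kalman-filter track
# linking with optimal gated assignment, track speeds, vessel association
# via mask dilation, and bootstrap inference on association proportions.

log_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  g <- outer(-r:r, -r:r, function(y, x)
    (x^2 + y^2 - 2 * sigma^2) / sigma^4 * exp(-(x^2 + y^2) / (2 * sigma^2)))
  g - mean(g)
}

#' Laplacian-of-Gaussian blob detection
#'
#' Scale-normalised LoG responses over a small sigma ladder; blob centres
#' are 3x3 spatial local maxima of the cross-scale maximum response above
#' `threshold`. Spots closer than the kernel width may merge (the count
#' can then undershoot).
#'
#' @param frame intensity matrix.
#' @param min_sigma,max_sigma blob scale range (pixels).
#' @param n_scales number of scales.
#' @param threshold minimal response, in intensity units (the response to
#'   a blob is a fraction of its amplitude).
#' @return data.frame: x, y, sigma, response.
#' @export
detect_blobs <- function(frame, min_sigma = 1.5, max_sigma = 4,
                         n_scales = 4L, threshold = 30) {
  sigmas <- seq(min_sigma, max_sigma, length.out = n_scales)
  h <- nrow(frame); w <- ncol(frame)
  resp <- array(0, c(h, w, n_scales))
  for (k in seq_len(n_scales)) {
    K <- -log_kernel(sigmas[k])                 # positive at bright blobs
    K <- K / sum(K[K > 0])                      # response in amplitude units
    resp[, , k] <- as.matrix(EBImage::filter2(frame, K))
  }
  best <- apply(resp, c(1, 2), max)
  best_k <- apply(resp, c(1, 2), which.max)
  # 3x3 local maxima of the best response
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- best
  is_max <- best >= threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & best >= pad[2:(h + 1) + dy, 2:(w + 1) + dx]
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
                      response = numeric(0)))
  data.frame(x = idx[, 2], y = idx[, 1],
             sigma = sigmas[best_k[idx]], response = best[idx])
}

new_track <- function(id, frame, x, y, meas_noise) {
  list(id = id, state = c(x, y, 0, 0),
       P = diag(c(meas_noise^2, meas_noise^2, 25, 25)),
       last_frame = frame, misses = 0L,
       frames = frame, xs = x, ys = y)
}

#' Link per-frame detections into tracks with a constant-velocity Kalman
#' filter
#'
#' Each live track predicts its next position with a constant-velocity
#' Kalman filter; predictions are matched to detections by minimal-cost
#' bipartite assignment with a distance gate. Unmatched detections seed
#' new tracks; tracks unmatched for more than `max_gap` consecutive
#' frames terminate. Reported track positions are the assigned (measured)
#' detections, so noiseless scenes are recovered exactly.
#'
#' @param detections list (one per frame) of data.frames with columns
#'   `x`, `y`.
#' @param dt hours per frame.
#' @param pixel_size micrometres per pixel.
#' @param process_noise white-acceleration noise sd (px/frame^2).
#' @param meas_noise measurement noise sd (px).
#' @param gate_radius maximal prediction-to-detection distance (px).
#' @param max_gap frames a track may coast unmatched before termination.
#' @return a `track_set`: `tracks` (id, frame, x, y), `dt`, `pixel_size`.
#' @export
link_tracks <- function(detections, dt = 0.25, pixel_size = 2,
                        process_noise = 0.5, meas_noise = 1,
                        gate_radius = 15, max_gap = 2L) {
  Fm <- diag(4); Fm[1, 3] <- 1; Fm[2, 4] <- 1
  q <- process_noise^2
  Q <- matrix(0, 4, 4)
  Q[1, 1] <- Q[2, 2] <- q / 4; Q[3, 3] <- Q[4, 4] <- q
  Q[1, 3] <- Q[3, 1] <- Q[2, 4] <- Q[4, 2] <- q / 2
  H <- matrix(0, 2, 4); H[1, 1] <- 1; H[2, 2] <- 1
  R <- diag(meas_noise^2, 2)

  live <- list(); done <- list(); next_id <- 1L
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    det <- data.frame(x = det$x, y = det$y)
    # predict
    preds <- lapply(live, function(tr) {
      tr$state <- as.numeric(Fm %*% tr$state)
      tr$P <- Fm %*% tr$P %*% t(Fm) + Q
      tr
    })
    nt <- length(preds); nd <- nrow(det)
    matched_t <- integer(0); matched_d <- integer(0)
    if (nt > 0 && nd > 0) {
      D <- vapply(seq_len(nd), function(j)
        vapply(preds, function(tr)
          sqrt((tr$state[1] - det$x[j])^2 + (tr$state[2] - det$y[j])^2),
          0), numeric(nt))
      D <- matrix(D, nt, nd)
      BIG <- 1e9
      Cg <- ifelse(D <= gate_radius, D, BIG)
      # square formulation allowing unmatched rows and columns
      size <- nt + nd
      Cfull <- matrix(0, size, size)
      Cfull[seq_len(nt), seq_len(nd)] <- Cg
      Cfull[seq_len(nt), nd + seq_len(nt)] <- BIG
      Cfull[cbind(seq_len(nt), nd + seq_len(nt))] <- gate_radius
      Cfull[nt + seq_len(nd), seq_len(nd)] <- BIG
      Cfull[cbind(nt + seq_len(nd), seq_len(nd))] <- gate_radius
      sol <- solve_assignment(Cfull)
      for (i in seq_len(nt)) {
        j <- sol[i]
        if (j <= nd && Cg[i, j] < BIG / 2) {
          matched_t <- c(matched_t, i); matched_d <- c(matched_d, j)
        }
      }
    }
    # update matched tracks
    upd <- preds
    if (length(matched_t)) {
      for (k in seq_along(matched_t)) {
        i <- matched_t[k]; j <- matched_d[k]
        tr <- preds[[i]]
        z <- c(det$x[j], det$y[j])
        S <- H %*% tr$P %*% t(H) + R
        K <- tr$P %*% t(H) %*% solve(S)
        tr$state <- as.numeric(tr$state + K %*% (z - H %*% tr$state))
        tr$P <- (diag(4) - K %*% H) %*% tr$P
        tr$misses <- 0L; tr$last_frame <- f
        tr$frames <- c(tr$frames, f)
        tr$xs <- c(tr$xs, z[1]); tr$ys <- c(tr$ys, z[2])
        upd[[i]] <- tr
      }
    }
    # unmatched tracks coast or die
    keep <- logical(length(upd))
    for (i in seq_along(upd)) {
      if (i %in% matched_t) { keep[i] <- TRUE; next }
      upd[[i]]$misses <- upd[[i]]$misses + 1L
      if (upd[[i]]$misses > max_gap) {
        done <- c(done, upd[i]); keep[i] <- FALSE
      } else keep[i] <- TRUE
    }
    live <- upd[keep]
    # unmatched detections start new tracks
    if (nd > 0) {
      for (j in setdiff(seq_len(nd), matched_d)) {
        live <- c(live, list(new_track(next_id, f, det$x[j], det$y[j],
                                       meas_noise)))
        next_id <- next_id + 1L
      }
    }
  }
  done <- c(done, live)
  tracks <- do.call(rbind, lapply(done, function(tr)
    data.frame(id = tr$id, frame = tr$frames, x = tr$xs, y = tr$ys)))
  if (is.null(tracks))
    tracks <- data.frame(id = integer(0), frame = integer(0),
                         x = numeric(0), y = numeric(0))
  tracks <- tracks[order(tracks$id, tracks$frame), ]
  rownames(tracks) <- NULL
  structure(list(tracks = tracks, dt = dt, pixel_size = pixel_size),
            class = "track_set")
}

#' Mean speed per track (micrometres per hour)
#'
#' Sum of consecutive-detection displacements divided by the elapsed
#' time, i.e. the average speed over the whole lifetime of the track.
#' Tracks with a single detection have undefined speed (NA).
#'
#' @param ts a `track_set`.
#' @return data.frame: id, n_frames, speed.
#' @export
track_speeds <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  by_id <- split(ts$tracks, ts$tracks$id)
  res <- lapply(by_id, function(tr) {
    n <- nrow(tr)
    if (n < 2) return(data.frame(id = tr$id[1], n_frames = n,
                                 speed = NA_real_))
    d <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) * ts$pixel_size
    tspan <- diff(tr$frame) * ts$dt
    data.frame(id = tr$id[1], n_frames = n, speed = sum(d) / sum(tspan))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Vessel association of tracked cells by mask dilation
#'
#' A cell is vessel-associated iff its centre lies inside the vessel mask
#' dilated with a disc of radius `dilation_radius`. For point positions
#' this is a direct mask lookup; for a `track_set` a cell counts as
#' associated when the majority of its track positions lie inside the
#' dilated mask (a free cell briefly crossing a vessel is not
#' associated).
#'
#' @param positions data.frame with `x`, `y` (one row per cell), or a
#'   `track_set`.
#' @param vessel_mask logical matrix.
#' @param dilation_radius disc radius in pixels (default 5).
#' @return list: logical `class` per cell, `proportion` associated.
#' @export
vessel_association <- function(positions, vessel_mask, dilation_radius = 5) {
  if (any(vessel_mask)) {
    brush <- EBImage::makeBrush(2 * dilation_radius + 1, shape = "disc")
    dil <- EBImage::dilate(EBImage::Image(vessel_mask * 1), brush)
    dil <- matrix(as.numeric(dil) > 0, nrow(vessel_mask), ncol(vessel_mask))
  } else {
    dil <- vessel_mask
  }
  lookup <- function(x, y) {
    iy <- pmin(pmax(round(y), 1), nrow(dil))
    ix <- pmin(pmax(round(x), 1), ncol(dil))
    dil[cbind(iy, ix)]
  }
  if (inherits(positions, "track_set")) {
    cls <- vapply(split(positions$tracks, positions$tracks$id),
                  function(tr) mean(lookup(tr$x, tr$y)) > 0.5, TRUE)
  } else {
    if (!nrow(positions)) return(list(class = logical(0), proportion = NaN))
    cls <- lookup(positions$x, positions$y)
  }
  list(class = unname(cls), proportion = mean(cls))
}

#' Bootstrap inference for vessel-association proportions
#'
#' Resamples cells with replacement within replicates; the statistic is
#' the mean of per-replicate proportions. Returns the estimate with a
#' percentile confidence interval and, when a second group is given, a
#' two-sided bootstrap p-value for the difference in proportions.
#'
#' @param replicates list of logical vectors (association class per cell),
#'   one element per replicate.
#' @param replicates2 optional second group for a difference test.
#' @param B bootstrap resamples (default 2000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed.
#' @return list: `estimate`, `ci`, and for two groups `diff`, `p`.
#' @export
bootstrap_proportion <- function(replicates, replicates2 = NULL, B = 2000L,
                                 conf = 0.95, seed = 1L) {
  stat <- function(reps) mean(vapply(reps, mean, 0))
  resample <- function(reps) vapply(reps, function(r)
    mean(r[sample.int(length(r), replace = TRUE)]), 0)
  with_seed(seed, {
    boots <- vapply(seq_len(B), function(b) {
      s1 <- mean(resample(replicates))
      if (is.null(replicates2)) s1
      else s1 - mean(resample(replicates2))
    }, 0)
    alpha <- (1 - conf) / 2
    if (is.null(replicates2)) {
      list(estimate = stat(replicates),
           ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))))
    } else {
      d <- stat(replicates) - stat(replicates2)
      p <- 2 * min(mean(boots <= 0), mean(boots >= 0))
      p <- min(1, max(p, 2 / (B + 1)))
      list(estimate = stat(replicates), diff = d,
           ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))), p = p)
    }
  })
}
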