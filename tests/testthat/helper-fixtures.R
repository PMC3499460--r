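# Shared fixtures: reference synthetic datasets, SNR helpers, and the
# truth-vs-detection matching used by the detection and tracking suites.

# photons giving a stated peak-pixel SNR (peak / sqrt(peak + background))
# for a Gaussian PSF sampled at the given pixel size
photons_for_snr <- function(snr, background = 10, psf_sigma_nm = 130,
                            pixel_size_nm = 106) {
  peak <- (snr^2 + snr * sqrt(snr^2 + 4 * background)) / 2
  peak * 2 * pi * (psf_sigma_nm / pixel_size_nm)^2
}

# ground-truth particles diffusing in a field, as a track_set; starting
# positions keep a minimum separation (sptPALM activates sparse subsets
# precisely so that concurrent emitters stay optically resolvable)
brownian_truth <- function(n_particles, n_frames, D_um2_s = 0.015,
                           fov_nm = c(6784, 6784), dt = 0.05, seed = 1,
                           margin_nm = 800, min_sep_nm = 1000) {
  set.seed(seed)
  sig <- sqrt(2 * D_um2_s * 1e6 * dt)
  sx <- sy <- numeric(0)
  while (length(sx) < n_particles) {
    px <- stats::runif(1, margin_nm, fov_nm[1] - margin_nm)
    py <- stats::runif(1, margin_nm, fov_nm[2] - margin_nm)
    if (length(sx) == 0 || min((sx - px)^2 + (sy - py)^2) >= min_sep_nm^2) {
      sx <- c(sx, px); sy <- c(sy, py)
    }
  }
  rows <- lapply(seq_len(n_particles), function(i) {
    x <- cumsum(c(sx[i], stats::rnorm(n_frames - 1, 0, sig)))
    y <- cumsum(c(sy[i], stats::rnorm(n_frames - 1, 0, sig)))
    data.frame(track_id = i, frame = seq_len(n_frames),
               t_s = (seq_len(n_frames) - 1) * dt, x_nm = x, y_nm = y)
  })
  track_set(do.call(rbind, rows), dt)
}

# render a truth track_set into a reference movie at a stated SNR
reference_movie <- function(truth, snr = 10, background = 10,
                            fov_nm = c(6784, 6784), seed = 1) {
  render_movie(truth, psf_sigma_nm = 130,
               photons = photons_for_snr(snr, background),
               background = background, gain = 50, read_noise = 5,
               pixel_size_nm = 106, fov_nm = fov_nm, seed = seed)
}

# greedy nearest matching of detections to truth within a radius;
# returns per-frame precision/recall counts and the matched pairs
match_detections <- function(truth_points, detections, radius_nm = 200) {
  tp <- 0L; fn <- 0L; pairs <- list()
  used <- rep(FALSE, nrow(detections))
  for (f in sort(unique(truth_points$frame))) {
    tr <- truth_points[truth_points$frame == f, , drop = FALSE]
    di <- which(detections$frame == f)
    for (i in seq_len(nrow(tr))) {
      if (length(di) == 0) { fn <- fn + 1L; next }
      d <- sqrt((detections$x_nm[di] - tr$x_nm[i])^2 +
                (detections$y_nm[di] - tr$y_nm[i])^2)
      j <- which.min(d)
      if (d[j] <= radius_nm && !used[di[j]]) {
        tp <- tp + 1L; used[di[j]] <- TRUE
        pairs[[length(pairs) + 1L]] <-
          data.frame(truth_id = tr$track_id[i], frame = f, det_row = di[j])
      } else fn <- fn + 1L
    }
  }
  fp <- sum(!used)
  list(tp = tp, fp = fp, fn = fn,
       precision = tp / max(tp + fp, 1L), recall = tp / max(tp + fn, 1L),
       pairs = if (length(pairs)) do.call(rbind, pairs) else NULL)
}

# fraction of ground-truth consecutive-frame links reproduced by the tracks
link_recovery <- function(truth, detections, tracks, radius_nm = 200) {
  m <- match_detections(truth$points, detections, radius_nm)
  if (is.null(m$pairs)) return(0)
  # detection row -> built track id (and frame)
  det_track <- rep(NA_integer_, nrow(detections))
  tp <- tracks$points
  for (k in seq_len(nrow(tp))) {
    hit <- which(detections$frame == tp$frame[k] &
                 abs(detections$x_nm - tp$x_nm[k]) < 1e-6 &
                 abs(detections$y_nm - tp$y_nm[k]) < 1e-6)
    if (length(hit)) det_track[hit[1]] <- tp$track_id[k]
  }
  truth_track_of <- m$pairs
  good <- 0L; total <- 0L
  for (id in unique(truth$points$track_id)) {
    fr <- sort(truth$points$frame[truth$points$track_id == id])
    for (i in seq_len(length(fr) - 1L)) {
      total <- total + 1L
      r1 <- truth_track_of[truth_track_of$truth_id == id &
                           truth_track_of$frame == fr[i], "det_row"]
      r2 <- truth_track_of[truth_track_of$truth_id == id &
                           truth_track_of$frame == fr[i + 1], "det_row"]
      if (length(r1) == 1 && length(r2) == 1 &&
          !is.na(det_track[r1]) && !is.na(det_track[r2]) &&
          det_track[r1] == det_track[r2])
        good <- good + 1L
    }
  }
  good / total
}

# exhaustive minimum-cost matching oracle for correspond_frame's objective:
# every track matched to a gated detection or left out at unassign_cost;
# unmatched detections cost unassign_cost each
brute_force_assignment <- function(cost, unassign_cost) {
  n <- nrow(cost); m <- ncol(cost)
  best <- Inf
  # enumerate all injective partial mappings tracks -> detections
  recurse <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > n) {
      tot <- acc + unassign_cost * (m - sum(used))
      if (tot < best) best <<- tot
      return()
    }
    recurse(i + 1L, used, acc + unassign_cost) # track i unassigned
    for (j in seq_len(m)) {
      if (!used[j] && is.finite(cost[i, j])) {
        used[j] <- TRUE
        recurse(i + 1L, used, acc + cost[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, m), 0)
  best
}
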