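# Single-frame particle detection: particle-probability image mapping
# (Haar-like center-surround feature + weak threshold + connected-ratio
# probability), Gaussian refinement, and marker-controlled segmentation of
# the original grayscale frame.

#' Haar-like centre-surround feature map
#'
#' Per-pixel contrast between a particle-sized inner box and a surrounding
#' ring of (approximately) equal area: mean over the inner
#' `particle_size_px` box minus mean over the ring between it and an outer
#' box of twice the inner area, computed with integral images. Constant
#' frames map to an identically zero feature; the feature is linear in the
#' image and invariant to offsets.
#'
#' @param frame numeric matrix.
#' @param particle_size_px nominal particle diameter in px (>= 1); rounded
#'   up to odd.
#' @return numeric matrix of the same size.
#' @export
haar_feature_map <- function(frame, particle_size_px = 5) {
  stopifnot(particle_size_px >= 1)
  w <- as.integer(particle_size_px)
  if (w %% 2L == 0L) w <- w + 1L
  h_in <- (w - 1L) %/% 2L
  # outer box of ~ twice the inner area: side w * sqrt(2), odd
  w_out <- as.integer(ceiling(w * sqrt(2)))
  if (w_out %% 2L == 0L) w_out <- w_out + 1L
  if (w_out <= w) w_out <- w + 2L
  h_out <- (w_out - 1L) %/% 2L
  if (min(dim(frame)) < 3L * w)
    stop("frame smaller than 3x the particle size", call. = FALSE)
  inner <- window_sum(frame, h_in)
  outer <- window_sum(frame, h_out)
  ring_sum <- outer$sum - inner$sum
  ring_cnt <- outer$count - inner$count
  inner$sum / inner$count - ring_sum / pmax(ring_cnt, 1L)
}

#' Weak-threshold pixel classification
#'
#' Coarsely classifies each pixel as particle (`TRUE`) or background from
#' the Haar-like feature. The default threshold is `k_mad` times the median
#' absolute deviation of the feature image - weak by construction, intended
#' to over-segment rather than miss particles.
#'
#' @param feature feature image from [haar_feature_map()].
#' @param threshold explicit threshold; overrides `k_mad` when given.
#' @param k_mad MAD multiplier for the default threshold.
#' @return logical matrix.
#' @export
classify_pixels <- function(feature, threshold = NULL, k_mad = 2) {
  thr <- threshold %||% (k_mad * stats::mad(feature))
  if (!is.finite(thr)) stop("threshold must be finite", call. = FALSE)
  feature > thr
}

#' Particle probability image
#'
#' For each particle pixel: the ratio of the number of pixels in the
#' particle-size window that belong to the pixel's own 8-connected particle
#' component, to the total number of pixels of a full window. Background
#' pixels get probability 0. Probabilities of well-formed particles approach
#' 1; isolated noise pixels get `1 / window_area`.
#'
#' @param mask logical matrix from [classify_pixels()].
#' @param particle_size_px window size in px (rounded up to odd).
#' @return object of class `probability_image` (matrix with values in
#'   [0, 1], attribute `provenance = "raw"`).
#' @export
particle_probability <- function(mask, particle_size_px = 5) {
  w <- as.integer(particle_size_px)
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  lab <- label_components(mask)
  p <- matrix(0, nrow(mask), ncol(mask))
  if (max(lab) > 0) {
    full <- as.numeric(w * w)
    for (l in seq_len(max(lab))) {
      comp <- lab == l
      cnt <- window_sum(comp * 1, half)$sum
      p[comp] <- cnt[comp] / full
    }
  }
  structure(pmin(p, 1), class = "probability_image", provenance = "raw")
}

#' Gaussian refinement of a probability image
#'
#' Applies a rotationally symmetric Gaussian low-pass filter to the particle
#' probability image and clips to [0, 1]. Smoothing preserves total
#' probability mass up to boundary effects.
#'
#' @param p a `probability_image`.
#' @param sigma_px filter sd in px (> 0).
#' @return refined `probability_image` (attribute `provenance = "refined"`).
#' @export
refine_probability <- function(p, sigma_px = 1) {
  stop_if_not_scalar_pos(sigma_px, "sigma_px")
  out <- gaussian_blur(unclass(p), sigma_px)
  structure(pmin(pmax(out, 0), 1), class = "probability_image",
            provenance = "refined")
}

# regional maxima (8-neighbourhood, plateaus allowed) of img above thr
regional_maxima <- function(img, thr) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- img
  mx <- matrix(-Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    mx <- pmax(mx, pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc])
  }
  img >= mx & img >= thr
}

#' Marker-controlled particle segmentation
#'
#' Segments particles from the original grayscale frame under the control of
#' the refined probability image: markers are the 8-connected regional
#' maxima of the refined probability at or above `marker_threshold`; the
#' segmentation support is the refined probability's positive region. Within
#' each support component, pixels are assigned to markers watershed-style by
#' steepest ascent on the original intensity (pixels whose ascent path ends
#' away from any marker fall to the nearest marker of the component).
#' Support components without a marker are discarded.
#'
#' Each segment yields a particle with an intensity-weighted sub-pixel
#' centroid, its pixel area, and its integrated background-subtracted
#' intensity; the background is the median of the frame outside all
#' supports.
#'
#' @param refined refined `probability_image`.
#' @param frame original grayscale frame.
#' @param marker_threshold regional-maximum threshold in [0, 1].
#' @param pixel_size_nm physical pixel size used for the nm centroid.
#' @param frame_index frame number recorded on the particles.
#' @param support_threshold minimal probability counted as support.
#' @return data frame of class `particle_table` with columns `frame`,
#'   `x_nm`, `y_nm`, `x_px`, `y_px`, `area_px`, `intensity`.
#' @export
segment_particles <- function(refined, frame, marker_threshold = 0.3,
                              pixel_size_nm = 106, frame_index = 1L,
                              support_threshold = 0.05) {
  stopifnot(marker_threshold >= 0, marker_threshold <= 1)
  support <- unclass(refined) > support_threshold
  markers <- regional_maxima(unclass(refined), marker_threshold) & support
  empty <- data.frame(frame = integer(0), x_nm = numeric(0),
                      y_nm = numeric(0), x_px = numeric(0),
                      y_px = numeric(0), area_px = integer(0),
                      intensity = numeric(0))
  class(empty) <- c("particle_table", "data.frame")
  if (!any(markers)) return(empty)
  bg <- stats::median(frame[!support])
  if (!is.finite(bg)) bg <- 0
  sup_lab <- label_components(support)
  mark_lab <- label_components(markers)
  n_mark <- max(mark_lab)
  # marker centroids (px centres) for nearest-marker fallback
  mark_pos <- t(vapply(seq_len(n_mark), function(l) {
    idx <- which(mark_lab == l, arr.ind = TRUE)
    c(mean(idx[, 2]) - 0.5, mean(idx[, 1]) - 0.5) # (x, y)
  }, numeric(2)))
  nr <- nrow(frame); nc <- ncol(frame)
  assign_lab <- matrix(0L, nr, nc)
  # steepest-ascent assignment, memoized per pixel
  climb <- function(r, c_) {
    path_r <- integer(0); path_c <- integer(0)
    repeat {
      if (assign_lab[r, c_] != 0L) break
      if (mark_lab[r, c_] > 0L) { assign_lab[r, c_] <<- mark_lab[r, c_]; break }
      path_r <- c(path_r, r); path_c <- c(path_c, c_)
      best_v <- frame[r, c_]; best_r <- r; best_c <- c_
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c_ + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        if (!support[rr, cc]) next
        if (frame[rr, cc] > best_v) { best_v <- frame[rr, cc]
          best_r <- rr; best_c <- cc }
      }
      if (best_r == r && best_c == c_) {
        # local max that is not a marker: nearest marker in this component
        comp <- sup_lab[r, c_]
        cand <- which(vapply(seq_len(n_mark), function(l) {
          idx <- which(mark_lab == l, arr.ind = TRUE)[1, ]
          sup_lab[idx[1], idx[2]] == comp
        }, logical(1)))
        if (length(cand) == 0L) { assign_lab[r, c_] <<- -1L; break }
        d <- (mark_pos[cand, 1] - (c_ - 0.5))^2 +
             (mark_pos[cand, 2] - (r - 0.5))^2
        assign_lab[r, c_] <<- cand[which.min(d)]
        break
      }
      r <- best_r; c_ <- best_c
    }
    lab <- assign_lab[r, c_]
    if (length(path_r) > 0) assign_lab[cbind(path_r, path_c)] <<- lab
    lab
  }
  sup_idx <- which(support, arr.ind = TRUE)
  for (i in seq_len(nrow(sup_idx))) climb(sup_idx[i, 1], sup_idx[i, 2])
  out <- vector("list", n_mark)
  for (l in seq_len(n_mark)) {
    idx <- which(assign_lab == l, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    wgt <- pmax(frame[idx] - bg, 0)
    if (sum(wgt) <= 0) wgt <- rep(1, nrow(idx))
    xc <- sum((idx[, 2] - 0.5) * wgt) / sum(wgt)
    yc <- sum((idx[, 1] - 0.5) * wgt) / sum(wgt)
    out[[l]] <- data.frame(frame = as.integer(frame_index),
                           x_nm = xc * pixel_size_nm,
                           y_nm = yc * pixel_size_nm,
                           x_px = xc, y_px = yc,
                           area_px = nrow(idx),
                           intensity = sum(pmax(frame[idx] - bg, 0)))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  class(res) <- c("particle_table", "data.frame")
  res
}

#' Detect particles in one frame
#'
#' Runs the full single-frame chain: Haar-like feature, weak threshold,
#' particle probability, Gaussian refinement, marker-controlled
#' segmentation.
#'
#' @param frame numeric matrix.
#' @param particle_size_px nominal particle size (px).
#' @param k_mad weak-threshold MAD multiplier.
#' @param marker_threshold marker threshold in [0, 1].
#' @param refine_sigma_px refinement filter sd (px).
#' @param pixel_size_nm physical pixel size.
#' @param frame_index frame number recorded on the particles.
#' @return a `particle_table` (see [segment_particles()]).
#' @export
detect_frame <- function(frame, particle_size_px = 5, k_mad = 2,
                         marker_threshold = 0.3, refine_sigma_px = 1,
                         pixel_size_nm = 106, frame_index = 1L) {
  feat <- haar_feature_map(frame, particle_size_px)
  mask <- classify_pixels(feat, k_mad = k_mad)
  prob <- particle_probability(mask, particle_size_px)
  ref <- refine_probability(prob, refine_sigma_px)
  segment_particles(ref, frame, marker_threshold,
                    pixel_size_nm = pixel_size_nm, frame_index = frame_index)
}

#' Detect particles in every frame of a stack
#'
#' @param stack an [image_stack()].
#' @param ... passed to [detect_frame()].
#' @return a `particle_table` over all frames.
#' @export
detect_particles <- function(stack, ...) {
  res <- lapply(seq_along(stack$frames), function(f)
    detect_frame(stack$frames[[f]], pixel_size_nm = stack$pixel_size_nm,
                 frame_index = f, ...))
  out <- do.call(rbind, res)
  class(out) <- c("particle_table", "data.frame")
  out
}
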