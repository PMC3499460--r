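# Synthetic camera movies (EMCCD model) and vesicle fusion traces.

#' Render a synthetic camera movie
#'
#' Renders point emitters into an EMCCD-like frame stack. Each emitter
#' contributes an integrated 2-D Gaussian PSF (error-function integral over
#' each pixel). Per pixel, Poisson shot noise is applied to the expected
#' photon count (signal + uniform background) *before* multiplication by the
#' EM gain, and Gaussian read noise is added *after* the gain. Emitters
#' outside the field of view are silently clipped (their integral simply
#' falls outside the raster).
#'
#' @param obj a [molecular_map()] (static emitters, repeated over
#'   `n_frames`) or a [track_set()] (emitter positions per frame).
#' @param psf_sigma_nm PSF Gaussian sd in nm.
#' @param photons expected photons per emitter per frame.
#' @param background expected background photons per pixel per frame.
#' @param gain EMCCD gain factor.
#' @param read_noise Gaussian read noise sd in counts (post-gain).
#' @param pixel_size_nm physical pixel size.
#' @param n_frames number of frames (molecular-map input only).
#' @param fov_nm field of view `c(width, height)` in nm; defaults to the map
#'   bounds, or to the bounding box of the tracks.
#' @param frame_interval_s frame interval in s.
#' @param shot_noise logical; disable to obtain noiseless expectation frames.
#' @param seed integer seed.
#' @return an [image_stack()]; its `meta` attribute records all parameters.
#' @export
render_movie <- function(obj, psf_sigma_nm = 130, photons = 500,
                         background = 10, gain = 100, read_noise = 5,
                         pixel_size_nm = 106, n_frames = 10, fov_nm = NULL,
                         frame_interval_s = 0.05, shot_noise = TRUE, seed = 1) {
  stop_if_not_scalar_pos(psf_sigma_nm, "psf_sigma_nm")
  stop_if_not_scalar_pos(photons, "photons")
  stop_if_not_scalar_pos(pixel_size_nm, "pixel_size_nm")
  if (inherits(obj, "molecular_map")) {
    fov_nm <- fov_nm %||% map_bounds(obj)
    per_frame <- rep(list(map_coords(obj)), n_frames)
  } else if (inherits(obj, "track_set")) {
    p <- obj$points
    fov_nm <- fov_nm %||% c(max(p$x_nm) + 5 * psf_sigma_nm,
                            max(p$y_nm) + 5 * psf_sigma_nm)
    frames_idx <- sort(unique(p$frame))
    n_frames <- max(frames_idx)
    per_frame <- lapply(seq_len(n_frames), function(f) {
      sub <- p[p$frame == f, , drop = FALSE]
      cbind(sub$x_nm, sub$y_nm)
    })
    frame_interval_s <- obj$frame_interval_s
  } else stop("obj must be a molecular_map or a track_set", call. = FALSE)
  nc <- max(1L, ceiling(fov_nm[1] / pixel_size_nm))
  nr <- max(1L, ceiling(fov_nm[2] / pixel_size_nm))
  ex <- pixel_size_nm * (0:nc)  # pixel edges, x
  ey <- pixel_size_nm * (0:nr)
  set.seed(seed)
  frames <- lapply(per_frame, function(em) {
    img <- matrix(background, nr, nc)
    if (nrow(em) > 0) {
      for (i in seq_len(nrow(em))) {
        fx <- diff(stats::pnorm(ex, em[i, 1], psf_sigma_nm))
        fy <- diff(stats::pnorm(ey, em[i, 2], psf_sigma_nm))
        img <- img + photons * (fy %o% fx)
      }
    }
    if (shot_noise)
      img <- matrix(stats::rpois(length(img), img), nr, nc)
    img <- img * gain
    if (read_noise > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, read_noise), nr, nc)
    img
  })
  st <- image_stack(frames, pixel_size_nm = pixel_size_nm,
                    frame_interval_s = frame_interval_s, gain = gain)
  attr(st, "meta") <- list(psf_sigma_nm = psf_sigma_nm, photons = photons,
                           background = background, gain = gain,
                           read_noise = read_noise, shot_noise = shot_noise,
                           fov_nm = fov_nm, seed = seed)
  st
}

#' Simulate a vesicle fusion intensity trace
#'
#' Fusion of an EGFP-loaded vesicle shows as a rapid fluorescence increase
#' (un-quenching) followed by an exponential decay as cargo diffuses away.
#' The trace is `baseline + noise` before the fusion time, steps to
#' `baseline + spike_amplitude` at fusion, and decays with time constant
#' `decay_tau_s` after.
#'
#' @param baseline pre-fusion mean intensity.
#' @param spike_amplitude intensity jump at fusion; 0 gives a flat trace.
#' @param decay_tau_s exponential decay constant (s), > 0.
#' @param fusion_time_s fusion time within the trace.
#' @param noise_sigma additive Gaussian noise sd.
#' @param duration_s trace duration (s).
#' @param dt_s sampling interval (s).
#' @param seed integer seed.
#' @return numeric intensity vector with attributes `t_s` (sample times),
#'   `fusion_frame` (index of the first post-fusion sample) and `dt_s`.
#' @export
simulate_fusion_trace <- function(baseline = 100, spike_amplitude = 200,
                                  decay_tau_s = 0.5, fusion_time_s = 2.5,
                                  noise_sigma = 5, duration_s = 5,
                                  dt_s = 0.05, seed = 1) {
  stop_if_not_scalar_pos(decay_tau_s, "decay_tau_s")
  if (fusion_time_s < 0 || fusion_time_s > duration_s)
    stop("fusion_time_s must lie within the trace duration", call. = FALSE)
  t <- seq(0, duration_s, by = dt_s)
  set.seed(seed)
  sig <- ifelse(t >= fusion_time_s,
                spike_amplitude * exp(-(t - fusion_time_s) / decay_tau_s), 0)
  tr <- baseline + sig +
    if (noise_sigma > 0) stats::rnorm(length(t), 0, noise_sigma) else 0
  attr(tr, "t_s") <- t
  attr(tr, "fusion_frame") <- which(t >= fusion_time_s)[1]
  attr(tr, "dt_s") <- dt_s
  tr
}
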