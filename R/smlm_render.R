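# SMLM localization and rendering: Gaussian fitting, activation-cycle
# summation, stage-drift quantification, and rendering at SMLM, STED-like
# and diffraction-limited resolutions.

#' Effective camera pixel size in the sample plane
#'
#' `floor(1000 * detector_pitch_um / magnification)` nm; floored to whole nm
#' (a 16 um detector behind a 150x objective gives 106 nm).
#'
#' @param detector_pitch_um physical detector pixel pitch, um.
#' @param magnification total magnification.
#' @return pixel size in whole nm.
#' @export
effective_pixel_size <- function(detector_pitch_um, magnification) {
  stop_if_not_scalar_pos(detector_pitch_um, "detector_pitch_um")
  stop_if_not_scalar_pos(magnification, "magnification")
  floor(1000 * detector_pitch_um / magnification)
}

#' Sum the frames of one activation cycle
#'
#' Pixel-wise sum of the frames belonging to one photoactivation cycle,
#' performed before localization to collapse repeated emissions from
#' long-lived dark states into a single spot.
#'
#' @param stack an [image_stack()].
#' @param cycle integer frame indices.
#' @return a single summed frame (matrix).
#' @export
sum_activation_cycle <- function(stack, cycle) {
  cycle <- as.integer(cycle)
  if (length(cycle) == 0) stop("empty activation cycle", call. = FALSE)
  if (any(cycle < 1) || any(cycle > length(stack$frames)))
    stop("cycle indices outside the stack", call. = FALSE)
  Reduce(`+`, stack$frames[cycle])
}

#' Localize one spot by 2-D Gaussian fitting
#'
#' Least-squares fit of `A * exp(-((x-x0)^2+(y-y0)^2) / (2 s^2)) + b` to a
#' candidate region, giving a sub-pixel centroid, the photon count (from the
#' fitted volume divided by the gain) and a Thompson-style localization
#' precision from the fit parameters.
#'
#' @param frame numeric matrix.
#' @param center_px approximate spot centre `c(col, row)` in px; defaults to
#'   the frame argmax.
#' @param halfwidth_px half-width of the square fit region.
#' @param pixel_size_nm physical pixel size.
#' @param gain camera gain used to convert counts to photons.
#' @return on success a list with `x_nm`, `y_nm`, `x_px`, `y_px`,
#'   `sigma_px`, `photons`, `precision_nm`, `converged = TRUE`; on a
#'   non-convergent or degenerate fit a list with `converged = FALSE`.
#' @export
localize_gaussian <- function(frame, center_px = NULL, halfwidth_px = 5,
                              pixel_size_nm = 106, gain = 1) {
  if (is.null(center_px)) {
    i <- arrayInd(which.max(frame), dim(frame))
    center_px <- c(i[2], i[1])
  }
  nr <- nrow(frame); nc <- ncol(frame)
  c0 <- round(center_px[1]); r0 <- round(center_px[2])
  cs <- max(1, c0 - halfwidth_px):min(nc, c0 + halfwidth_px)
  rs <- max(1, r0 - halfwidth_px):min(nr, r0 + halfwidth_px)
  sub <- frame[rs, cs, drop = FALSE]
  # pixel-centre coordinates of the region
  xg <- matrix(cs - 0.5, nrow(sub), ncol(sub), byrow = TRUE)
  yg <- matrix(rs - 0.5, nrow(sub), ncol(sub))
  z <- as.vector(sub); x <- as.vector(xg); y <- as.vector(yg)
  b0 <- min(z); a0 <- max(z) - b0
  if (a0 <= 0) return(list(converged = FALSE))
  start <- list(A = a0, x0 = x[which.max(z)], y0 = y[which.max(z)],
                s = 1.3, b = b0)
  fit <- tryCatch(
    minpack.lm::nlsLM(z ~ A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)) + b,
                      start = start,
                      lower = c(A = 0, x0 = min(x) - 1, y0 = min(y) - 1,
                                s = 0.3, b = -Inf),
                      upper = c(A = Inf, x0 = max(x) + 1, y0 = max(y) + 1,
                                s = diff(range(x)) + 1, b = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(converged = FALSE))
  p <- as.list(stats::coef(fit))
  if (p$A <= 0 || !is.finite(p$x0) || !is.finite(p$y0))
    return(list(converged = FALSE))
  # reject fits indistinguishable from a flat frame: amplitude below the
  # residual noise level
  resid_sd <- stats::sd(stats::resid(fit))
  if (p$A < 5 * resid_sd) return(list(converged = FALSE))
  # a physical PSF is never narrower than ~half a pixel: fits collapsing to
  # the sigma floor are single noise pixels, not spots
  if (p$s < 0.6) return(list(converged = FALSE))
  photons <- 2 * pi * p$A * p$s^2 / gain
  s_nm <- p$s * pixel_size_nm
  a_nm <- pixel_size_nm
  b_photons <- max(resid_sd / gain, 0)
  prec2 <- (s_nm^2 + a_nm^2 / 12) / photons +
    8 * pi * s_nm^4 * b_photons^2 / (a_nm^2 * photons^2)
  list(x_nm = p$x0 * pixel_size_nm, y_nm = p$y0 * pixel_size_nm,
       x_px = p$x0, y_px = p$y0, sigma_px = p$s, photons = photons,
       precision_nm = sqrt(prec2), converged = TRUE)
}

#' Localize every frame of a bead series and quantify residual drift
#'
#' Localizes the fiducial in each frame by Gaussian fitting (seeded from the
#' previous frame's position) and reports the smallest radius about the mean
#' centroid containing a stated fraction of the per-frame centroids
#' (default 99.9%).
#'
#' @param bead_stack an [image_stack()] with one dominant fiducial.
#' @param fraction fraction of centroids the radius must contain.
#' @param halfwidth_px fit-region half-width.
#' @return object of class `drift_report`: list with `centroids_nm`
#'   (frames x 2), `radius_nm`, `fraction`.
#' @export
assess_drift <- function(bead_stack, fraction = 0.999, halfwidth_px = 5) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- length(bead_stack$frames)
  cents <- matrix(NA_real_, n, 2)
  centre <- NULL
  for (f in seq_len(n)) {
    loc <- localize_gaussian(bead_stack$frames[[f]], center_px = centre,
                             halfwidth_px = halfwidth_px,
                             pixel_size_nm = bead_stack$pixel_size_nm,
                             gain = bead_stack$gain)
    if (!isTRUE(loc$converged))
      stop(sprintf("fiducial lost in frame %d", f), call. = FALSE)
    cents[f, ] <- c(loc$x_nm, loc$y_nm)
    centre <- c(loc$x_px, loc$y_px)
  }
  mu <- colMeans(cents)
  r <- sqrt((cents[, 1] - mu[1])^2 + (cents[, 2] - mu[2])^2)
  rs <- sort(r)
  radius <- rs[max(1L, ceiling(fraction * n))]
  structure(list(centroids_nm = cents, radius_nm = radius,
                 fraction = fraction),
            class = "drift_report")
}

#' Localization table
#'
#' Standard long-form localization table used between the localization and
#' rendering stages.
#'
#' @param x_nm,y_nm coordinates in nm.
#' @param frame integer acquisition frame (>= 0).
#' @param photons photon count per localization.
#' @param precision_nm localization precision (> 0).
#' @param source_id optional ground-truth molecule id.
#' @return data frame of class `localization_table`.
#' @export
localization_table <- function(x_nm, y_nm, frame = 0L, photons = NA_real_,
                               precision_nm = NA_real_, source_id = NULL) {
  stopifnot(all(frame >= 0), all(is.na(precision_nm) | precision_nm > 0))
  df <- data.frame(x_nm = x_nm, y_nm = y_nm,
                   frame = rep_len(as.integer(frame), length(x_nm)),
                   photons = rep_len(photons, length(x_nm)),
                   precision_nm = rep_len(precision_nm, length(x_nm)))
  if (!is.null(source_id)) df$source_id <- rep_len(source_id, length(x_nm))
  structure(df, class = c("localization_table", "data.frame"))
}

# shared rasterizer: each localization drawn as a unit-integral Gaussian of
# the given sd (possibly per-row), integrated over pixels
raster_gaussians <- function(x_nm, y_nm, sigma_nm, out_pixel_nm, fov_nm) {
  nc <- max(1L, ceiling(fov_nm[1] / out_pixel_nm))
  nr <- max(1L, ceiling(fov_nm[2] / out_pixel_nm))
  img <- matrix(0, nr, nc)
  ex <- out_pixel_nm * (0:nc); ey <- out_pixel_nm * (0:nr)
  sigma_nm <- rep_len(sigma_nm, length(x_nm))
  for (i in seq_along(x_nm)) {
    fx <- diff(stats::pnorm(ex, x_nm[i], sigma_nm[i]))
    fy <- diff(stats::pnorm(ey, y_nm[i], sigma_nm[i]))
    img <- img + fy %o% fx
  }
  img
}

#' Render a localization table as an SMLM image
#'
#' `"points"` mode bins localizations into pixels (2-D histogram);
#' `"gaussian"` mode draws each localization as a unit-integral Gaussian of
#' sd equal to its localization precision. In both modes the image integral
#' equals the number of localizations, up to raster clipping at the field
#' edge.
#'
#' @param locs a [localization_table()].
#' @param mode `"points"` or `"gaussian"`.
#' @param out_pixel_nm output pixel size, nm.
#' @param fov_nm field of view `c(width, height)` nm; defaults to the
#'   localization bounding box padded by 5 pixels.
#' @return numeric matrix (rows = y).
#' @export
render_smlm <- function(locs, mode = c("gaussian", "points"),
                        out_pixel_nm = 10, fov_nm = NULL) {
  mode <- match.arg(mode)
  stop_if_not_scalar_pos(out_pixel_nm, "out_pixel_nm")
  if (nrow(locs) == 0) {
    warning("empty localization table; returning a zero image")
    return(matrix(0, 1, 1))
  }
  fov_nm <- fov_nm %||% c(max(locs$x_nm) + 5 * out_pixel_nm,
                          max(locs$y_nm) + 5 * out_pixel_nm)
  if (mode == "points") {
    nc <- max(1L, ceiling(fov_nm[1] / out_pixel_nm))
    nr <- max(1L, ceiling(fov_nm[2] / out_pixel_nm))
    ix <- pmin(pmax(floor(locs$x_nm / out_pixel_nm) + 1L, 1L), nc)
    iy <- pmin(pmax(floor(locs$y_nm / out_pixel_nm) + 1L, 1L), nr)
    img <- matrix(0, nr, nc)
    tab <- table((ix - 1L) * nr + iy)
    img[as.integer(names(tab))] <- as.vector(tab)
    return(img)
  }
  sig <- locs$precision_nm
  sig[is.na(sig)] <- stats::median(locs$precision_nm, na.rm = TRUE)
  if (all(is.na(sig))) sig <- rep(out_pixel_nm, nrow(locs))
  raster_gaussians(locs$x_nm, locs$y_nm, sig, out_pixel_nm, fov_nm)
}

#' Convolve a localization map to a lower-resolution image
#'
#' Renders the localization delta image convolved with an isotropic
#' Gaussian PSF of the stated FWHM, sampled at `out_pixel_nm`. Presets:
#' diffraction-limited TIRFM = 250 nm FWHM at 106 nm pixels; STED = 60 nm
#' FWHM at 30 nm pixels.
#'
#' @param locs a [localization_table()].
#' @param psf_fwhm_nm PSF full width at half maximum, nm.
#' @param out_pixel_nm output pixel size, nm.
#' @param fov_nm optional field of view, nm.
#' @return numeric matrix.
#' @export
convolve_to_resolution <- function(locs, psf_fwhm_nm = 250,
                                   out_pixel_nm = 106, fov_nm = NULL) {
  stop_if_not_scalar_pos(psf_fwhm_nm, "psf_fwhm_nm")
  stop_if_not_scalar_pos(out_pixel_nm, "out_pixel_nm")
  if (nrow(locs) == 0) {
    warning("empty localization table; returning a zero image")
    return(matrix(0, 1, 1))
  }
  fov_nm <- fov_nm %||% c(max(locs$x_nm) + 5 * out_pixel_nm,
                          max(locs$y_nm) + 5 * out_pixel_nm)
  sigma <- psf_fwhm_nm / (2 * sqrt(2 * log(2)))
  raster_gaussians(locs$x_nm, locs$y_nm, sigma, out_pixel_nm, fov_nm)
}
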