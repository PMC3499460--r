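# Per-track and population kinematics: speeds, maximum displacement,
# turning-angle rose diagrams, cumulative displacement profiles, and
# pre-fusion vesicle speed profiles.

# largest pairwise distance within one track (nm)
max_displacement <- function(x, y) {
  if (length(x) < 2) return(NA_real_)
  max(stats::dist(cbind(x, y)))
}

#' Per-track kinematics summary
#'
#' For every track with at least two points: step speeds (step displacement
#' divided by the step time), the track mean speed, the total path length
#' (sum of step lengths) and the maximum displacement (the longest distance
#' between any two points of the track). Single-point tracks are skipped and
#' counted.
#'
#' @param tracks a [track_set()].
#' @return object of class `kinematics_summary`: list with `per_track`
#'   (data frame: `track_id`, `n_points`, `mean_speed_um_s`,
#'   `total_length_nm`, `max_displacement_nm`), `n_skipped`
#'   (single-point tracks) and summary statistics `speed_mean`, `speed_sd`
#'   in um/s.
#' @export
track_kinematics <- function(tracks) {
  per <- lapply(track_split(tracks), function(tr) {
    n <- nrow(tr)
    if (n < 2) return(NULL)
    dx <- diff(tr$x_nm); dy <- diff(tr$y_nm); dt <- diff(tr$t_s)
    step <- sqrt(dx^2 + dy^2)
    data.frame(track_id = tr$track_id[1], n_points = n,
               mean_speed_um_s = mean(step / dt) / 1000,
               total_length_nm = sum(step),
               max_displacement_nm = max_displacement(tr$x_nm, tr$y_nm))
  })
  keep <- !vapply(per, is.null, logical(1))
  df <- do.call(rbind, per[keep])
  if (is.null(df))
    df <- data.frame(track_id = integer(0), n_points = integer(0),
                     mean_speed_um_s = numeric(0), total_length_nm = numeric(0),
                     max_displacement_nm = numeric(0))
  rownames(df) <- NULL
  structure(list(per_track = df, n_skipped = sum(!keep),
                 speed_mean = mean(df$mean_speed_um_s),
                 speed_sd = stats::sd(df$mean_speed_um_s)),
            class = "kinematics_summary")
}

#' Turning-angle rose histogram
#'
#' Bins step directions into 36 wedges of 10 degrees covering (-180, 180]
#' (counter-clockwise positive; the first positive wedge is (0, 10]).
#' In `"deviation"` mode the angle is the signed deviation of each step from
#' the forward extension of the preceding step (three consecutive points
#' define one angle); a reversal gives 180 degrees. In `"absolute"` mode the
#' angle is the lab-frame direction of each step. Zero-length steps have no
#' direction and are skipped. Each wedge also carries the mean speed of the
#' steps contributing to it.
#'
#' @param tracks a [track_set()].
#' @param mode `"deviation"` or `"absolute"`.
#' @return object of class `rose_histogram`: list with `wedges` (data frame:
#'   `wedge_start_deg`, `wedge_end_deg`, `frequency`, `mean_speed_um_s`,
#'   `n`), `angles_deg` (raw angles), `speeds_um_s`, `mode`.
#' @export
turning_angles <- function(tracks, mode = c("deviation", "absolute")) {
  mode <- match.arg(mode)
  angles <- numeric(0); speeds <- numeric(0)
  for (tr in track_split(tracks)) {
    n <- nrow(tr)
    dx <- diff(tr$x_nm); dy <- diff(tr$y_nm); dt <- diff(tr$t_s)
    len <- sqrt(dx^2 + dy^2)
    dir <- atan2(dy, dx) # direction of each step
    if (mode == "absolute") {
      ok <- len > 0
      angles <- c(angles, dir[ok] * 180 / pi)
      speeds <- c(speeds, (len / dt)[ok] / 1000)
    } else {
      if (n < 3) next
      i <- seq_len(n - 2) # consecutive step pairs
      ok <- len[i] > 0 & len[i + 1] > 0
      th <- (dir[i + 1] - dir[i])[ok] * 180 / pi
      th <- ((th + 180) %% 360) - 180 # wrap to (-180, 180]
      th[th == -180] <- 180
      angles <- c(angles, th)
      speeds <- c(speeds, (len[i + 1] / dt[i + 1])[ok] / 1000)
    }
  }
  # wedge index 1 = (-180, -170], ..., 36 = (170, 180]
  idx <- ceiling((angles + 180) / 10)
  idx[idx < 1L] <- 1L
  n_w <- tabulate(idx, nbins = 36)
  ms <- rep(NA_real_, 36)
  if (length(angles) > 0) {
    agg <- tapply(speeds, factor(idx, levels = 1:36), mean)
    ms <- as.numeric(agg)
  }
  wedges <- data.frame(wedge_start_deg = seq(-180, 170, by = 10),
                       wedge_end_deg = seq(-170, 180, by = 10),
                       frequency = if (length(angles)) n_w / length(angles)
                                   else rep(0, 36),
                       mean_speed_um_s = ms, n = n_w)
  structure(list(wedges = wedges, angles_deg = angles,
                 speeds_um_s = speeds, mode = mode),
            class = "rose_histogram")
}

#' Direction-reversal bias
#'
#' Fraction of deviation-mode turning angles with |angle| > 90 degrees.
#' Isotropic (Brownian) motion gives 0.5; confined motion ("a ball
#' ricocheting inside a box") gives a value above 0.5.
#'
#' @param rose a deviation-mode `rose_histogram`.
#' @return scalar in [0, 1].
#' @export
reversal_bias <- function(rose) {
  if (!inherits(rose, "rose_histogram") || rose$mode != "deviation")
    stop("reversal_bias needs a deviation-mode rose histogram", call. = FALSE)
  if (length(rose$angles_deg) == 0) return(NA_real_)
  mean(abs(rose$angles_deg) > 90)
}

#' Cumulative maximum-displacement profile by track length
#'
#' Bins tracks by total path length (default: quartiles of the observed
#' total-length distribution) and reports, per bin, the cumulative number of
#' tracks as a function of maximum displacement.
#'
#' @param tracks a [track_set()].
#' @param length_bins optional numeric breakpoints (nm) for the total-length
#'   bins; defaults to the quartiles.
#' @return list of class `displacement_profile`: per bin a data frame
#'   (`max_displacement_nm`, `cumulative_n`) plus the bin breaks.
#' @export
cumulative_displacement_profile <- function(tracks, length_bins = NULL) {
  kin <- track_kinematics(tracks)$per_track
  if (nrow(kin) == 0) stop("no usable tracks", call. = FALSE)
  breaks <- length_bins %||%
    unique(stats::quantile(kin$total_length_nm, probs = seq(0, 1, 0.25)))
  if (length(breaks) < 2) breaks <- c(0, max(kin$total_length_nm))
  bin <- cut(kin$total_length_nm, breaks = breaks, include.lowest = TRUE)
  profiles <- lapply(split(kin$max_displacement_nm, bin), function(md) {
    md <- sort(md)
    data.frame(max_displacement_nm = md, cumulative_n = seq_along(md))
  })
  structure(list(profiles = profiles, breaks = breaks),
            class = "displacement_profile")
}

#' Pre-fusion vesicle speed profile
#'
#' Averages the instantaneous speed of fusion-aligned vesicle track excerpts
#' over events, on a time axis ending at 0 (the fusion frame). Reports mean
#' and SEM per time point; SEM is NA where only one event contributes.
#'
#' @param excerpts list of aligned excerpts as returned by
#'   [detect_fusion_events()]: data frames with columns `t_rel_s`, `x_nm`,
#'   `y_nm`.
#' @return data frame with columns `t_rel_s`, `mean_speed_um_s`,
#'   `sem_speed_um_s`, `n`.
#' @export
prefusion_speed_profile <- function(excerpts) {
  stopifnot(length(excerpts) >= 1)
  speed_tab <- lapply(excerpts, function(e) {
    if (nrow(e) < 2) return(NULL)
    dt <- diff(e$t_rel_s)
    v <- sqrt(diff(e$x_nm)^2 + diff(e$y_nm)^2) / dt / 1000
    data.frame(t_rel_s = e$t_rel_s[-1], speed = v)
  })
  speed_tab <- do.call(rbind, speed_tab)
  if (is.null(speed_tab)) stop("no excerpt has >= 2 points", call. = FALSE)
  sp <- split(speed_tab$speed, speed_tab$t_rel_s)
  out <- data.frame(t_rel_s = as.numeric(names(sp)),
                    mean_speed_um_s = vapply(sp, mean, numeric(1)),
                    sem_speed_um_s = vapply(sp, function(v)
                      if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                      else NA_real_, numeric(1)),
                    n = lengths(sp))
  out[order(out$t_rel_s), ]
}
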