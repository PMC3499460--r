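# S3 containers used throughout the pipeline. All coordinates are in nm,
# origin at the lower-left corner of the domain, x right / y up.

#' Molecular coordinate map
#'
#' Container for 2-D molecular coordinates with species labels, the
#' rectangular domain they live on, and (for synthetic data) ground-truth
#' cluster membership.
#'
#' @param x,y numeric coordinates in nm.
#' @param species character species label per point (recycled).
#' @param bounds numeric length-2 domain size `c(width_nm, height_nm)`.
#' @param truth optional integer cluster id per point (0 = background).
#' @return an object of class `molecular_map`: a data frame with columns
#'   `x_nm`, `y_nm`, `species` (and `truth` if given) plus a `bounds`
#'   attribute.
#' @export
molecular_map <- function(x, y, species = "SNAP-25", bounds, truth = NULL) {
  stopifnot(length(x) == length(y), length(bounds) == 2, all(bounds > 0))
  if (length(x) > 0 &&
      (any(x < 0) || any(y < 0) || any(x > bounds[1]) || any(y > bounds[2])))
    stop("all points must lie within the domain bounds", call. = FALSE)
  df <- data.frame(x_nm = as.numeric(x), y_nm = as.numeric(y),
                   species = rep_len(as.character(species), length(x)),
                   stringsAsFactors = FALSE)
  if (!is.null(truth)) df$truth <- rep_len(as.integer(truth), length(x))
  structure(df, bounds = as.numeric(bounds),
            class = c("molecular_map", "data.frame"))
}

#' @export
print.molecular_map <- function(x, ...) {
  b <- attr(x, "bounds")
  cat(sprintf("<molecular_map> %d molecules on %.2f x %.2f um\n",
              nrow(x), b[1] / 1000, b[2] / 1000))
  print(table(x$species))
  invisible(x)
}

map_bounds <- function(map) attr(map, "bounds")
map_coords <- function(map) cbind(map$x_nm, map$y_nm)

#' Secretory vesicle set
#'
#' Vesicle centroid coordinates with a shared physical radius and optional
#' per-vesicle fluorescence intensity traces.
#'
#' @param x,y centroid coordinates in nm.
#' @param radius_nm physical vesicle radius (default 200 nm).
#' @param bounds domain size in nm, `c(width, height)`.
#' @param traces optional numeric matrix of intensity traces
#'   (vesicles x frames).
#' @param frame_interval_s sampling interval of `traces`, in s.
#' @return an object of class `vesicle_set`.
#' @export
vesicle_set <- function(x, y, radius_nm = 200, bounds,
                        traces = NULL, frame_interval_s = NA_real_) {
  stopifnot(length(x) == length(y), radius_nm > 0, length(bounds) == 2)
  if (length(x) > 0 &&
      (any(x < 0) || any(y < 0) || any(x > bounds[1]) || any(y > bounds[2])))
    stop("vesicle centroids must lie within the domain bounds", call. = FALSE)
  if (!is.null(traces)) {
    traces <- as.matrix(traces)
    stopifnot(nrow(traces) == length(x))
  }
  structure(list(x_nm = as.numeric(x), y_nm = as.numeric(y),
                 radius_nm = radius_nm, bounds = as.numeric(bounds),
                 traces = traces, frame_interval_s = frame_interval_s),
            class = "vesicle_set")
}

#' @export
print.vesicle_set <- function(x, ...) {
  cat(sprintf("<vesicle_set> %d vesicles, radius %.0f nm%s\n",
              length(x$x_nm), x$radius_nm,
              if (is.null(x$traces)) "" else
                sprintf(", traces of %d frames", ncol(x$traces))))
  invisible(x)
}

n_vesicles <- function(ves) length(ves$x_nm)
vesicle_coords <- function(ves) cbind(ves$x_nm, ves$y_nm)

#' Camera image stack
#'
#' Ordered list of equally sized 2-D intensity frames with the acquisition
#' metadata needed to interpret them physically.
#'
#' @param frames list of numeric matrices (identical dimensions).
#' @param pixel_size_nm physical pixel pitch in the sample plane.
#' @param frame_interval_s time between frames in s.
#' @param gain EMCCD gain factor applied after shot noise.
#' @param activation_cycles optional list of integer frame-index vectors,
#'   one per photoactivation cycle.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size_nm, frame_interval_s = 0.05,
                        gain = 1, activation_cycles = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1)
  stop_if_not_scalar_pos(pixel_size_nm, "pixel_size_nm")
  stop_if_not_scalar_pos(frame_interval_s, "frame_interval_s")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share dimensions", call. = FALSE)
  structure(list(frames = frames, pixel_size_nm = pixel_size_nm,
                 frame_interval_s = frame_interval_s, gain = gain,
                 activation_cycles = activation_cycles),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frames of %d x %d px (%.0f nm px, %.3f s)\n",
              length(x$frames), d[1], d[2], x$pixel_size_nm,
              x$frame_interval_s))
  invisible(x)
}

#' Track set
#'
#' Time-ordered particle trajectories. Stored long-form: one row per
#' (track, frame) observation.
#'
#' @param df data frame with columns `track_id`, `frame`, `t_s`, `x_nm`,
#'   `y_nm` and optionally `intensity`, `area_px`.
#' @param frame_interval_s nominal frame interval in s.
#' @return an object of class `track_set`.
#' @export
track_set <- function(df, frame_interval_s) {
  need <- c("track_id", "frame", "t_s", "x_nm", "y_nm")
  if (!all(need %in% names(df)))
    stop("track data frame needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$track_id, df$t_s), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 0) {
    ok <- tapply(df$t_s, df$track_id, function(t) all(diff(t) > 0))
    if (!all(unlist(ok)))
      stop("timestamps must strictly increase within a track", call. = FALSE)
    dup <- duplicated(df[, c("track_id", "frame")])
    if (any(dup)) stop("duplicate (track, frame) rows", call. = FALSE)
  }
  structure(list(points = df, frame_interval_s = frame_interval_s),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks, %d points, dt = %.3f s\n",
              length(unique(x$points$track_id)), nrow(x$points),
              x$frame_interval_s))
  invisible(x)
}

n_tracks <- function(ts) length(unique(ts$points$track_id))

# split a track_set into per-track coordinate data frames, in time order
track_split <- function(ts) {
  split(ts$points, ts$points$track_id)
}
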