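# File interchange: molecule / vesicle / track CSVs, ThunderSTORM-style
# localization tables, TIFF stacks with JSON metadata sidecars, YAML
# configurations.

#' Write / read a molecular map as CSV
#'
#' Columns `x_nm`, `y_nm`, `species` (plus `truth` when present); the domain
#' bounds travel in a `# bounds_nm:` header comment.
#'
#' @param map a [molecular_map()].
#' @param path CSV file path.
#' @return `write_molecular_map` returns `path` invisibly;
#'   `read_molecular_map` returns a [molecular_map()].
#' @export
write_molecular_map <- function(map, path) {
  b <- map_bounds(map)
  con <- file(path, "w")
  writeLines(sprintf("# bounds_nm: %.6f %.6f", b[1], b[2]), con)
  utils::write.csv(as.data.frame(map), con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_molecular_map
#' @export
read_molecular_map <- function(path) {
  hdr <- readLines(path, n = 1)
  b <- as.numeric(strsplit(sub("# bounds_nm: *", "", hdr), " ")[[1]])
  df <- utils::read.csv(path, comment.char = "#")
  molecular_map(df$x_nm, df$y_nm, species = df$species, bounds = b,
                truth = df$truth)
}

#' Write / read a vesicle set as CSV
#'
#' @param ves a [vesicle_set()].
#' @param path CSV file path.
#' @return the path (write) or a [vesicle_set()] (read).
#' @export
write_vesicles <- function(ves, path) {
  con <- file(path, "w")
  writeLines(sprintf("# bounds_nm: %.6f %.6f radius_nm: %.6f",
                     ves$bounds[1], ves$bounds[2], ves$radius_nm), con)
  utils::write.csv(data.frame(vesicle_id = seq_along(ves$x_nm),
                              x_nm = ves$x_nm, y_nm = ves$y_nm),
                   con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_vesicles
#' @export
read_vesicles <- function(path) {
  hdr <- readLines(path, n = 1)
  nums <- as.numeric(regmatches(hdr, gregexpr("[0-9.]+", hdr))[[1]])
  df <- utils::read.csv(path, comment.char = "#")
  vesicle_set(df$x_nm, df$y_nm, radius_nm = nums[3], bounds = nums[1:2])
}

#' Write / read a track set as CSV
#'
#' Long form: `track_id`, `frame`, `t_s`, `x_nm`, `y_nm` (+ `intensity`,
#' `area_px` when present).
#'
#' @param tracks a [track_set()].
#' @param path CSV file path.
#' @param frame_interval_s frame interval used when reading.
#' @return the path (write) or a [track_set()] (read).
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks$points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path, frame_interval_s = 0.05) {
  track_set(utils::read.csv(path), frame_interval_s)
}

#' Write / read a localization table (ThunderSTORM-compatible CSV)
#'
#' Column names follow the ThunderSTORM convention: `"x [nm]"`, `"y [nm]"`,
#' `"frame"`, `"intensity [photon]"`, `"uncertainty [nm]"`.
#'
#' @param locs a [localization_table()].
#' @param path CSV file path.
#' @return the path (write) or a [localization_table()] (read).
#' @export
write_localizations <- function(locs, path) {
  df <- data.frame(locs$frame, locs$x_nm, locs$y_nm, locs$photons,
                   locs$precision_nm, check.names = FALSE)
  names(df) <- c("frame", "x [nm]", "y [nm]", "intensity [photon]",
                 "uncertainty [nm]")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  localization_table(x_nm = df[["x [nm]"]], y_nm = df[["y [nm]"]],
                     frame = df[["frame"]],
                     photons = df[["intensity [photon]"]],
                     precision_nm = df[["uncertainty [nm]"]])
}

#' Write / read an image stack as multi-frame TIFF with a JSON sidecar
#'
#' Frames are scaled to the 32-bit float range expected by the TIFF writer;
#' pixel size, frame interval, gain and activation cycles travel in a
#' `<path>.json` sidecar.
#'
#' @param stack an [image_stack()].
#' @param path TIFF file path.
#' @return the path (write) or an [image_stack()] (read).
#' @export
write_stack <- function(stack, path) {
  tiff::writeTIFF(lapply(stack$frames, function(f) f / 65535),
                  path, bits.per.sample = 32L)
  meta <- list(pixel_size_nm = stack$pixel_size_nm,
               frame_interval_s = stack$frame_interval_s,
               gain = stack$gain,
               activation_cycles = stack$activation_cycles,
               scale = 65535)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(frames, function(f) f * (meta$scale %||% 1))
  image_stack(frames, pixel_size_nm = meta$pixel_size_nm,
              frame_interval_s = meta$frame_interval_s,
              gain = meta$gain %||% 1,
              activation_cycles = meta$activation_cycles)
}

#' Write a Ripley result as CSV
#'
#' @param rip a `ripley_result` from [monte_carlo_envelope()].
#' @param path CSV file path.
#' @return the path, invisibly.
#' @export
write_ripley <- function(rip, path) {
  utils::write.csv(as.data.frame(rip), path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration (YAML)
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}
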