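# End-to-end orchestration: generate -> detect -> track -> statistics ->
# simulate, from a single configuration, with derived per-stage seeds and a
# provenance manifest.

PIPELINE_STAGES <- c("generate", "detect", "track", "ripley", "occupancy",
                     "contours", "rose", "simulate")

validate_run_config <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  if (is.null(config$seed) || !is.numeric(config$seed))
    stop("config$seed (integer) is required", call. = FALSE)
  stages <- config$stages %||% "all"
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  # pre-flight: every explicitly referenced input must exist
  for (s in stages) {
    inp <- config[[s]]$input
    if (!is.null(inp) && !file.exists(inp))
      stop(sprintf("stage '%s': input not found: %s", s, inp), call. = FALSE)
  }
  stages
}

#' Run the analysis pipeline
#'
#' Executes the selected stages from one configuration. Each stochastic
#' stage receives a sub-seed derived deterministically from the global seed,
#' so re-running the same configuration reproduces identical outputs. A
#' `manifest.json` records the configuration hash, package version,
#' per-stage sub-seeds and MD5 checksums of every output file; on a stage
#' failure the partial manifest is written before the error propagates.
#'
#' Configuration keys: `seed` (required), `stages` (subset of
#' generate, detect, track, ripley, occupancy, contours, rose, simulate,
#' or `"all"`), and one optional parameter block per stage. Stages read the
#' outputs of earlier stages from the run directory unless an explicit
#' `input` path is given in their block.
#'
#' @param config a named list or the path to a YAML file.
#' @param out_dir run directory (created if needed); defaults to
#'   `config$out_dir` or a `"snarescape-run"` directory under the current
#'   working directory.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stages <- validate_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% "snarescape-run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  cfg_file <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_file)),
                   package_version =
                     as.character(utils::packageVersion("snarescape")),
                   seed = config$seed, stages = stages,
                   sub_seeds = list(), outputs = list())
  p <- function(...) file.path(out_dir, ...)
  record <- function(stage, files) {
    for (f in files)
      manifest$outputs[[basename(f)]] <<- unname(tools::md5sum(f))
  }
  flush_manifest <- function(partial = FALSE) {
    manifest$partial <<- partial
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  run_stage <- function(stage, fun) {
    sub <- derive_seed(config$seed, match(stage, PIPELINE_STAGES))
    manifest$sub_seeds[[stage]] <<- sub
    files <- tryCatch(fun(sub), error = function(e) {
      flush_manifest(partial = TRUE)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    record(stage, files)
  }
  blk <- function(s) config[[s]] %||% list()

  if ("generate" %in% stages) run_stage("generate", function(sub) {
    b <- blk("generate")
    cfg <- synthetic_config(
      density_per_um2 = b$density_per_um2 %||% 55,
      parent_per_um2 = b$parent_per_um2 %||% 2,
      sigma_c_nm = b$sigma_c_nm %||% 50,
      background_fraction = b$background_fraction %||% 0.2,
      bounds_nm = unlist(b$bounds_nm %||% c(10000, 10000)),
      n_vesicles = b$n_vesicles %||% 20,
      vesicle_bias = b$vesicle_bias %||% 2,
      seed = sub)
    map <- generate_molecular_map(cfg)
    ves <- place_vesicles(map, cfg$n_vesicles, cfg$vesicle_bias,
                          seed = derive_seed(sub, 1),
                          radius_nm = cfg$vesicle_radius_nm)
    write_molecular_map(map, p("map.csv"))
    write_vesicles(ves, p("vesicles.csv"))
    # short movie of diffusing emitters for the detection chain
    n_mov <- b$movie_molecules %||% 8
    nf <- b$movie_frames %||% 30
    sim <- simulate_dynamics(
      sim_config(domain_nm = c(3000, 3000), duration_s = nf * 0.05,
                 sample_interval_s = 0.05, seed = derive_seed(sub, 2)),
      molecular_map(stats::runif(n_mov, 500, 2500),
                    stats::runif(n_mov, 500, 2500),
                    bounds = c(3000, 3000)),
      vesicle_set(numeric(0), numeric(0), bounds = c(3000, 3000)))
    trk <- subsample_tracks(sim, bleach_mean_s = Inf,
                            seed = derive_seed(sub, 3))
    movie <- render_movie(trk, photons = b$movie_photons %||% 800,
                          background = 10, gain = 50, read_noise = 5,
                          pixel_size_nm = 106, fov_nm = c(3000, 3000),
                          seed = derive_seed(sub, 4))
    write_stack(movie, p("movie.tif"))
    c(p("map.csv"), p("vesicles.csv"), p("movie.tif"),
      paste0(p("movie.tif"), ".json"))
  })

  if ("detect" %in% stages) run_stage("detect", function(sub) {
    b <- blk("detect")
    stack <- read_stack(b$input %||% p("movie.tif"))
    parts <- detect_particles(stack,
                              particle_size_px = b$particle_size_px %||% 5,
                              k_mad = b$k_mad %||% 2,
                              marker_threshold = b$marker_threshold %||% 0.3)
    utils::write.csv(parts, p("particles.csv"), row.names = FALSE)
    p("particles.csv")
  })

  if ("track" %in% stages) run_stage("track", function(sub) {
    b <- blk("track")
    parts <- utils::read.csv(b$input %||% p("particles.csv"))
    ts <- build_tracks(parts, frame_interval_s = b$frame_interval_s %||% 0.05,
                       meas_sigma_nm = b$meas_sigma_nm %||% 20)
    write_tracks(ts, p("tracks.csv"))
    p("tracks.csv")
  })

  if ("ripley" %in% stages) run_stage("ripley", function(sub) {
    b <- blk("ripley")
    map <- read_molecular_map(b$input %||% p("map.csv"))
    rip <- monte_carlo_envelope(map, n_sim = b$n_sim %||% 100, seed = sub)
    write_ripley(rip, p("ripley.csv"))
    p("ripley.csv")
  })

  if ("occupancy" %in% stages) run_stage("occupancy", function(sub) {
    b <- blk("occupancy")
    map <- read_molecular_map(b$input %||% p("map.csv"))
    ves <- read_vesicles(b$vesicles %||% p("vesicles.csv"))
    occ <- assign_and_count(map, ves,
                            window_radius_nm = b$window_radius_nm %||% 82.5)
    utils::write.csv(data.frame(vesicle_id = seq_along(occ$counts),
                                count = occ$counts),
                     p("occupancy.csv"), row.names = FALSE)
    p("occupancy.csv")
  })

  if ("contours" %in% stages) run_stage("contours", function(sub) {
    b <- blk("contours")
    ts <- read_tracks(b$input %||% p("tracks.csv"),
                      frame_interval_s = b$frame_interval_s %||% 0.05)
    cm <- contour_maps(ts, box_nm = b$box_nm %||% 100)
    utils::write.csv(cm$density, p("contour_density.csv"), row.names = FALSE)
    utils::write.csv(cm$speed, p("contour_speed.csv"), row.names = FALSE)
    c(p("contour_density.csv"), p("contour_speed.csv"))
  })

  if ("rose" %in% stages) run_stage("rose", function(sub) {
    b <- blk("rose")
    ts <- read_tracks(b$input %||% p("tracks.csv"),
                      frame_interval_s = b$frame_interval_s %||% 0.05)
    rose <- turning_angles(ts, mode = b$mode %||% "deviation")
    utils::write.csv(rose$wedges, p("rose.csv"), row.names = FALSE)
    p("rose.csv")
  })

  if ("simulate" %in% stages) run_stage("simulate", function(sub) {
    b <- blk("simulate")
    map <- read_molecular_map(b$input %||% p("map.csv"))
    ves <- read_vesicles(b$vesicles %||% p("vesicles.csv"))
    scfg <- sim_config(domain_nm = map_bounds(map),
                       duration_s = b$duration_s %||% 5,
                       dt_fine_s = b$dt_fine_s %||% 1e-5,
                       seed = sub)
    sim <- simulate_dynamics(scfg, map, ves)
    occ <- occupancy(sim)
    dist <- occupancy_distribution(occ)
    utils::write.csv(data.frame(count = dist$counts_range,
                                mean_freq = dist$mean_freq),
                     p("sim_occupancy.csv"), row.names = FALSE)
    trk <- subsample_tracks(sim, bleach_mean_s = b$bleach_mean_s %||% 0.5,
                            seed = derive_seed(sub, 1))
    write_tracks(trk, p("sim_tracks.csv"))
    c(p("sim_occupancy.csv"), p("sim_tracks.csv"))
  })

  flush_manifest(partial = FALSE)
  invisible(manifest)
}
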