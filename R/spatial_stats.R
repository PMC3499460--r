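# Point-pattern statistics: Ripley K/L with Monte-Carlo envelopes,
# vesicle-centric occupancy counting, interaction geometry, contour maps.

#' Ripley's K function
#'
#' Second-order summary of a 2-D point pattern:
#' `K(r) = (area / n^2) * sum_{i != j} 1[d_ij <= r]`.
#' No edge correction is applied; the identical estimator is used for the
#' observed data and for every randomization, so shared boundary bias
#' cancels in the envelope comparison. The maximum radius is capped at one
#' quarter of the shorter domain side.
#'
#' @param map a [molecular_map()] with at least 2 points.
#' @param radii increasing numeric radii grid in nm; default 50 values up to
#'   a quarter of the shorter domain side.
#' @return data frame with columns `r_nm` and `K`.
#' @export
ripley_k <- function(map, radii = NULL) {
  n <- nrow(map)
  if (n < 2) stop("Ripley's K needs at least 2 points", call. = FALSE)
  b <- map_bounds(map)
  rmax_ok <- min(b) / 4
  radii <- radii %||% seq(0, rmax_ok, length.out = 51)[-1]
  if (max(radii) > rmax_ok + 1e-9)
    stop("max radius exceeds a quarter of the shorter domain side",
         call. = FALSE)
  d <- stats::dist(map_coords(map))
  counts <- 2 * vapply(radii, function(r) sum(d <= r), numeric(1))
  data.frame(r_nm = radii, K = prod(b) / n^2 * counts)
}

#' L transformation of Ripley's K
#'
#' `L(r) = sqrt(K(r) / pi)`; under complete spatial randomness `L(r) = r`,
#' so `L(r) - r` linearizes deviations from randomness.
#'
#' @param K numeric vector of K values (or the data frame from [ripley_k()]).
#' @return numeric vector of L values (or the input data frame with `L` and
#'   `L_minus_r` columns added).
#' @export
ripley_l <- function(K) {
  if (is.data.frame(K)) {
    K$L <- sqrt(K$K / pi)
    K$L_minus_r <- K$L - K$r_nm
    return(K)
  }
  if (any(K < 0)) stop("K must be non-negative", call. = FALSE)
  sqrt(K / pi)
}

#' Monte-Carlo randomization envelope for Ripley's L
#'
#' Redistributes the same number of molecules uniformly over the same domain
#' `n_sim` times (default 1000), computes L(r) for each randomization, and
#' reports the pointwise min/max envelope. The observed L is classified per
#' radius as `above`, `within` or `below` the envelope; deviation above the
#' envelope at short radii indicates a non-random pattern with areas of high
#' and low density, deviation below would indicate minimum-distance ordering.
#'
#' @param map observed [molecular_map()].
#' @param radii radii grid (nm); defaults as in [ripley_k()].
#' @param n_sim number of randomizations (>= 1).
#' @param seed integer seed.
#' @return object of class `ripley_result`: data frame with columns `r_nm`,
#'   `K`, `L`, `L_minus_r`, `env_lo`, `env_hi`, `class`.
#' @export
monte_carlo_envelope <- function(map, radii = NULL, n_sim = 1000, seed = 1) {
  stopifnot(n_sim >= 1)
  obs <- ripley_l(ripley_k(map, radii))
  b <- map_bounds(map)
  n <- nrow(map)
  set.seed(seed)
  sims <- matrix(NA_real_, length(obs$r_nm), n_sim)
  for (s in seq_len(n_sim)) {
    sim_map <- molecular_map(stats::runif(n, 0, b[1]),
                             stats::runif(n, 0, b[2]), bounds = b)
    sims[, s] <- ripley_l(ripley_k(sim_map, obs$r_nm)$K)
  }
  obs$env_lo <- apply(sims, 1, min)
  obs$env_hi <- apply(sims, 1, max)
  obs$class <- ifelse(obs$L > obs$env_hi, "above",
                      ifelse(obs$L < obs$env_lo, "below", "within"))
  structure(obs, class = c("ripley_result", "data.frame"), n_sim = n_sim)
}

#' Half-length of the vesicle contact chord
#'
#' For a vesicle of radius `R` docked on the plasma membrane (bilayer
#' separation 0), the membrane region within molecular reach `h` of the
#' vesicle surface is a disc whose radius is the half-length of the chord at
#' height `h`: `sqrt(2 * R * h - h^2)`. With the combined maximum tSNARE +
#' vSNARE reach of 17.8 nm and a 200 nm vesicle radius this gives the
#' 82.5 nm interaction window used throughout the occupancy analysis.
#'
#' @param reach_h_nm molecular reach above the membrane plane, nm.
#' @param vesicle_radius_nm vesicle radius, nm.
#' @return chord half-length in nm.
#' @export
chord_half_length <- function(reach_h_nm = 17.8, vesicle_radius_nm = 200) {
  stopifnot(reach_h_nm >= 0, vesicle_radius_nm > 0)
  if (reach_h_nm > 2 * vesicle_radius_nm)
    stop("reach exceeds the vesicle diameter", call. = FALSE)
  sqrt(2 * vesicle_radius_nm * reach_h_nm - reach_h_nm^2)
}

#' Nearest-vesicle assignment and occupancy counting
#'
#' Assigns every molecule to its nearest vesicle centroid (Euclidean) and
#' counts, per vesicle, the assigned molecules within the interaction
#' window. Because the count is restricted to assigned molecules, a molecule
#' within the window of two overlapping vesicles is counted only for the
#' nearer one.
#'
#' @param mols [molecular_map()].
#' @param ves [vesicle_set()] with at least one vesicle.
#' @param window_radius_nm interaction window radius (default 82.5 nm).
#' @return object of class `occupancy_histogram`: list with `counts`
#'   (per-vesicle), `histogram` (table over integer counts 0..max), `mean`
#'   and `window_radius_nm`.
#' @export
assign_and_count <- function(mols, ves, window_radius_nm = 82.5) {
  if (n_vesicles(ves) < 1) stop("need at least one vesicle", call. = FALSE)
  nv <- n_vesicles(ves)
  counts <- integer(nv)
  if (nrow(mols) > 0) {
    d <- cross_dist(map_coords(mols), vesicle_coords(ves))
    nearest <- max.col(-d, ties.method = "first")
    dmin <- d[cbind(seq_len(nrow(d)), nearest)]
    inwin <- nearest[dmin <= window_radius_nm]
    tab <- tabulate(inwin, nbins = nv)
    counts <- as.integer(tab)
  }
  hist <- tabulate(counts + 1L, nbins = max(counts) + 1L)
  names(hist) <- 0:max(counts)
  structure(list(counts = counts, histogram = hist,
                 mean = mean(counts), window_radius_nm = window_radius_nm),
            class = "occupancy_histogram")
}

#' Combine occupancy histograms across replicates
#'
#' Mean and SEM (sd / sqrt(n), n - 1 denominator) of the per-count relative
#' frequencies across replicate maps, as plotted for n cells.
#'
#' @param occ_list list of `occupancy_histogram` objects.
#' @return data frame with columns `count`, `mean_freq`, `sem_freq`.
#' @export
combine_occupancy <- function(occ_list) {
  stopifnot(length(occ_list) >= 1)
  kmax <- max(vapply(occ_list, function(o) max(o$counts), numeric(1)))
  freq <- vapply(occ_list, function(o) {
    f <- tabulate(o$counts + 1L, nbins = kmax + 1L)
    f / sum(f)
  }, numeric(kmax + 1))
  freq <- matrix(freq, nrow = kmax + 1)
  n <- length(occ_list)
  sem <- if (n > 1) apply(freq, 1, stats::sd) / sqrt(n) else rep(NA_real_, kmax + 1)
  data.frame(count = 0:kmax, mean_freq = rowMeans(freq), sem_freq = sem)
}

#' Track density and speed contour maps
#'
#' Segments the field into square boxes (default 100 nm) and reports, per
#' box, (i) the number of distinct tracks passing through it, normalized so
#' all density values sum to one, and (ii) the mean of the mean speeds of
#' the tracks passing through it. A track is counted at most once per box;
#' "passing through" is judged from the sampled track points.
#'
#' @param tracks a [track_set()] with at least one track.
#' @param box_nm box edge length in nm.
#' @return object of class `contour_maps`: list with `density` and `speed`
#'   matrices (rows = y bins, cols = x bins), `box_nm`, `origin_nm`.
#' @export
contour_maps <- function(tracks, box_nm = 100) {
  p <- tracks$points
  if (nrow(p) == 0) stop("no tracks", call. = FALSE)
  ox <- floor(min(p$x_nm) / box_nm) * box_nm
  oy <- floor(min(p$y_nm) / box_nm) * box_nm
  nx <- max(1L, ceiling((max(p$x_nm) - ox) / box_nm + 1e-9))
  ny <- max(1L, ceiling((max(p$y_nm) - oy) / box_nm + 1e-9))
  ix <- pmin(pmax(floor((p$x_nm - ox) / box_nm) + 1L, 1L), nx)
  iy <- pmin(pmax(floor((p$y_nm - oy) / box_nm) + 1L, 1L), ny)
  box <- (ix - 1L) * ny + iy
  # mean speed per track
  kin <- track_kinematics(tracks)$per_track
  spd <- stats::setNames(kin$mean_speed_um_s, kin$track_id)
  # distinct (track, box) visits
  visits <- unique(data.frame(track = p$track_id, box = box))
  dens <- matrix(0, ny, nx)
  tab <- table(visits$box)
  dens[as.integer(names(tab))] <- as.vector(tab)
  dens <- dens / sum(dens)
  speed <- matrix(NA_real_, ny, nx)
  vs <- split(spd[as.character(visits$track)], visits$box)
  mv <- vapply(vs, function(v) mean(v, na.rm = TRUE), numeric(1))
  speed[as.integer(names(mv))] <- mv
  structure(list(density = dens, speed = speed, box_nm = box_nm,
                 origin_nm = c(ox, oy)),
            class = "contour_maps")
}
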