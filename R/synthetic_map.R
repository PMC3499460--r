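# Synthetic ground truth: clustered molecular point patterns, density-biased
# vesicle placement, and localization-error / blinking corruption.

#' Synthetic dataset configuration
#'
#' Parameters of the synthetic plasma-membrane model. Molecules are drawn
#' from a Thomas cluster process (Poisson parents, Poisson offspring with
#' isotropic Gaussian displacement) superposed on a uniform background, which
#' reproduces the drifts of higher and lower molecular density seen in SMLM
#' maps of tSNAREs. The mean offspring count is derived from the target
#' density so that the expected total count is always
#' `density_per_um2 * area`.
#'
#' @param density_per_um2 target molecular density (default 55, calibrated so
#'   the expectation within the 82.5 nm interaction window is ~1.2 molecules).
#' @param parent_per_um2 cluster (parent) intensity per um^2.
#' @param mean_offspring optional mean molecules per cluster; when supplied it
#'   overrides `density_per_um2`, which is then implied by
#'   `parent_per_um2 * mean_offspring / (1 - background_fraction)`.
#' @param sigma_c_nm Gaussian cluster spread (offspring dispersion), nm.
#' @param background_fraction fraction of molecules placed uniformly; 1 gives
#'   complete spatial randomness.
#' @param bounds_nm domain size `c(width, height)` in nm.
#' @param species species label for generated molecules.
#' @param n_vesicles number of vesicles to place.
#' @param vesicle_bias non-negative strength of the bias of vesicles towards
#'   low molecular density (0 = uniform placement).
#' @param vesicle_radius_nm physical vesicle radius.
#' @param loc_sigma_range_nm localization-error range `c(lo, hi)` in nm
#'   (default 4-21 nm, the PALM/GSDIM precision range).
#' @param blink_mean mean number of repeated localizations per molecule
#'   (geometric, minimum 1); 0 disables blinking.
#' @param seed mandatory integer seed; there is no hidden global state.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(density_per_um2 = 55,
                             parent_per_um2 = 2,
                             mean_offspring = NULL,
                             sigma_c_nm = 50,
                             background_fraction = 0.2,
                             bounds_nm = c(10000, 10000),
                             species = "SNAP-25",
                             n_vesicles = 20,
                             vesicle_bias = 2,
                             vesicle_radius_nm = 200,
                             loc_sigma_range_nm = c(4, 21),
                             blink_mean = 0,
                             seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (!is.null(mean_offspring)) {
    stopifnot(mean_offspring > 0)
    density_per_um2 <- parent_per_um2 * mean_offspring /
      max(1 - background_fraction, .Machine$double.eps)
  }
  stopifnot(density_per_um2 > 0, parent_per_um2 > 0, sigma_c_nm >= 0,
            background_fraction >= 0, background_fraction <= 1,
            n_vesicles >= 0, vesicle_bias >= 0,
            all(loc_sigma_range_nm >= 0), all(loc_sigma_range_nm <= 50),
            blink_mean == 0 || blink_mean >= 1)
  structure(list(density_per_um2 = density_per_um2,
                 parent_per_um2 = parent_per_um2,
                 sigma_c_nm = sigma_c_nm,
                 background_fraction = background_fraction,
                 bounds_nm = as.numeric(bounds_nm),
                 species = species,
                 n_vesicles = n_vesicles,
                 vesicle_bias = vesicle_bias,
                 vesicle_radius_nm = vesicle_radius_nm,
                 loc_sigma_range_nm = as.numeric(loc_sigma_range_nm),
                 blink_mean = blink_mean,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a clustered molecular map
#'
#' Draws a molecular point pattern on a rectangular domain from a Thomas
#' cluster process plus a uniform background. Parents are Poisson with
#' intensity `parent_per_um2`; each parent receives a Poisson number of
#' offspring displaced by an isotropic Gaussian of sd `sigma_c_nm`; offspring
#' falling outside the domain are wrapped periodically so the realized
#' intensity stays homogeneous. The expected total count equals
#' `density_per_um2 * area`.
#'
#' @param config a [synthetic_config()].
#' @return a [molecular_map()] whose `truth` column holds the parent cluster
#'   id per molecule (0 for background molecules).
#' @export
generate_molecular_map <- function(config) {
  b <- config$bounds_nm
  area_um2 <- prod(b) / 1e6
  if (area_um2 <= 0) stop("zero-area domain", call. = FALSE)
  n_expected <- config$density_per_um2 * area_um2
  if (n_expected > 1e7)
    stop("expected point count exceeds 1e7; refusing", call. = FALSE)
  set.seed(config$seed)
  bf <- config$background_fraction
  # uniform background component
  n_bg <- stats::rpois(1, bf * n_expected)
  xb <- stats::runif(n_bg, 0, b[1]); yb <- stats::runif(n_bg, 0, b[2])
  # Thomas cluster component
  xc <- yc <- numeric(0); cl <- integer(0)
  if (bf < 1) {
    n_par <- stats::rpois(1, config$parent_per_um2 * area_um2)
    if (n_par > 0) {
      mu <- (1 - bf) * config$density_per_um2 / config$parent_per_um2
      px <- stats::runif(n_par, 0, b[1]); py <- stats::runif(n_par, 0, b[2])
      n_off <- stats::rpois(n_par, mu)
      cl <- rep.int(seq_len(n_par), n_off)
      xc <- (px[cl] + stats::rnorm(length(cl), 0, config$sigma_c_nm)) %% b[1]
      yc <- (py[cl] + stats::rnorm(length(cl), 0, config$sigma_c_nm)) %% b[2]
    }
  }
  molecular_map(c(xb, xc), c(yb, yc), species = config$species, bounds = b,
                truth = c(integer(n_bg), cl))
}

#' Place vesicles with a bias towards low molecular density
#'
#' Vesicle centroids are placed by rejection sampling: uniform proposals are
#' accepted with probability `exp(-bias * d / d_mean)` where `d` is the
#' Gaussian kernel density estimate of the molecular pattern at the proposal
#' (bandwidth 100 nm, matching the 100 nm analysis grid) and `d_mean` the
#' global mean density. `bias = 0` reduces exactly to uniform placement.
#'
#' @param map a [molecular_map()].
#' @param n number of vesicles.
#' @param bias non-negative bias strength.
#' @param seed integer seed.
#' @param radius_nm physical vesicle radius in nm.
#' @param bandwidth_nm KDE bandwidth in nm.
#' @return a [vesicle_set()].
#' @export
place_vesicles <- function(map, n, bias = 2, seed, radius_nm = 200,
                           bandwidth_nm = 100) {
  stopifnot(n >= 0, bias >= 0)
  b <- map_bounds(map)
  packing_max <- floor(0.25 * prod(b) / (pi * radius_nm^2))
  if (n > packing_max)
    stop(sprintf("n = %d exceeds the packing limit (%d) for this domain",
                 n, packing_max), call. = FALSE)
  if (n == 0)
    return(vesicle_set(numeric(0), numeric(0), radius_nm = radius_nm,
                       bounds = b))
  set.seed(seed)
  pts <- map_coords(map)
  d_mean <- nrow(pts) / prod(b) # points per nm^2
  xs <- ys <- numeric(0)
  max_rounds <- 1000L
  for (round in seq_len(max_rounds)) {
    need <- n - length(xs)
    if (need == 0L) break
    m <- max(4L * need, 32L)
    qx <- stats::runif(m, 0, b[1]); qy <- stats::runif(m, 0, b[2])
    if (bias > 0 && nrow(pts) > 0 && d_mean > 0) {
      dens <- kde_density(pts, cbind(qx, qy), bandwidth_nm)
      w <- exp(-bias * dens / d_mean)
    } else {
      w <- rep(1, m)
    }
    keep <- stats::runif(m) < w
    xs <- c(xs, qx[keep])[seq_len(min(n, length(xs) + sum(keep)))]
    ys <- c(ys, qy[keep])[seq_len(length(xs))]
  }
  if (length(xs) < n)
    stop("rejection sampling failed to place the requested vesicles",
         call. = FALSE)
  vesicle_set(xs, ys, radius_nm = radius_nm, bounds = b)
}

#' Corrupt a ground-truth map with localization error and blinking
#'
#' Emulates SMLM acquisition: each ground-truth molecule is localized
#' `k >= 1` times (k - 1 ~ geometric, so `E[k] = blink_mean`; `k = 1` when
#' `blink_mean = 0`), each repetition displaced by isotropic Gaussian noise
#' whose sd is drawn uniformly from `sigma_range_nm`. GSDIM-style blinking
#' makes molecule counting ambiguous; the `truth` of each localization
#' records its source molecule index.
#'
#' @param map ground-truth [molecular_map()].
#' @param sigma_range_nm localization sd range `c(lo, hi)` in nm, within
#'   0-50 nm.
#' @param blink_mean mean localizations per molecule (geometric, min 1), or 0
#'   for exactly one localization per molecule.
#' @param seed integer seed.
#' @return a [molecular_map()] of localizations; its `truth` column is the
#'   row index of the source molecule in `map`.
#' @export
corrupt_localizations <- function(map, sigma_range_nm = c(4, 21),
                                  blink_mean = 0, seed) {
  sigma_range_nm <- rep_len(as.numeric(sigma_range_nm), 2L)
  if (any(sigma_range_nm < 0) || any(sigma_range_nm > 50))
    stop("sigma_range_nm must lie within [0, 50] nm", call. = FALSE)
  stopifnot(blink_mean == 0 || blink_mean >= 1)
  b <- map_bounds(map)
  n <- nrow(map)
  set.seed(seed)
  k <- if (blink_mean > 0) 1L + stats::rgeom(n, 1 / blink_mean)
       else rep(1L, n)
  src <- rep.int(seq_len(n), k)
  m <- length(src)
  sig <- stats::runif(m, sigma_range_nm[1], sigma_range_nm[2])
  x <- map$x_nm[src] + stats::rnorm(m, 0, sig)
  y <- map$y_nm[src] + stats::rnorm(m, 0, sig)
  # clamp to the domain so the map invariant holds (sub-nm effect at the rim)
  x <- pmin(pmax(x, 0), b[1])
  y <- pmin(pmax(y, 0), b[2])
  molecular_map(x, y, species = map$species[src], bounds = b, truth = src)
}
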