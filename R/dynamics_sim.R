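# Stochastic encounter simulation: Brownian tSNARE molecules and
# Ornstein-Uhlenbeck-tethered vesicles on a periodic domain, with
# per-vesicle occupancy counting within the interaction window.

#' Simulation configuration
#'
#' Parameters of the membrane encounter simulation. Molecules follow free
#' Brownian motion; vesicles follow a mean-reverting Ornstein-Uhlenbeck (OU)
#' process tethered to their initial ("morphologically docked") position.
#' Both are integrated with Euler-Maruyama on a periodic rectangle. No
#' interaction exists between any of the particles.
#'
#' Because the Brownian transition density is exactly Gaussian, the
#' molecular Euler-Maruyama step is exact at any step size; molecules are
#' therefore advanced one exact step per sample interval, while the OU
#' vesicles are integrated at `dt_fine_s`. A fine-step molecular path can be
#' requested for selected molecules via `store_fine`.
#'
#' @param domain_nm periodic domain size `c(width, height)` in nm.
#' @param dt_fine_s fine integration step (default 1e-5 s).
#' @param sample_interval_s observation interval (default 0.05 s, the 20 Hz
#'   sptPALM frame rate).
#' @param duration_s total simulated time (default 5 s, the maximum period a
#'   molecule is observed under sptPALM).
#' @param D_um2_s named diffusion coefficients per species (um^2/s).
#'   Defaults: SNAP-25 0.015, syntaxin 0.008 (calibrated stand-ins chosen so
#'   SNAP-25 is faster than syntaxin and 5-s maximum displacements stay
#'   below 1.6 um; see the methods vignette).
#' @param theta_s OU mean-reversion rate (1/s).
#' @param sigma_ou_nm OU noise intensity (nm/sqrt(s)); default gives a
#'   stationary positional sd of 50 nm per coordinate
#'   (`sigma_ou = sqrt(2 * theta) * 50`).
#' @param window_radius_nm occupancy window radius (default 82.5 nm).
#' @param seed mandatory integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(domain_nm = c(10000, 10000), dt_fine_s = 1e-5,
                       sample_interval_s = 0.05, duration_s = 5,
                       D_um2_s = c("SNAP-25" = 0.015, "syntaxin" = 0.008),
                       theta_s = 5, sigma_ou_nm = sqrt(2 * 5) * 50,
                       window_radius_nm = 82.5, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(dt_fine_s > 0, dt_fine_s <= sample_interval_s,
            sample_interval_s <= duration_s,
            all(D_um2_s >= 0), theta_s >= 0, sigma_ou_nm >= 0)
  structure(list(domain_nm = as.numeric(domain_nm), dt_fine_s = dt_fine_s,
                 sample_interval_s = sample_interval_s,
                 duration_s = duration_s, D_um2_s = D_um2_s,
                 theta_s = theta_s, sigma_ou_nm = sigma_ou_nm,
                 window_radius_nm = window_radius_nm,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# single Euler-Maruyama step of the tethered OU process (vectorized over
# particles); xi are standard normal draws
ou_step <- function(x, mu, theta, dt, sigma, xi) {
  x + theta * (mu - x) * dt + sigma * sqrt(dt) * xi
}

#' Run the Brownian / Ornstein-Uhlenbeck encounter simulation
#'
#' Integrates molecule and vesicle positions with Euler-Maruyama on a
#' periodic domain. Molecule update per coordinate:
#' `x <- x + sqrt(2 D dt) * xi` (exact for Brownian motion at any `dt`, so
#' molecules take one exact step per sample interval). Vesicle update:
#' `x <- x + theta * (mu - x) * dt + sigma_ou * sqrt(dt) * xi` at
#' `dt_fine_s`, with `mu` fixed at the vesicle's initial position.
#' Trajectories are stored unwrapped (so kinematics see true displacements);
#' periodic wrapping is applied when distances are measured in
#' [occupancy()]. Over the 5 s default the Brownian drift is far below half
#' the domain size, so the minimum-image convention remains exact.
#'
#' @param config a [sim_config()].
#' @param init_mols initial molecule positions, a [molecular_map()].
#' @param init_ves initial vesicle positions, a [vesicle_set()].
#' @param store_fine integer indices of molecules whose full fine-step path
#'   should be stored (these molecules are integrated at `dt_fine_s`).
#' @return object of class `sim_result`: list with `t_s` (sample times),
#'   `mol_x`, `mol_y` (matrices, molecules x samples), `species`,
#'   `ves_x`, `ves_y` (vesicles x samples), `fine` (list of fine-path data
#'   frames), `config`.
#' @export
simulate_dynamics <- function(config, init_mols, init_ves,
                              store_fine = integer(0)) {
  L <- config$domain_nm
  th <- config$theta_s; dtf <- config$dt_fine_s
  if (th > 0 && th * dtf >= 1)
    stop("theta * dt_fine >= 1: Euler-Maruyama unstable for the OU process",
         call. = FALSE)
  t_s <- seq(0, config$duration_s, by = config$sample_interval_s)
  ns <- length(t_s)
  set.seed(config$seed)

  # molecules: exact Brownian steps at the sample interval
  nm_ <- nrow(init_mols)
  sp <- init_mols$species
  D_nm2 <- unname(config$D_um2_s[sp]) * 1e6 # nm^2/s
  if (anyNA(D_nm2))
    stop("config$D_um2_s lacks a coefficient for some species", call. = FALSE)
  sig_step <- sqrt(2 * D_nm2 * config$sample_interval_s)
  mol_x <- matrix(0, nm_, ns); mol_y <- matrix(0, nm_, ns)
  if (nm_ > 0) {
    mol_x[, 1] <- init_mols$x_nm; mol_y[, 1] <- init_mols$y_nm
    for (k in seq_len(ns - 1L)) {
      mol_x[, k + 1L] <- mol_x[, k] + sig_step * stats::rnorm(nm_)
      mol_y[, k + 1L] <- mol_y[, k] + sig_step * stats::rnorm(nm_)
    }
  }

  # selected molecules re-integrated on the fine grid (replaces their
  # sampled path so the stored fine path and samples agree)
  fine <- list()
  n_sub <- round(config$sample_interval_s / dtf)
  for (i in store_fine) {
    sigf <- sqrt(2 * D_nm2[i] * dtf)
    n_tot <- n_sub * (ns - 1L)
    fx <- init_mols$x_nm[i] + cumsum(c(0, sigf * stats::rnorm(n_tot)))
    fy <- init_mols$y_nm[i] + cumsum(c(0, sigf * stats::rnorm(n_tot)))
    fine[[as.character(i)]] <- data.frame(
      t_s = seq(0, by = dtf, length.out = n_tot + 1L), x_nm = fx, y_nm = fy)
    at <- 1L + n_sub * (0:(ns - 1L))
    mol_x[i, ] <- fx[at]; mol_y[i, ] <- fy[at]
  }

  # vesicles: OU at the fine step, mean fixed at the initial position
  nv <- n_vesicles(init_ves)
  ves_x <- matrix(0, nv, ns); ves_y <- matrix(0, nv, ns)
  if (nv > 0) {
    mux <- init_ves$x_nm; muy <- init_ves$y_nm
    vx <- mux; vy <- muy
    ves_x[, 1] <- vx; ves_y[, 1] <- vy
    sig <- config$sigma_ou_nm
    for (k in seq_len(ns - 1L)) {
      for (s in seq_len(n_sub)) {
        vx <- ou_step(vx, mux, th, dtf, sig, stats::rnorm(nv))
        vy <- ou_step(vy, muy, th, dtf, sig, stats::rnorm(nv))
      }
      ves_x[, k + 1L] <- vx; ves_y[, k + 1L] <- vy
    }
  }

  structure(list(t_s = t_s, mol_x = mol_x, mol_y = mol_y, species = sp,
                 ves_x = ves_x, ves_y = ves_y, fine = fine, config = config),
            class = "sim_result")
}

#' Per-vesicle occupancy over time
#'
#' Counts, at every sample time, the molecules within `window_radius_nm` of
#' each vesicle centre, using minimum-image distances on the periodic
#' domain.
#'
#' @param sim a `sim_result` from [simulate_dynamics()].
#' @param window_radius_nm window radius; defaults to the simulation config.
#' @return object of class `occupancy_series`: list with `t_s` and `counts`
#'   (matrix, vesicles x samples).
#' @export
occupancy <- function(sim, window_radius_nm = NULL) {
  w <- window_radius_nm %||% sim$config$window_radius_nm
  L <- sim$config$domain_nm
  nv <- nrow(sim$ves_x); ns <- length(sim$t_s)
  counts <- matrix(0L, nv, ns)
  if (nv > 0 && nrow(sim$mol_x) > 0) {
    for (k in seq_len(ns)) {
      d <- cross_dist_periodic(cbind(sim$ves_x[, k] %% L[1],
                                     sim$ves_y[, k] %% L[2]),
                               cbind(sim$mol_x[, k] %% L[1],
                                     sim$mol_y[, k] %% L[2]), L)
      counts[, k] <- as.integer(rowSums(d <= w))
    }
  }
  structure(list(t_s = sim$t_s, counts = counts, window_radius_nm = w),
            class = "occupancy_series")
}

#' Occupancy frequency distributions and summaries
#'
#' Per-vesicle normalized frequency distribution of the instantaneous
#' occupancy, the cross-vesicle mean per count bin, and scalar summaries
#' over all (vesicle, time) samples.
#'
#' @param series an `occupancy_series` from [occupancy()].
#' @return list of class `occupancy_distribution`: `per_vesicle` (matrix,
#'   vesicles x count bins, rows sum to 1), `mean_freq` (cross-vesicle mean
#'   per bin), `counts_range` (bin labels), `median`, `max`, `mean`.
#' @export
occupancy_distribution <- function(series) {
  cts <- series$counts
  if (length(cts) == 0) stop("empty occupancy series", call. = FALSE)
  kmax <- max(cts)
  per <- t(apply(cts, 1, function(v) tabulate(v + 1L, nbins = kmax + 1L) /
                   length(v)))
  per <- matrix(per, nrow = nrow(cts))
  colnames(per) <- 0:kmax
  structure(list(per_vesicle = per, mean_freq = colMeans(per),
                 counts_range = 0:kmax,
                 median = stats::median(cts), max = max(cts),
                 mean = mean(cts)),
            class = "occupancy_distribution")
}

#' Subsample simulated molecules into photobleach-limited tracks
#'
#' Converts the sampled molecular trajectories into a [track_set()] as
#' observed under sptPALM: each molecule is followed from t = 0 until an
#' exponentially distributed photobleaching time (mean `bleach_mean_s`),
#' capped at the simulation duration. Tracks shorter than two samples are
#' dropped.
#'
#' @param sim a `sim_result`.
#' @param bleach_mean_s mean bleaching time in s (default 0.5); `Inf`
#'   disables bleaching.
#' @param seed integer seed for the bleaching times.
#' @return a [track_set()] (unwrapped coordinates, so step lengths and
#'   displacements are the physical ones).
#' @export
subsample_tracks <- function(sim, bleach_mean_s = 0.5, seed = 1) {
  ns <- length(sim$t_s)
  nm_ <- nrow(sim$mol_x)
  set.seed(seed)
  t_bleach <- if (is.finite(bleach_mean_s))
    stats::rexp(nm_, 1 / bleach_mean_s) else rep(Inf, nm_)
  rows <- vector("list", nm_)
  for (i in seq_len(nm_)) {
    keep <- which(sim$t_s <= min(t_bleach[i], sim$config$duration_s))
    if (length(keep) < 2) next
    rows[[i]] <- data.frame(track_id = i, frame = keep,
                            t_s = sim$t_s[keep],
                            x_nm = sim$mol_x[i, keep],
                            y_nm = sim$mol_y[i, keep])
  }
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(track_id = integer(0), frame = integer(0),
                     t_s = numeric(0), x_nm = numeric(0), y_nm = numeric(0))
  track_set(df, frame_interval_s = sim$config$sample_interval_s)
}

#' Recover OU parameters from sampled vesicle trajectories
#'
#' Fits the exact AR(1) form of the sampled OU process per coordinate:
#' `x_{k+1} - mu = a (x_k - mu) + e`, with `a = exp(-theta dt)` and
#' `Var(e) = sigma^2 (1 - a^2) / (2 theta)`; pooled across vesicles.
#'
#' @param sim a `sim_result` with at least one vesicle.
#' @return list with `theta_s` and `sigma_ou_nm` estimates.
#' @export
fit_ou <- function(sim) {
  nv <- nrow(sim$ves_x)
  stopifnot(nv >= 1)
  dt <- sim$config$sample_interval_s
  num <- den <- rss <- 0; n <- 0
  for (i in seq_len(nv)) {
    for (coord in list(sim$ves_x[i, ], sim$ves_y[i, ])) {
      z <- coord - mean(coord)
      z0 <- z[-length(z)]; z1 <- z[-1]
      num <- num + sum(z0 * z1); den <- den + sum(z0^2)
    }
  }
  a <- num / den
  if (a <= 0 || a >= 1) stop("AR(1) fit outside (0,1); run too short?",
                             call. = FALSE)
  theta <- -log(a) / dt
  for (i in seq_len(nv)) {
    for (coord in list(sim$ves_x[i, ], sim$ves_y[i, ])) {
      z <- coord - mean(coord)
      e <- z[-1] - a * z[-length(z)]
      rss <- rss + sum(e^2); n <- n + length(e)
    }
  }
  var_e <- rss / n
  sigma2 <- var_e * 2 * theta / (1 - a^2)
  list(theta_s = theta, sigma_ou_nm = sqrt(sigma2))
}
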