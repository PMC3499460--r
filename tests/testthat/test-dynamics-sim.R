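# Brownian / OU encounter simulation: diffusion laws, OU stationarity and
# recovery, occupancy counting, track subsampling, determinism and
# Euler-Maruyama convergence.

test_that("zero noise freezes all positions", {
  map <- molecular_map(c(1000, 2000), c(1000, 2000), bounds = c(5000, 5000))
  ves <- vesicle_set(3000, 3000, bounds = c(5000, 5000))
  cfg <- sim_config(domain_nm = c(5000, 5000), duration_s = 1,
                    D_um2_s = c("SNAP-25" = 0), theta_s = 5, sigma_ou_nm = 0,
                    dt_fine_s = 1e-3, seed = 1)
  sim <- simulate_dynamics(cfg, map, ves)
  expect_true(all(sim$mol_x == sim$mol_x[, 1]))
  expect_true(all(sim$ves_y == 3000))
})

test_that("molecular MSD follows 4 D t", {
  n <- 2000
  set.seed(71)
  map <- molecular_map(runif(n, 0, 10000), runif(n, 0, 10000),
                       bounds = c(10000, 10000))
  cfg <- sim_config(duration_s = 2, seed = 72)
  sim <- simulate_dynamics(cfg, map,
                           vesicle_set(numeric(0), numeric(0),
                                       bounds = c(10000, 10000)))
  D <- 0.015 * 1e6 # nm^2/s
  for (k in c(11, 21, 41)) { # t = 0.5, 1, 2 s
    t <- sim$t_s[k]
    r2 <- (sim$mol_x[, k] - sim$mol_x[, 1])^2 +
          (sim$mol_y[, k] - sim$mol_y[, 1])^2
    # r^2 ~ 2Dt * chisq_2, so sd(mean) = 4Dt / sqrt(n)
    expect_lt(abs(mean(r2) - 4 * D * t), 3 * 4 * D * t / sqrt(n))
  }
})

test_that("OU vesicles reach the stationary law and parameters are recoverable", {
  cfg <- sim_config(domain_nm = c(5000, 5000), dt_fine_s = 1e-3,
                    duration_s = 50, theta_s = 5, seed = 73)
  set.seed(74)
  ves <- vesicle_set(runif(50, 1000, 4000), runif(50, 1000, 4000),
                     bounds = c(5000, 5000))
  sim <- simulate_dynamics(cfg, molecular_map(numeric(0), numeric(0),
                                              bounds = c(5000, 5000)), ves)
  v <- mean(c(apply(sim$ves_x, 1, var), apply(sim$ves_y, 1, var)))
  expect_lt(abs(v - cfg$sigma_ou_nm^2 / (2 * 5)) /
            (cfg$sigma_ou_nm^2 / (2 * 5)), 0.05)
  fit <- fit_ou(sim)
  expect_lt(abs(fit$theta_s - 5) / 5, 0.1)
  expect_lt(abs(fit$sigma_ou_nm - cfg$sigma_ou_nm) / cfg$sigma_ou_nm, 0.1)
  # instability guard
  expect_error(simulate_dynamics(
    sim_config(dt_fine_s = 0.05, sample_interval_s = 0.05, theta_s = 30,
               seed = 1), molecular_map(numeric(0), numeric(0),
                                        bounds = c(5000, 5000)), ves),
    "unstable")
})

test_that("occupancy counting matches the minimum-image oracle", {
  # pinned molecule at a vesicle centre: count 1 at every sample
  map <- molecular_map(2000, 2000, bounds = c(4000, 4000))
  ves <- vesicle_set(2000, 2000, bounds = c(4000, 4000))
  cfg0 <- sim_config(domain_nm = c(4000, 4000), duration_s = 1,
                     D_um2_s = c("SNAP-25" = 0), sigma_ou_nm = 0,
                     dt_fine_s = 1e-3, seed = 2)
  expect_true(all(occupancy(simulate_dynamics(cfg0, map, ves))$counts == 1))
  # no molecules: all zero
  cfg0b <- cfg0; cfg0b$seed <- 3L
  sim0 <- simulate_dynamics(cfg0, molecular_map(numeric(0), numeric(0),
                                                bounds = c(4000, 4000)), ves)
  expect_true(all(occupancy(sim0)$counts == 0))
  # oracle on a small random instance (near-boundary molecules included)
  set.seed(75)
  mapr <- molecular_map(runif(60, 0, 4000), runif(60, 0, 4000),
                        bounds = c(4000, 4000))
  vesr <- vesicle_set(runif(5, 0, 4000), runif(5, 0, 4000),
                      bounds = c(4000, 4000))
  cfg <- sim_config(domain_nm = c(4000, 4000), duration_s = 1,
                    dt_fine_s = 1e-3, window_radius_nm = 300, seed = 76)
  sim <- simulate_dynamics(cfg, mapr, vesr)
  occ <- occupancy(sim)
  for (k in c(1, 11, 21)) {
    for (v in 1:5) {
      dx <- abs(sim$mol_x[, k] %% 4000 - sim$ves_x[v, k] %% 4000)
      dy <- abs(sim$mol_y[, k] %% 4000 - sim$ves_y[v, k] %% 4000)
      dx <- pmin(dx, 4000 - dx); dy <- pmin(dy, 4000 - dy)
      expect_equal(occ$counts[v, k], sum(sqrt(dx^2 + dy^2) <= 300))
    }
  }
})

test_that("occupancy at t = 0 agrees with the fixed-map counting route", {
  map <- generate_molecular_map(synthetic_config(seed = 77))
  ves <- place_vesicles(map, 15, bias = 2, seed = 78)
  # vesicle windows never overlap here, so nearest-assignment counting and
  # pure radius counting coincide
  d_vv <- as.matrix(dist(cbind(ves$x_nm, ves$y_nm)))
  diag(d_vv) <- Inf
  expect_gt(min(d_vv), 2 * 82.5)
  cfg <- sim_config(duration_s = 0.1, seed = 79)
  sim <- simulate_dynamics(cfg, map, ves)
  occ0 <- occupancy(sim)$counts[, 1]
  expect_equal(occ0, assign_and_count(map, ves)$counts)
})

test_that("occupancy distributions summarize counts correctly", {
  series <- structure(list(t_s = 0:4,
                           counts = matrix(3L, 2, 5),
                           window_radius_nm = 82.5),
                      class = "occupancy_series")
  d <- occupancy_distribution(series)
  expect_equal(d$median, 3)
  expect_equal(d$max, 3)
  expect_equal(unname(d$mean_freq[4]), 1)
  expect_true(all(abs(rowSums(d$per_vesicle) - 1) < 1e-12))
})

test_that("subsampled tracks honor bleaching and the Rayleigh step law", {
  map <- molecular_map(runif(1000, 0, 10000), runif(1000, 0, 10000),
                       bounds = c(10000, 10000))
  cfg <- sim_config(duration_s = 2, seed = 81)
  sim <- simulate_dynamics(cfg, map,
                           vesicle_set(numeric(0), numeric(0),
                                       bounds = c(10000, 10000)))
  # no bleaching: every track spans the full duration
  full <- subsample_tracks(sim, bleach_mean_s = Inf, seed = 82)
  expect_true(all(table(full$points$track_id) == 41))
  # mean track duration ~ bleach mean when bleach << duration
  short <- subsample_tracks(sim, bleach_mean_s = 0.25, seed = 83)
  durations <- tapply(short$points$t_s, short$points$track_id, max)
  expect_lt(abs(mean(durations) - 0.25), 0.25 * 0.15)
  # mean step speed matches the Rayleigh law sqrt(pi D / dt) within 5%
  kin <- track_kinematics(full)
  expect_lt(abs(kin$speed_mean - sqrt(pi * 0.015 / 0.05)) /
            sqrt(pi * 0.015 / 0.05), 0.05)
})

test_that("simulation is deterministic under a fixed seed", {
  map <- molecular_map(runif(50, 0, 4000), runif(50, 0, 4000),
                       bounds = c(4000, 4000))
  ves <- vesicle_set(runif(4, 0, 4000), runif(4, 0, 4000),
                     bounds = c(4000, 4000))
  cfg <- sim_config(domain_nm = c(4000, 4000), duration_s = 1,
                    dt_fine_s = 1e-3, seed = 84)
  s1 <- simulate_dynamics(cfg, map, ves, store_fine = 1L)
  s2 <- simulate_dynamics(cfg, map, ves, store_fine = 1L)
  expect_identical(s1, s2)
  # the stored fine path agrees with the sampled path at sample times
  at <- 1L + 50L * (0:(length(s1$t_s) - 1L))
  expect_equal(s1$fine[["1"]]$x_nm[at], s1$mol_x[1, ])
})

test_that("halving the fine step leaves occupancy statistics unchanged", {
  # common-random-number Euler-Maruyama refinement: the coarse step uses the
  # summed increments of the two fine half-steps
  map <- generate_molecular_map(synthetic_config(bounds_nm = c(8000, 8000),
                                                 density_per_um2 = 40,
                                                 seed = 85))
  ves <- place_vesicles(map, 30, bias = 2, seed = 86)
  cfg <- sim_config(domain_nm = c(8000, 8000), duration_s = 5,
                    dt_fine_s = 2e-4, seed = 87)
  sim <- simulate_dynamics(cfg, map, ves)
  nv <- length(ves$x_nm); ns <- length(sim$t_s)
  dtc <- 2e-4; dtf <- 1e-4
  th <- 5; sig <- cfg$sigma_ou_nm
  set.seed(88)
  vx_c <- vx_f <- ves$x_nm; vy_c <- vy_f <- ves$y_nm
  ves_x_c <- ves_x_f <- matrix(0, nv, ns)
  ves_y_c <- ves_y_f <- matrix(0, nv, ns)
  ves_x_c[, 1] <- ves_x_f[, 1] <- ves$x_nm
  ves_y_c[, 1] <- ves_y_f[, 1] <- ves$y_nm
  for (k in seq_len(ns - 1)) {
    for (s in seq_len(round(0.05 / dtc))) {
      x1 <- rnorm(nv); x2 <- rnorm(nv)
      y1 <- rnorm(nv); y2 <- rnorm(nv)
      vx_f <- snarescape:::ou_step(vx_f, ves$x_nm, th, dtf, sig, x1)
      vx_f <- snarescape:::ou_step(vx_f, ves$x_nm, th, dtf, sig, x2)
      vy_f <- snarescape:::ou_step(vy_f, ves$y_nm, th, dtf, sig, y1)
      vy_f <- snarescape:::ou_step(vy_f, ves$y_nm, th, dtf, sig, y2)
      vx_c <- snarescape:::ou_step(vx_c, ves$x_nm, th, dtc, sig,
                                   (x1 + x2) / sqrt(2))
      vy_c <- snarescape:::ou_step(vy_c, ves$y_nm, th, dtc, sig,
                                   (y1 + y2) / sqrt(2))
    }
    ves_x_c[, k + 1] <- vx_c; ves_x_f[, k + 1] <- vx_f
    ves_y_c[, k + 1] <- vy_c; ves_y_f[, k + 1] <- vy_f
  }
  sim_c <- sim; sim_c$ves_x <- ves_x_c; sim_c$ves_y <- ves_y_c
  sim_f <- sim; sim_f$ves_x <- ves_x_f; sim_f$ves_y <- ves_y_f
  oc <- occupancy_distribution(occupancy(sim_c))
  of <- occupancy_distribution(occupancy(sim_f))
  expect_lt(abs(oc$mean - of$mean) / max(of$mean, 1e-12), 0.01)
  expect_equal(oc$median, of$median)
  expect_equal(oc$max, of$max)
})
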