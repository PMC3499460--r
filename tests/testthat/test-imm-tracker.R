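# IMM filter behavior, gating, optimal assignment, track building and
# fusion-event detection.

det_row <- function(x, y, intensity = 100, area = 9)
  data.frame(x_nm = x, y_nm = y, intensity = intensity, area_px = area)

test_that("IMM prediction reduces to the expected Kalman limits", {
  # RW-only bank: prediction = last position, covariance grown by Q
  bank_rw <- motion_model_bank(transition = diag(3), init_prob = c(1, 0, 0))
  h <- new_hypothesis(det_row(1000, 2000), bank_rw, 1, meas_sigma_nm = 10)
  pr <- imm_predict(h, bank_rw, 0.05)
  expect_equal(pr$z_mix, c(1000, 2000))
  q <- 2 * bank_rw$D_rw_nm2_s * 0.05
  expect_equal(pr$S_mix[1, 1], 100 + q + 100, tolerance = 1e-6)
  # FO model with velocity v: predicted displacement = v dt
  bank_fo <- motion_model_bank(transition = diag(3), init_prob = c(0, 1, 0))
  h2 <- new_hypothesis(det_row(0, 0), bank_fo, 1)
  h2$x <- lapply(h2$x, function(x) { x[2] <- 800; x[5] <- -400; x })
  pr2 <- imm_predict(h2, bank_fo, 0.1)
  expect_equal(pr2$z_mix, c(80, -40), tolerance = 1e-9)
  # uniform probabilities over identical states: mix = mean of predictions
  bank_u <- motion_model_bank(transition = matrix(1 / 3, 3, 3))
  h3 <- new_hypothesis(det_row(500, 500), bank_u, 1)
  h3$x <- lapply(h3$x, function(x) { x[2] <- 300; x[5] <- 300; x })
  pr3 <- imm_predict(h3, bank_u, 0.1)
  per_model <- do.call(rbind, pr3$z)
  expect_equal(pr3$z_mix, colMeans(per_model), tolerance = 1e-9)
})

test_that("association cost is zero at the prediction, monotone, and gated", {
  bank <- motion_model_bank()
  h <- new_hypothesis(det_row(1000, 1000), bank, 1)
  pr <- imm_predict(h, bank, 0.05)
  topo <- list(intensity = 100, area = 9)
  expect_equal(association_cost(pr, det_row(pr$z_mix[1], pr$z_mix[2]), topo), 0)
  # monotone along a ray
  costs <- vapply(c(5, 10, 20, 40), function(r)
    association_cost(pr, det_row(pr$z_mix[1] + r, pr$z_mix[2]), topo),
    numeric(1))
  expect_true(all(diff(costs) > 0))
  # beyond the 99% chi-square gate: excluded
  gate <- qchisq(0.99, 2)
  r_out <- sqrt(gate * pr$S_mix[1, 1]) * 1.01
  expect_identical(association_cost(pr, det_row(pr$z_mix[1] + r_out,
                                                pr$z_mix[2]), topo), Inf)
  r_in <- sqrt(gate * pr$S_mix[1, 1]) * 0.99
  expect_true(is.finite(association_cost(pr, det_row(pr$z_mix[1] + r_in,
                                                     pr$z_mix[2]), topo)))
})

test_that("assignment solver matches the exhaustive permutation minimum", {
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    C <- matrix(runif(n * n, 0, 10), n, n)
    sol <- solve_assignment(C)
    got <- sum(C[cbind(seq_len(n), sol)])
    perms <- function(v) if (length(v) == 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    best <- min(vapply(perms(seq_len(n)), function(p)
      sum(C[cbind(seq_len(n), p)]), numeric(1)))
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("frame correspondence is optimal including births and misses", {
  bank <- motion_model_bank()
  hs <- lapply(1:3, function(i)
    new_hypothesis(det_row(i * 1000, 1000), bank, i))
  preds <- lapply(hs, imm_predict, bank = bank, dt_s = 0.05)
  topos <- lapply(hs, `[[`, "topology")
  # simple case: nearest pairing recovered
  dets <- det_row(c(1010, 2020, 2990), c(995, 1000, 1005))
  cor <- correspond_frame(preds, topos, dets)
  expect_equal(cor$assign, 1:3)
  expect_length(cor$births, 0)
  # oracle comparison over random scenarios with births and misses
  set.seed(5)
  for (rep in 1:8) {
    m <- sample(1:4, 1)
    dets <- det_row(runif(m, 500, 3500), runif(m, 800, 1200),
                    intensity = runif(m, 50, 200), area = runif(m, 5, 15))
    cor <- correspond_frame(preds, topos, dets)
    uc <- qchisq(0.99, 2)
    C <- matrix(NA_real_, 3, m)
    for (i in 1:3) for (j in 1:m)
      C[i, j] <- association_cost(preds[[i]], dets[j, , drop = FALSE],
                                  topos[[i]])
    total <- cor$total_cost +
      uc * (sum(is.na(cor$assign)) + length(cor$births))
    expect_equal(total, brute_force_assignment(C, uc), tolerance = 1e-9)
  }
})

test_that("topology terms preserve identity through a crossing", {
  # two particles crossing with 5x different intensities
  n <- 21
  xa <- seq(1000, 3000, length.out = n); ya <- rep(1000, n)
  xb <- seq(3000, 1000, length.out = n); yb <- rep(1000, n)
  set.seed(2)
  parts <- do.call(rbind, lapply(seq_len(n), function(f) rbind(
    data.frame(frame = f, x_nm = xa[f] + rnorm(1, 0, 5),
               y_nm = ya[f] + rnorm(1, 0, 5), intensity = 500, area_px = 9),
    data.frame(frame = f, x_nm = xb[f] + rnorm(1, 0, 5),
               y_nm = yb[f] + rnorm(1, 0, 5), intensity = 2500, area_px = 9))))
  ts <- build_tracks(parts, meas_sigma_nm = 10)
  expect_equal(n_tracks(ts), 2)
  p <- ts$points
  for (id in unique(p$track_id)) {
    tr <- p[p$track_id == id, ]
    expect_equal(nrow(tr), n)
    # a track keeps one intensity class throughout the crossing
    expect_equal(length(unique(tr$intensity)), 1)
  }
})

test_that("IMM update honors Kalman limits and keeps valid probabilities", {
  bank <- motion_model_bank()
  # near-zero measurement noise: posterior position = measurement
  h <- new_hypothesis(det_row(1000, 1000), bank, 1, meas_sigma_nm = 1e-4)
  pr <- imm_predict(h, bank, 0.05)
  up <- imm_update(h, pr, det_row(1030, 980))
  st <- snarescape:::hypothesis_state(up)
  expect_equal(st[1], 1030, tolerance = 1e-4)
  expect_equal(st[4], 980, tolerance = 1e-4)
  # model probabilities stay a distribution along trajectories
  set.seed(9)
  h2 <- new_hypothesis(det_row(0, 0), bank, 1)
  x <- 0
  for (k in 1:30) {
    pr2 <- imm_predict(h2, bank, 0.05)
    x <- x + 100
    h2 <- imm_update(h2, pr2, det_row(x + rnorm(1, 0, 10), rnorm(1, 0, 10)))
    expect_equal(sum(h2$mu), 1, tolerance = 1e-9)
    expect_true(all(h2$mu >= 0))
  }
})

test_that("model probabilities identify the underlying motion", {
  bank <- motion_model_bank()
  run_traj <- function(xy) {
    h <- new_hypothesis(det_row(xy[1, 1], xy[1, 2]), bank, 1)
    for (k in 2:nrow(xy)) {
      pr <- imm_predict(h, bank, 0.05)
      h <- imm_update(h, pr, det_row(xy[k, 1], xy[k, 2]))
    }
    h$mu
  }
  set.seed(3)
  n <- 60
  cv <- cbind(1000 + (1:n) * 100 + rnorm(n, 0, 10), 1000 + rnorm(n, 0, 10))
  mu_cv <- run_traj(cv)
  expect_gt(mu_cv[2], mu_cv[1])
  expect_gt(mu_cv[2], mu_cv[3])
  stat <- cbind(1000 + rnorm(n, 0, 25), 1000 + rnorm(n, 0, 25))
  mu_st <- run_traj(stat)
  expect_gt(mu_st[1], mu_st[2])
  expect_gt(mu_st[1], mu_st[3])
})

test_that("build_tracks handles simple and empty inputs deterministically", {
  # one noiseless particle over 100 frames -> one track of length 100
  parts <- data.frame(frame = 1:100, x_nm = 2000, y_nm = 3000,
                      intensity = 100, area_px = 9)
  ts <- build_tracks(parts)
  expect_equal(n_tracks(ts), 1)
  expect_equal(nrow(ts$points), 100)
  # empty input -> empty track set
  empty <- build_tracks(parts[0, ])
  expect_equal(n_tracks(empty), 0)
  # determinism
  set.seed(1)
  parts2 <- data.frame(frame = rep(1:20, each = 3),
                       x_nm = runif(60, 0, 5000), y_nm = runif(60, 0, 5000),
                       intensity = runif(60, 50, 500), area_px = 9)
  expect_identical(build_tracks(parts2)$points, build_tracks(parts2)$points)
})

test_that("link recovery is high on noisy Brownian detections and falls with density", {
  make_dets <- function(n_particles, seed) {
    truth <- brownian_truth(n_particles, 40, fov_nm = c(10000, 10000),
                            seed = seed, min_sep_nm = 600)
    set.seed(seed + 1)
    p <- truth$points
    data.frame(frame = p$frame, x_nm = p$x_nm + rnorm(nrow(p), 0, 15),
               y_nm = p$y_nm + rnorm(nrow(p), 0, 15),
               intensity = 100, area_px = 9, truth_id = p$track_id)
  }
  recover <- function(dets) {
    ts <- build_tracks(dets[, 1:5], meas_sigma_nm = 15)
    tp <- ts$points
    good <- 0L; tot <- 0L
    for (id in unique(dets$truth_id)) {
      sub <- dets[dets$truth_id == id, ]
      for (i in seq_len(nrow(sub) - 1)) {
        tot <- tot + 1L
        t1 <- tp$track_id[tp$frame == sub$frame[i] &
                          abs(tp$x_nm - sub$x_nm[i]) < 1e-9]
        t2 <- tp$track_id[tp$frame == sub$frame[i + 1] &
                          abs(tp$x_nm - sub$x_nm[i + 1]) < 1e-9]
        if (length(t1) == 1 && length(t2) == 1 && t1 == t2) good <- good + 1L
      }
    }
    good / tot
  }
  r_sparse <- recover(make_dets(10, seed = 41))
  expect_gte(r_sparse, 0.9)
  r_dense <- recover(make_dets(60, seed = 41))
  expect_lte(r_dense, r_sparse)
})

test_that("degenerate single-model tracker equals a nearest-neighbor Kalman filter", {
  bank_rw <- motion_model_bank(transition = diag(3), init_prob = c(1, 0, 0))
  set.seed(14)
  truth <- brownian_truth(5, 25, fov_nm = c(8000, 8000), seed = 15,
                          min_sep_nm = 1500)
  p <- truth$points
  dets <- data.frame(frame = p$frame, x_nm = p$x_nm + rnorm(nrow(p), 0, 10),
                     y_nm = p$y_nm + rnorm(nrow(p), 0, 10))
  ts <- build_tracks(dets, bank = bank_rw, meas_sigma_nm = 10,
                     w_I = 0, w_A = 0)
  # oracle: plain per-frame nearest-neighbor Kalman (RW) tracker
  nn_tracks <- local({
    R <- 100; q <- 2 * bank_rw$D_rw_nm2_s * 0.05
    st <- NULL # per track: x, y, P
    lab <- rep(NA_integer_, nrow(dets))
    nxt <- 1L
    for (f in sort(unique(dets$frame))) {
      idx <- which(dets$frame == f)
      if (is.null(st)) {
        st <- lapply(idx, function(i)
          list(x = dets$x_nm[i], y = dets$y_nm[i], P = R, id = {
            id <- nxt; nxt <<- nxt + 1L; id }))
        lab[idx] <- vapply(st, `[[`, integer(1), "id")
        next
      }
      for (s in seq_along(st)) st[[s]]$P <- st[[s]]$P + q
      # greedy NN is optimal here because tracks are far apart
      free <- idx
      for (s in seq_along(st)) {
        d <- sqrt((dets$x_nm[free] - st[[s]]$x)^2 +
                  (dets$y_nm[free] - st[[s]]$y)^2)
        j <- free[which.min(d)]
        K <- st[[s]]$P / (st[[s]]$P + R)
        st[[s]]$x <- st[[s]]$x + K * (dets$x_nm[j] - st[[s]]$x)
        st[[s]]$y <- st[[s]]$y + K * (dets$y_nm[j] - st[[s]]$y)
        st[[s]]$P <- (1 - K) * st[[s]]$P
        lab[j] <- st[[s]]$id
        free <- setdiff(free, j)
      }
    }
    lab
  })
  # same partition of detections into tracks
  tp <- ts$points
  imm_lab <- rep(NA_integer_, nrow(dets))
  for (k in seq_len(nrow(tp))) {
    i <- which(dets$frame == tp$frame[k] & abs(dets$x_nm - tp$x_nm[k]) < 1e-9)
    imm_lab[i] <- tp$track_id[k]
  }
  expect_false(any(is.na(imm_lab)))
  expect_equal(length(unique(paste(imm_lab, nn_tracks))),
               length(unique(imm_lab)))
})

test_that("fusion events are detected at the right frame and ramps rejected", {
  # flat trace: no events
  set.seed(6)
  flat <- matrix(100 + rnorm(300, 0, 3), 1)
  ves_flat <- vesicle_set(500, 500, bounds = c(1000, 1000), traces = flat,
                          frame_interval_s = 0.05)
  expect_equal(nrow(detect_fusion_events(ves_flat)$events), 0)
  # generated fusion trace, spike SNR 10: event at the true frame +/- 1
  tr <- simulate_fusion_trace(baseline = 100, spike_amplitude = 10 * 4,
                              decay_tau_s = 0.5, fusion_time_s = 2.5,
                              noise_sigma = 4, duration_s = 5, dt_s = 0.05,
                              seed = 8)
  ves <- vesicle_set(500, 500, bounds = c(1000, 1000),
                     traces = matrix(tr, 1), frame_interval_s = 0.05)
  ev <- detect_fusion_events(ves)$events
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$frame - attr(tr, "fusion_frame")), 1)
  expect_equal(ev$tau_s, 0.5, tolerance = 0.25)
  # monotone ramp without decay: rejected by the decay-fit criterion
  ramp <- matrix(c(rep(100, 50), seq(100, 400, length.out = 50)), 1)
  ves_r <- vesicle_set(500, 500, bounds = c(1000, 1000), traces = ramp,
                       frame_interval_s = 0.05)
  expect_equal(nrow(detect_fusion_events(ves_r)$events), 0)
})
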