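# Frame-to-frame correspondence with an Interacting Multiple Model (IMM)
# filter: a bank of three Kalman motion models (random walk, first-order and
# second-order linear extrapolation) with Markov switching, chi-square
# gating, topology-aware association costs, and an exact optimal one-to-one
# assignment per frame.
#
# State vector (per hypothesis, per model): (x, vx, ax, y, vy, ay) in nm,
# nm/s, nm/s^2. All models live in this common 6-dim space; the smaller
# models zero out the components they do not use.

#' Motion model bank
#'
#' Three linear state-space models: `RW` (position random walk, process
#' noise matched to a diffusion coefficient), `FO` (constant velocity with
#' white acceleration) and `SO` (constant acceleration with white jerk),
#' plus the Markov model-transition matrix and initial model probabilities.
#'
#' @param D_rw_um2_s random-walk diffusion coefficient (um^2/s); its
#'   per-step positional variance is `2 D dt`.
#' @param q_fo white-acceleration intensity of the FO model (nm^2/s^3).
#' @param q_so white-jerk intensity of the SO model (nm^2/s^5).
#' @param transition 3x3 Markov matrix (rows sum to 1); default 0.8
#'   self-transition, 0.1 cross.
#' @param init_prob initial model probabilities (default uniform).
#' @return a list of class `motion_model_bank`.
#' @export
motion_model_bank <- function(D_rw_um2_s = 0.015, q_fo = 4e7, q_so = 1e11,
                              transition = NULL, init_prob = rep(1, 3) / 3) {
  transition <- transition %||%
    matrix(c(0.8, 0.1, 0.1, 0.1, 0.8, 0.1, 0.1, 0.1, 0.8), 3, 3, byrow = TRUE)
  stopifnot(nrow(transition) == 3, ncol(transition) == 3,
            all(abs(rowSums(transition) - 1) < 1e-9),
            all(transition >= 0), length(init_prob) == 3,
            abs(sum(init_prob) - 1) < 1e-9,
            D_rw_um2_s > 0, q_fo > 0, q_so > 0)
  structure(list(D_rw_nm2_s = D_rw_um2_s * 1e6, q_fo = q_fo, q_so = q_so,
                 transition = transition, init_prob = init_prob,
                 names = c("RW", "FO", "SO")),
            class = "motion_model_bank")
}

blkdiag2 <- function(A) {
  n <- nrow(A)
  M <- matrix(0, 2 * n, 2 * n)
  M[1:n, 1:n] <- A
  M[(n + 1):(2 * n), (n + 1):(2 * n)] <- A
  M
}

# per-model transition and process-noise matrices for a time step dt
model_matrices <- function(bank, dt, model) {
  eps <- 1e-9
  if (model == 1L) { # RW
    F3 <- diag(c(1, 0, 0))
    Q3 <- diag(c(2 * bank$D_rw_nm2_s * dt, eps, eps))
  } else if (model == 2L) { # FO
    F3 <- matrix(c(1, dt, 0, 0, 1, 0, 0, 0, 0), 3, 3, byrow = TRUE)
    Q3 <- bank$q_fo * matrix(c(dt^3 / 3, dt^2 / 2, 0,
                               dt^2 / 2, dt, 0,
                               0, 0, 0), 3, 3, byrow = TRUE) + diag(eps, 3)
  } else { # SO
    F3 <- matrix(c(1, dt, dt^2 / 2, 0, 1, dt, 0, 0, 1), 3, 3, byrow = TRUE)
    Q3 <- bank$q_so * matrix(c(dt^5 / 20, dt^4 / 8, dt^3 / 6,
                               dt^4 / 8, dt^3 / 3, dt^2 / 2,
                               dt^3 / 6, dt^2 / 2, dt), 3, 3, byrow = TRUE) +
      diag(eps, 3)
  }
  list(F = blkdiag2(F3), Q = blkdiag2(Q3))
}

H_MEAS <- local({
  H <- matrix(0, 2, 6)
  H[1, 1] <- 1; H[2, 4] <- 1
  H
})

# symmetrize and verify positive semi-definiteness (numerical guard)
ensure_psd <- function(P, label = "covariance") {
  P <- (P + t(P)) / 2
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6 * max(abs(ev), 1)) {
    P <- P + diag(2 * abs(min(ev)), nrow(P)) # symmetrization retry
    ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-6 * max(abs(ev), 1))
      stop(label, " is not positive semi-definite", call. = FALSE)
  }
  P
}

#' Start a new track hypothesis from a detection
#'
#' @param particle one-row particle data (list or data frame row with
#'   `x_nm`, `y_nm`, optionally `intensity`, `area_px`).
#' @param bank a [motion_model_bank()].
#' @param id track id.
#' @param meas_sigma_nm measurement noise sd (localization precision).
#' @param init_vel_sd velocity prior sd (nm/s).
#' @param init_acc_sd acceleration prior sd (nm/s^2).
#' @return a list of class `track_hypothesis`.
#' @export
new_hypothesis <- function(particle, bank, id, meas_sigma_nm = 20,
                           init_vel_sd = 2000, init_acc_sd = 2e4) {
  x0 <- c(particle$x_nm, 0, 0, particle$y_nm, 0, 0)
  P0 <- diag(c(meas_sigma_nm^2, init_vel_sd^2, init_acc_sd^2)[c(1, 2, 3)])
  P0 <- blkdiag2(P0)
  structure(list(id = id,
                 x = replicate(3, x0, simplify = FALSE),
                 P = replicate(3, P0, simplify = FALSE),
                 mu = bank$init_prob,
                 topology = list(intensity = particle$intensity %||% NA_real_,
                                 area = particle$area_px %||% NA_real_),
                 meas_var = meas_sigma_nm^2,
                 miss = 0L),
            class = "track_hypothesis")
}

#' IMM mixing and prediction
#'
#' Standard IMM step: mix the per-model states with the Markov transition
#' matrix, propagate each model through its own dynamics, and form the
#' probability-weighted mixed measurement prediction used for gating and
#' association.
#'
#' @param h a `track_hypothesis`.
#' @param bank a [motion_model_bank()].
#' @param dt_s prediction interval (> 0).
#' @return a list of class `imm_prediction`: per-model predicted states
#'   (`x`, `P`), predicted measurement means `z` and covariances `S`, mixed
#'   measurement mean `z_mix` and covariance `S_mix`, predicted model
#'   probabilities `c_j`.
#' @export
imm_predict <- function(h, bank, dt_s) {
  stopifnot(dt_s > 0)
  Pt <- bank$transition
  c_j <- as.numeric(t(Pt) %*% h$mu)
  c_j <- pmax(c_j, 1e-300)
  R <- diag(h$meas_var, 2)
  xs <- Ps <- Ss <- zs <- vector("list", 3)
  for (j in 1:3) {
    w <- Pt[, j] * h$mu / c_j[j]
    x0 <- Reduce(`+`, Map(`*`, h$x, w))
    P0 <- matrix(0, 6, 6)
    for (i in 1:3) {
      dxi <- h$x[[i]] - x0
      P0 <- P0 + w[i] * (h$P[[i]] + dxi %*% t(dxi))
    }
    mm <- model_matrices(bank, dt_s, j)
    xs[[j]] <- as.numeric(mm$F %*% x0)
    Ps[[j]] <- ensure_psd(mm$F %*% P0 %*% t(mm$F) + mm$Q)
    zs[[j]] <- as.numeric(H_MEAS %*% xs[[j]])
    Ss[[j]] <- H_MEAS %*% Ps[[j]] %*% t(H_MEAS) + R
  }
  cn <- c_j / sum(c_j)
  z_mix <- Reduce(`+`, Map(`*`, zs, cn))
  S_mix <- matrix(0, 2, 2)
  for (j in 1:3) {
    dz <- zs[[j]] - z_mix
    S_mix <- S_mix + cn[j] * (Ss[[j]] + dz %*% t(dz))
  }
  structure(list(x = xs, P = Ps, z = zs, S = Ss, c_j = cn,
                 z_mix = z_mix, S_mix = ensure_psd(S_mix, "S_mix"),
                 dt_s = dt_s),
            class = "imm_prediction")
}

#' Association cost between a prediction and a detection
#'
#' Squared Mahalanobis innovation distance of the detection position under
#' the mixed prediction, plus topology terms
#' `w_I * |delta log intensity| + w_A * |delta log area|`. Detections whose
#' positional distance exceeds the chi-square gate (2 df) are gated out
#' (`Inf`).
#'
#' @param pred an `imm_prediction`.
#' @param particle detection row (`x_nm`, `y_nm`, optionally `intensity`,
#'   `area_px`).
#' @param topology the tracked hypothesis' last topology (list with
#'   `intensity`, `area`), or `NULL` to skip topology terms.
#' @param w_I,w_A topology weights (log scale).
#' @param gate_p chi-square gate probability.
#' @return non-negative scalar, `Inf` if gated out.
#' @export
association_cost <- function(pred, particle, topology = NULL,
                             w_I = 1, w_A = 1, gate_p = 0.99) {
  v <- c(particle$x_nm, particle$y_nm) - pred$z_mix
  d2 <- as.numeric(t(v) %*% solve(pred$S_mix, v))
  if (d2 > stats::qchisq(gate_p, df = 2)) return(Inf)
  cost <- d2
  if (!is.null(topology)) {
    ti <- topology$intensity; pi_ <- particle$intensity %||% NA_real_
    if (isTRUE(is.finite(ti) && is.finite(pi_) && ti > 0 && pi_ > 0))
      cost <- cost + w_I * abs(log(pi_) - log(ti))
    ta <- topology$area; pa <- particle$area_px %||% NA_real_
    if (isTRUE(is.finite(ta) && is.finite(pa) && ta > 0 && pa > 0))
      cost <- cost + w_A * abs(log(pa) - log(ta))
  }
  cost
}

#' Exact solver for the linear assignment problem
#'
#' Jonker-Volgenant style shortest-augmenting-path algorithm on a square
#' cost matrix; returns, per row, the assigned column of a minimum-total-cost
#' perfect matching.
#'
#' @param cost square numeric matrix (finite entries).
#' @return integer vector: `result[i]` is the column assigned to row `i`.
#' @export
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  if (n == 0) return(integer(0))
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1L
    minv <- rep(INF, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  out <- integer(n)
  for (j in seq_len(n)) out[p[j]] <- j
  out
}

#' Optimal frame correspondence
#'
#' One-to-one assignment between predicted tracks and detections minimizing
#' the total association cost over gated pairs; leaving a track or a
#' detection unassigned costs `unassign_cost` each. Solved exactly on an
#' augmented square matrix.
#'
#' @param preds list of `imm_prediction`s, one per active track.
#' @param topologies list of track topologies (parallel to `preds`).
#' @param detections a `particle_table` (or data frame of detections).
#' @param w_I,w_A,gate_p cost parameters, see [association_cost()].
#' @param unassign_cost cost of an unassigned track or detection; default
#'   the chi-square 99% gate value.
#' @return list with `assign` (per track: detection index or `NA`), `births`
#'   (unassigned detection indices), `total_cost` (sum over assigned pairs).
#' @export
correspond_frame <- function(preds, topologies, detections,
                             w_I = 1, w_A = 1, gate_p = 0.99,
                             unassign_cost = stats::qchisq(0.99, 2)) {
  n <- length(preds); m <- nrow(detections)
  if (n == 0 && m == 0)
    return(list(assign = integer(0), births = integer(0), total_cost = 0))
  BIG <- 1e12
  C <- matrix(BIG, n + m, n + m)
  if (n > 0 && m > 0) {
    for (i in seq_len(n)) for (j in seq_len(m)) {
      cst <- association_cost(preds[[i]], detections[j, , drop = FALSE],
                              topologies[[i]], w_I, w_A, gate_p)
      C[i, j] <- if (is.finite(cst)) cst else BIG
    }
  }
  if (n > 0) for (i in seq_len(n)) C[i, m + i] <- unassign_cost
  if (m > 0) for (j in seq_len(m)) C[n + j, j] <- unassign_cost
  if (n > 0 && m > 0) C[(n + 1):(n + m), (m + 1):(m + n)] <- 0
  sol <- solve_assignment(C)
  assign <- rep(NA_integer_, n)
  total <- 0
  for (i in seq_len(n)) {
    j <- sol[i]
    if (j <= m && C[i, j] < BIG / 2) {
      assign[i] <- j
      total <- total + C[i, j]
    }
  }
  births <- setdiff(seq_len(m), assign[!is.na(assign)])
  list(assign = assign, births = births, total_cost = total)
}

#' IMM measurement update
#'
#' Per-model Kalman update of a predicted hypothesis with a gated detection;
#' model probabilities are re-weighted by the per-model Gaussian innovation
#' likelihoods and renormalized. Topology fields are refreshed from the
#' detection.
#'
#' @param h the `track_hypothesis` that was predicted.
#' @param pred the matching `imm_prediction`.
#' @param particle the associated detection row.
#' @return the updated `track_hypothesis`.
#' @export
imm_update <- function(h, pred, particle) {
  z <- c(particle$x_nm, particle$y_nm)
  lik <- numeric(3)
  for (j in 1:3) {
    v <- z - pred$z[[j]]
    S <- pred$S[[j]]
    Sinv <- solve(S)
    K <- pred$P[[j]] %*% t(H_MEAS) %*% Sinv
    h$x[[j]] <- pred$x[[j]] + as.numeric(K %*% v)
    h$P[[j]] <- ensure_psd((diag(6) - K %*% H_MEAS) %*% pred$P[[j]])
    d2 <- as.numeric(t(v) %*% Sinv %*% v)
    lik[j] <- exp(-d2 / 2) / (2 * pi * sqrt(det(S)))
  }
  mu <- pred$c_j * lik
  if (sum(mu) <= 0 || !all(is.finite(mu))) mu <- pred$c_j
  h$mu <- mu / sum(mu)
  if (is.finite(particle$intensity %||% NA_real_))
    h$topology$intensity <- particle$intensity
  if (is.finite(particle$area_px %||% NA_real_))
    h$topology$area <- particle$area_px
  h$miss <- 0L
  h
}

# combined (probability-weighted) state of a hypothesis
hypothesis_state <- function(h) {
  Reduce(`+`, Map(`*`, h$x, h$mu))
}

#' Build tracks from per-frame detections
#'
#' Runs the IMM filter and optimal assignment frame by frame: active tracks
#' are predicted forward, matched to detections by [correspond_frame()],
#' updated on a match, and closed after `max_miss` consecutive missed
#' frames; unmatched detections start new tracks immediately. Deterministic
#' given the inputs.
#'
#' @param particles a `particle_table` with columns `frame`, `x_nm`, `y_nm`
#'   and optionally `intensity`, `area_px`.
#' @param bank a [motion_model_bank()].
#' @param frame_interval_s frame interval (s).
#' @param meas_sigma_nm measurement noise sd (localization precision).
#' @param max_miss close a track after this many consecutive misses.
#' @param min_track_len minimum observations for a reported track; shorter
#'   ones are counted as unassigned-birth singletons.
#' @param w_I,w_A,gate_p association parameters.
#' @return a [track_set()]; attribute `n_singletons` counts the dropped
#'   singleton births.
#' @export
build_tracks <- function(particles, bank = motion_model_bank(),
                         frame_interval_s = 0.05, meas_sigma_nm = 20,
                         max_miss = 2L, min_track_len = 2L,
                         w_I = 1, w_A = 1, gate_p = 0.99) {
  empty <- track_set(data.frame(track_id = integer(0), frame = integer(0),
                                t_s = numeric(0), x_nm = numeric(0),
                                y_nm = numeric(0)), frame_interval_s)
  if (nrow(particles) == 0) return(empty)
  frames <- seq_len(max(particles$frame))
  active <- list()
  done <- list()
  next_id <- 1L
  for (f in frames) {
    dets <- particles[particles$frame == f, , drop = FALSE]
    preds <- lapply(active, function(h)
      imm_predict(h, bank, dt_s = (h$miss + 1L) * frame_interval_s))
    topo <- lapply(active, `[[`, "topology")
    cor <- correspond_frame(preds, topo, dets, w_I = w_I, w_A = w_A,
                            gate_p = gate_p)
    keep <- list()
    for (i in seq_along(active)) {
      h <- active[[i]]
      j <- cor$assign[i]
      if (!is.na(j)) {
        h <- imm_update(h, preds[[i]], dets[j, , drop = FALSE])
        h$obs <- rbind(h$obs, data.frame(
          track_id = h$id, frame = f, t_s = (f - 1) * frame_interval_s,
          x_nm = dets$x_nm[j], y_nm = dets$y_nm[j],
          intensity = dets$intensity[j] %||% NA_real_,
          area_px = dets$area_px[j] %||% NA_real_))
        keep <- c(keep, list(h))
      } else {
        h$miss <- h$miss + 1L
        # carry the prediction so the next gate opens from the right place
        h$x <- preds[[i]]$x; h$P <- preds[[i]]$P; h$mu <- preds[[i]]$c_j
        if (h$miss > max_miss) done <- c(done, list(h))
        else keep <- c(keep, list(h))
      }
    }
    for (j in cor$births) {
      h <- new_hypothesis(dets[j, , drop = FALSE], bank, next_id,
                          meas_sigma_nm = meas_sigma_nm)
      h$obs <- data.frame(track_id = next_id, frame = f,
                          t_s = (f - 1) * frame_interval_s,
                          x_nm = dets$x_nm[j], y_nm = dets$y_nm[j],
                          intensity = dets$intensity[j] %||% NA_real_,
                          area_px = dets$area_px[j] %||% NA_real_)
      next_id <- next_id + 1L
      keep <- c(keep, list(h))
    }
    active <- keep
  }
  done <- c(done, active)
  obs <- lapply(done, `[[`, "obs")
  lens <- vapply(obs, nrow, integer(1))
  df <- do.call(rbind, obs[lens >= min_track_len])
  n_single <- sum(lens < min_track_len)
  if (is.null(df)) {
    attr(empty, "n_singletons") <- n_single
    return(empty)
  }
  ts <- track_set(df, frame_interval_s)
  attr(ts, "n_singletons") <- n_single
  ts
}

#' Detect vesicle fusion events in intensity traces
#'
#' A fusion event is a single-sample intensity increase exceeding
#' `k_mad` times the rolling median absolute deviation of the trace
#' increments, whose post-peak trace fits an exponential decay
#' (`r^2 >= r2_min`, decay constant within `tau_bounds_s`). Peaks failing
#' the decay criterion (e.g. monotone ramps) are rejected. When vesicle
#' tracks are supplied, each event returns a track excerpt re-indexed so the
#' peak (fusion) frame is `t_rel_s = 0`.
#'
#' @param ves a [vesicle_set()] carrying intensity `traces` and
#'   `frame_interval_s`.
#' @param k_mad jump threshold in rolling-MAD units.
#' @param tau_bounds_s admissible decay constants (s).
#' @param r2_min minimal r-squared of the log-linear decay fit.
#' @param fit_window_s post-peak window used for the decay fit.
#' @param tracks optional [track_set()] of vesicle positions whose
#'   `track_id` matches the vesicle index.
#' @return list with `events` (data frame: `vesicle`, `frame`, `t_s`,
#'   `tau_s`, `r2`) and `excerpts` (list of aligned data frames with
#'   `t_rel_s`, `x_nm`, `y_nm`). No events is a valid result.
#' @export
detect_fusion_events <- function(ves, k_mad = 5, tau_bounds_s = c(0.05, 5),
                                 r2_min = 0.8, fit_window_s = 2,
                                 tracks = NULL) {
  if (is.null(ves$traces)) stop("vesicle set carries no traces", call. = FALSE)
  dt <- ves$frame_interval_s
  if (!is.finite(dt)) stop("traces need a frame interval", call. = FALSE)
  events <- list(); excerpts <- list()
  for (v in seq_len(nrow(ves$traces))) {
    tr <- ves$traces[v, ]
    inc <- diff(tr)
    scale <- stats::mad(inc)
    if (scale <= 0) scale <- stats::sd(inc)
    if (!isTRUE(scale > 0)) next
    cand <- which(inc > k_mad * scale) + 1L
    if (length(cand) == 0) next
    # candidate peak: local maximum at/after the jump
    for (cd in cand) {
      pk <- cd
      while (pk < length(tr) && tr[pk + 1] > tr[pk]) pk <- pk + 1L
      n_fit <- min(length(tr), pk + round(fit_window_s / dt))
      seg <- tr[pk:n_fit]
      if (length(seg) < 5) next
      base <- stats::median(tr[seq_len(max(cd - 2L, 1L))])
      y <- seg - base
      if (y[1] <= 0) next
      t_seg <- (seq_along(seg) - 1) * dt
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ A * exp(-t_seg / tau),
                          start = list(A = y[1], tau = 5 * dt),
                          lower = c(A = 0, tau = dt / 10),
                          control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
      if (is.null(fit)) next
      tau <- stats::coef(fit)[["tau"]]
      r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
      if (!is.finite(tau) || tau < tau_bounds_s[1] || tau > tau_bounds_s[2] ||
          r2 < r2_min) next
      events[[length(events) + 1L]] <-
        data.frame(vesicle = v, frame = pk, t_s = (pk - 1) * dt,
                   tau_s = tau, r2 = r2)
      if (!is.null(tracks)) {
        p <- tracks$points
        exc <- p[p$track_id == v & p$frame <= pk, , drop = FALSE]
        if (nrow(exc) > 0) {
          exc$t_rel_s <- (exc$frame - pk) * dt
          excerpts[[length(excerpts) + 1L]] <-
            exc[, c("t_rel_s", "x_nm", "y_nm")]
        }
      }
      break # one event per vesicle trace
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(vesicle = integer(0), frame = integer(0), t_s = numeric(0),
               tau_s = numeric(0), r2 = numeric(0))
  rownames(ev) <- NULL
  list(events = ev, excerpts = excerpts)
}
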