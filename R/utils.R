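# Internal numeric and image helpers shared across modules.
#
# Image convention: matrices are indexed [row, col] with col mapping to x and
# row mapping to y; the centre of pixel (r, c) sits at physical coordinates
# ((c - 0.5) * pixel_size, (r - 0.5) * pixel_size), origin at the lower-left
# corner of the field, x right, y up.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

#' Derive a stage seed from a global seed
#'
#' Deterministic splitting of one user-facing seed into per-stage seeds,
#' kept strictly below 2^31 so the result is always a valid R integer.
#'
#' @param seed integer global seed.
#' @param k integer stage index (>= 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(k + 1L)) s <- (s * 48271) %% 2147483647
  as.integer(s)
}

# sampled, normalised 1-D Gaussian kernel
gaussian_kernel1d <- function(sigma, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# separable convolution along rows (zero padding)
conv_rows <- function(img, k) {
  r <- (length(k) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(0, nr + 2L * r, nc)
  pad[(r + 1L):(r + nr), ] <- img
  out <- matrix(0, nr, nc)
  for (i in seq_along(k))
    out <- out + k[i] * pad[i:(i + nr - 1L), , drop = FALSE]
  out
}

# rotationally symmetric Gaussian low-pass filter, zero padded
gaussian_blur <- function(img, sigma, truncate = 4) {
  k <- gaussian_kernel1d(sigma, truncate)
  t(conv_rows(t(conv_rows(img, k)), k))
}

# integral image with a leading row/column of zeros
integral_image <- function(img) {
  S <- apply(img, 2, cumsum)
  S <- t(apply(S, 1, cumsum))
  rbind(0, cbind(0, S))
}

# sum of `img` over a (2h+1)-square window centred at every pixel, windows
# clipped at the borders; returns a list with the sums and the pixel counts
window_sum <- function(img, half) {
  nr <- nrow(img); nc <- ncol(img)
  S <- integral_image(img)
  r <- matrix(seq_len(nr), nr, nc)
  c_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  r1 <- pmax(r - half, 1L); r2 <- pmin(r + half, nr)
  c1 <- pmax(c_ - half, 1L); c2 <- pmin(c_ + half, nc)
  sums <- S[cbind(as.vector(r2 + 1L), as.vector(c2 + 1L))] -
    S[cbind(as.vector(r1), as.vector(c2 + 1L))] -
    S[cbind(as.vector(r2 + 1L), as.vector(c1))] +
    S[cbind(as.vector(r1), as.vector(c1))]
  counts <- (r2 - r1 + 1L) * (c2 - c1 + 1L)
  list(sum = matrix(sums, nr, nc), count = counts)
}

# 8-connected labelling of a logical matrix; 0 = background.
# Two-pass union-find; images here are small (<= a few hundred px a side).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  nxt <- 0L
  for (c_ in seq_len(nc)) {
    for (r in seq_len(nr)) {
      if (!mask[r, c_]) next
      nb <- integer(0)
      if (r > 1L && lab[r - 1L, c_] > 0L) nb <- c(nb, lab[r - 1L, c_])
      if (c_ > 1L) {
        if (lab[r, c_ - 1L] > 0L) nb <- c(nb, lab[r, c_ - 1L])
        if (r > 1L && lab[r - 1L, c_ - 1L] > 0L) nb <- c(nb, lab[r - 1L, c_ - 1L])
        if (r < nr && lab[r + 1L, c_ - 1L] > 0L) nb <- c(nb, lab[r + 1L, c_ - 1L])
      }
      if (length(nb) == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[r, c_] <- nxt
      } else {
        roots <- vapply(unique(nb), find, integer(1))
        m <- min(roots)
        lab[r, c_] <- m
        for (x in roots) parent[x] <- m
      }
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  remap <- integer(nxt)
  remap[sort(unique(roots))] <- seq_along(unique(roots))
  idx <- lab > 0L
  lab[idx] <- remap[roots[lab[idx]]]
  lab
}

# pairwise Euclidean distances between two 2-column coordinate matrices
cross_dist <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(pmax(d2, 0))
}

# minimum-image pairwise distances on a periodic rectangle
cross_dist_periodic <- function(a, b, box) {
  dx <- abs(outer(a[, 1], b[, 1], "-"))
  dy <- abs(outer(a[, 2], b[, 2], "-"))
  dx <- pmin(dx, box[1] - dx)
  dy <- pmin(dy, box[2] - dy)
  sqrt(dx^2 + dy^2)
}

# Gaussian kernel density of a point set evaluated at query locations,
# in points per nm^2 (used for density-biased vesicle placement)
kde_density <- function(points, query, bandwidth_nm) {
  if (nrow(points) == 0L) return(rep(0, nrow(query)))
  d <- cross_dist(query, points)
  rowSums(exp(-d^2 / (2 * bandwidth_nm^2))) / (2 * pi * bandwidth_nm^2)
}
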