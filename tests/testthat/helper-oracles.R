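# Independent oracles used across the suite. Each is a deliberately naive
# implementation kept separate from the package code paths it checks.

# MSD by the literal double loop over start frames and lags
oracle_msd <- function(x, y, dt, max_lag) {
  n <- length(x)
  vapply(seq_len(max_lag), function(m) {
    acc <- 0
    for (i in seq_len(n - m))
      acc <- acc + (x[i + m] - x[i])^2 + (y[i + m] - y[i])^2
    acc / (n - m)
  }, numeric(1))
}

# joint log-likelihood via dense determinant and explicit inverse
oracle_loglik_dense <- function(dx, dy, alpha, beta) {
  n <- length(dx)
  S <- diag(alpha, n)
  if (n > 1) {
    idx <- seq_len(n - 1)
    S[cbind(idx, idx + 1)] <- beta
    S[cbind(idx + 1, idx)] <- beta
  }
  Si <- solve(S)
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  -ld - 0.5 * drop(dx %*% Si %*% dx) - 0.5 * drop(dy %*% Si %*% dy)
}

# O(n^3) convex hull area: a point is a hull vertex iff it is not strictly
# inside any triangle of other points; area by the shoelace formula on the
# angularly sorted vertices
oracle_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  in_triangle <- function(p, a, b, c) {
    d1 <- cross(a, b, p); d2 <- cross(b, c, p); d3 <- cross(c, a, p)
    (d1 > 1e-12 && d2 > 1e-12 && d3 > 1e-12) ||
      (d1 < -1e-12 && d2 < -1e-12 && d3 < -1e-12)
  }
  keep <- rep(TRUE, n)
  for (p in seq_len(n)) {
    others <- setdiff(seq_len(n), p)
    for (a in others) for (b in setdiff(others, a)) for (cc in setdiff(others, c(a, b))) {
      if (in_triangle(pts[p, ], pts[a, ], pts[b, ], pts[cc, ])) {
        keep[p] <- FALSE
        break
      }
    }
  }
  v <- pts[keep, , drop = FALSE]
  cx <- mean(v[, 1]); cy <- mean(v[, 2])
  ord <- order(atan2(v[, 2] - cy, v[, 1] - cx))
  v <- v[ord, , drop = FALSE]
  hx <- v[, 1]; hy <- v[, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# exact covariance of substep-averaged Brownian observations:
# frame n records the mean of the path at times n*dt + j*dt/K, j = 1..K;
# Brownian covariance Cov(x(s), x(t)) = 2 D min(s, t)
oracle_blur_displacement_cov <- function(D, dt, K, n_frames = 3) {
  tau <- dt / K
  tt <- as.vector(sapply(0:(n_frames - 1), function(n) n * dt + (1:K) * tau))
  Cov <- 2 * D * outer(tt, tt, pmin)
  A <- kronecker(diag(n_frames), matrix(1 / K, 1, K))
  Cy <- A %*% Cov %*% t(A)
  Dm <- diff(diag(n_frames))
  Dm %*% Cy %*% t(Dm)
}

random_trajectory <- function(n, dt = 0.033, id = "t") {
  trajectory(x = cumsum(rnorm(n)), y = cumsum(rnorm(n)), dt = dt, id = id)
}
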