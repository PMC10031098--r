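#' Motion blur coefficient of a camera shutter
#'
#' The apparent motion of a diffusing particle is smeared over the camera
#' exposure. For a normalised shutter (illumination) profile s(t) on
#' \[0, T\] with cumulative S(t), the blur coefficient is
#' `R = (1/T) * integral of S(t) (1 - S(t)) dt`. Continuous illumination
#' (s = 1/T) gives R = 1/6; an instantaneous shutter gives R = 0.
#'
#' @param shutter Function s(t), vectorised, non-negative on \[0, T\].
#'   Ignored when `cumulative` is supplied.
#' @param T Exposure length in seconds (the result is dimensionless and
#'   does not depend on T for a fixed shape).
#' @param cumulative Optional cumulative shutter S(t) as a function;
#'   allows degenerate shutters (e.g. a Dirac pulse at t = 0 has
#'   `S(t) = 1` on (0, T\]) that have no density representation.
#' @param n_grid Number of grid points for the trapezoid quadrature.
#' @return The blur coefficient R (dimensionless, in \[0, 1/4\]).
#' @examples
#' motion_blur_coefficient(function(t) rep(1, length(t)), T = 1) # 1/6
#' motion_blur_coefficient(cumulative = function(t) as.numeric(t > 0)) # 0
#' @export
motion_blur_coefficient <- function(shutter = NULL, T = 1,
                                    cumulative = NULL, n_grid = 20001L) {
  tt <- seq(0, T, length.out = n_grid)
  if (is.null(cumulative)) {
    if (is.null(shutter))
      stop("supply either shutter or cumulative", call. = FALSE)
    s <- shutter(tt)
    if (any(s < 0)) stop("shutter must be non-negative", call. = FALSE)
    S <- pracma::cumtrapz(tt, s)[, 1L]
  } else {
    S <- cumulative(tt)
  }
  if (abs(S[n_grid] - 1) > 1e-6)
    stop(sprintf("shutter is not normalised: S(T) = %.8g, expected 1",
                 S[n_grid]), call. = FALSE)
  pracma::trapz(tt, S * (1 - S)) / T
}

#' Displacement covariance model for diffusion with noise and blur
#'
#' Observed displacements of a Brownian particle with static localization
#' noise sigma and motion blur R have a tridiagonal Toeplitz N x N
#' covariance: diagonal `2*D*dt - 2*(2*D*R*dt - sigma^2)`, first
#' off-diagonals `2*D*R*dt - sigma^2`, zero elsewhere. The constructor
#' asserts positive definiteness (guaranteed for R <= 1/4 whenever D > 0
#' or sigma > 0); the fully degenerate point D = sigma = 0 is rejected.
#'
#' @param D Diffusion coefficient in um^2/s (>= 0).
#' @param sigma Static localization noise in um (>= 0).
#' @param dt Frame time in seconds (> 0).
#' @param R Blur coefficient, in \[0, 1/4\]; 1/6 for continuous
#'   illumination.
#' @param N Number of displacements (frames - 1, >= 1).
#' @return An object of class `"cov_model"` with elements `D`, `sigma`,
#'   `dt`, `R`, `N` and the precomputed Toeplitz entries `alpha`
#'   (diagonal) and `beta` (off-diagonal), both in um^2.
#' @export
covariance_model <- function(D, sigma, dt, R = 1 / 6, N) {
  stopifnot(is.numeric(D), D >= 0, is.numeric(sigma), sigma >= 0,
            is.numeric(dt), dt > 0, is.numeric(R), R >= 0, R <= 0.25,
            N >= 1)
  if (D == 0 && sigma == 0)
    stop("degenerate model: D = sigma = 0 gives a singular covariance",
         call. = FALSE)
  alpha <- 2 * D * dt - 2 * (2 * D * R * dt - sigma^2)
  beta <- 2 * D * R * dt - sigma^2
  # exact tridiagonal-Toeplitz eigenvalues: alpha + 2 beta cos(k pi / (N+1))
  lam_min <- alpha - 2 * abs(beta) * cos(pi / (N + 1))
  if (lam_min <= 0)
    stop("covariance model is not positive definite", call. = FALSE)
  structure(list(D = D, sigma = sigma, dt = dt, R = R, N = as.integer(N),
                 alpha = alpha, beta = beta),
            class = "cov_model")
}

#' Dense displacement covariance matrix
#'
#' Materialises the tridiagonal Toeplitz matrix of a [covariance_model()].
#' Mainly for inspection and testing; the likelihood functions never build
#' it.
#'
#' @param model A [covariance_model()].
#' @return A symmetric `N x N` matrix (um^2).
#' @export
covariance_matrix <- function(model) {
  stopifnot(inherits(model, "cov_model"))
  n <- model$N
  m <- diag(model$alpha, n)
  if (n > 1L) {
    idx <- seq_len(n - 1L)
    m[cbind(idx, idx + 1L)] <- model$beta
    m[cbind(idx + 1L, idx)] <- model$beta
  }
  m
}

# symmetric tridiagonal Toeplitz LDL' factor diagonal and the forward
# substitution z with L z = x; quadratic form x' Sigma^-1 x = sum(z^2 / d)
.tridiag_ldl_quad <- function(alpha, beta, x) {
  n <- length(x)
  d <- numeric(n)
  z <- numeric(n)
  d[1L] <- alpha
  z[1L] <- x[1L]
  if (n > 1L) for (i in 2:n) {
    if (d[i - 1L] <= 0) return(NULL)
    l <- beta / d[i - 1L]
    d[i] <- alpha - beta * l
    z[i] <- x[i] - l * z[i - 1L]
  }
  if (d[n] <= 0) return(NULL)
  list(logdet = sum(log(d)), quad = sum(z^2 / d))
}

#' Direct log-likelihood of displacement vectors
#'
#' Evaluates `L = -log|Sigma| - (1/2) dx' Sigma^-1 dx -
#' (1/2) dy' Sigma^-1 dy` exactly (no additive constants), using the LDL'
#' factorisation of the tridiagonal covariance: the log-determinant comes
#' from the factor diagonal and the quadratic forms from substitution, so
#' no matrix is ever inverted. Note the joint form carries `-log|Sigma|`,
#' not `-(1/2) log|Sigma|` per axis: the two axes are independent and
#' share Sigma.
#'
#' @param disp A [displacements()] object with `model$N` displacements.
#' @param model A [covariance_model()].
#' @return The log-likelihood (scalar).
#' @export
log_likelihood_direct <- function(disp, model) {
  stopifnot(inherits(disp, "displacements"), inherits(model, "cov_model"))
  if (length(disp$dx) != model$N)
    stop("displacement length does not match model N", call. = FALSE)
  fx <- .tridiag_ldl_quad(model$alpha, model$beta, disp$dx)
  fy <- .tridiag_ldl_quad(model$alpha, model$beta, disp$dy)
  if (is.null(fx) || is.null(fy))
    stop("covariance model is not positive definite at these parameters",
         call. = FALSE)
  -fx$logdet - 0.5 * fx$quad - 0.5 * fy$quad
}

#' Circulant approximation to the displacement log-likelihood
#'
#' Replaces the tridiagonal Toeplitz covariance by its circulant surrogate,
#' whose eigenvalues are `psi_k = alpha + 2 beta cos(2 pi k / N)` for
#' k = 0..N-1, and evaluates the same likelihood form in the Fourier basis
#' using the unnormalised DFTs of dx and dy. The approximation error is
#' O(1/N); it is intended for long tracks, where it avoids the O(N) serial
#' factorisation in favour of an FFT.
#'
#' @inheritParams log_likelihood_direct
#' @return The approximate log-likelihood (scalar).
#' @export
log_likelihood_circulant <- function(disp, model) {
  stopifnot(inherits(disp, "displacements"), inherits(model, "cov_model"))
  n <- model$N
  if (length(disp$dx) != n)
    stop("displacement length does not match model N", call. = FALSE)
  psi <- model$alpha + 2 * model$beta * cos(2 * pi * (0:(n - 1L)) / n)
  if (any(psi <= 0))
    stop("circulant surrogate is not positive definite at these parameters",
         call. = FALSE)
  p2 <- (Mod(stats::fft(disp$dx))^2 + Mod(stats::fft(disp$dy))^2) / n
  -sum(log(psi)) - 0.5 * sum(p2 / psi)
}

# raw DST-I: a_k = sum_j x_j sin(pi j k / (n+1)), via FFT of the odd extension
.dst1 <- function(x) {
  n <- length(x)
  -Im(stats::fft(c(0, x, 0, -rev(x))))[2:(n + 1L)] / 2
}

#' Optimiser settings for [fit_mle()]
#'
#' @param reltol Relative function tolerance of the Nelder-Mead search.
#' @param maxit Maximum iterations per start.
#' @param switch_frames Frame count at and above which the circulant
#'   likelihood replaces the direct one (default 1001, i.e. direct up to
#'   1000 frames).
#' @param d_floor Lower floor excluding the exact origin D = sigma = 0
#'   from the search region (natural units).
#' @return A list of settings.
#' @export
mle_control <- function(reltol = 1e-10, maxit = 1000L,
                        switch_frames = 1001L, d_floor = 1e-12) {
  list(reltol = reltol, maxit = as.integer(maxit),
       switch_frames = as.integer(switch_frames), d_floor = d_floor)
}

#' Maximum-likelihood estimation of diffusion coefficient and noise
#'
#' Jointly estimates the diffusion coefficient D and the static
#' localization noise sigma of one trajectory by maximising the Gaussian
#' likelihood of its displacement vectors under the tridiagonal covariance
#' model (see [covariance_model()]). The search is box-constrained to
#' D >= 0, sigma >= 0 by optimising over square roots, so boundary
#' solutions (in particular D_hat = 0 for apparently immobile particles)
#' are representable; unlike the MSD fit, the estimate can never be
#' negative.
#'
#' Tracks of fewer than `switch_frames` frames use the exact direct
#' likelihood; longer tracks use the circulant approximation. Both are
#' evaluated in a spectral basis precomputed once per trajectory (sine
#' basis for the tridiagonal Toeplitz matrix, Fourier basis for the
#' circulant surrogate), which is algebraically identical to
#' [log_likelihood_direct()] / [log_likelihood_circulant()] but makes each
#' optimiser step O(N) with no serial recursion.
#'
#' Starting values come from the MSD three-point fit (clipped into the
#' admissible region), with a moment-based fallback start that splits the
#' observed displacement variance between diffusion and noise.
#'
#' @param traj A gap-free [trajectory()] with at least 3 frames.
#' @param R Blur coefficient (default 1/6, continuous illumination); a
#'   per-run constant.
#' @param control A [mle_control()] list.
#' @return An object of class `"mle_result"`: list with `D_hat` (um^2/s,
#'   >= 0), `sigma_hat` (um, >= 0), `loglik`, `method` ("direct" or
#'   "circulant"), `converged` (logical) and `n_frames`.
#' @export
fit_mle <- function(traj, R = 1 / 6, control = mle_control()) {
  stopifnot(inherits(traj, "trajectory"))
  n <- n_frames(traj)
  if (n < 3L) stop("MLE needs at least 3 frames", call. = FALSE)
  disp <- displacements(traj)
  dt <- traj$dt
  N <- n - 1L
  if (all(disp$dx == 0) && all(disp$dy == 0)) {
    warning("all displacements are zero; returning boundary estimate D = sigma = 0",
            call. = FALSE)
    return(structure(list(D_hat = 0, sigma_hat = 0, loglik = NA_real_,
                          method = "degenerate", converged = TRUE,
                          n_frames = n), class = "mle_result"))
  }

  use_circulant <- n >= control$switch_frames
  if (use_circulant) {
    p2 <- (Mod(stats::fft(disp$dx))^2 + Mod(stats::fft(disp$dy))^2) / N
    ck <- cos(2 * pi * (0:(N - 1L)) / N)
    negloglik <- function(alpha, beta) {
      psi <- alpha + 2 * beta * ck
      if (any(psi <= 0)) return(Inf)
      sum(log(psi)) + 0.5 * sum(p2 / psi)
    }
  } else {
    a2 <- .dst1(disp$dx)^2 + .dst1(disp$dy)^2
    ck <- cos(pi * seq_len(N) / (N + 1L))
    negloglik <- function(alpha, beta) {
      lam <- alpha + 2 * beta * ck
      if (any(lam <= 0)) return(Inf)
      sum(log(lam)) + sum(a2 / lam) / (N + 1L)
    }
  }

  floor_ <- control$d_floor
  objective <- function(theta) {
    D <- theta[1L]^2
    s2 <- theta[2L]^4             # theta[2]^2 = sigma, sigma^2 = theta^4
    if (D < floor_ && s2 < floor_) return(Inf)
    alpha <- 2 * D * dt - 2 * (2 * D * R * dt - s2)
    beta <- 2 * D * R * dt - s2
    negloglik(alpha, beta)
  }

  # moment start: split the per-axis displacement variance between the two
  v <- mean(disp$dx^2 + disp$dy^2) / 2
  starts <- list(c(sqrt(max(v / (8 * dt), floor_)),
                   max(v / 4, floor_)^(1 / 4)))
  if (n >= 4L) {
    ms <- tryCatch(fit_msd(traj), error = function(e) NULL)
    if (!is.null(ms)) {
      D0 <- max(ms$D, 1e-6)
      s0sq <- max(ms$intercept / 4 + 2 * D0 * R * dt, 1e-10)
      starts <- c(list(c(sqrt(D0), s0sq^(1 / 4))), starts)
    }
  }

  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      stats::optim(th0, objective, method = "Nelder-Mead",
                   control = list(reltol = control$reltol,
                                  maxit = control$maxit)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("MLE optimisation failed for trajectory '", traj$id, "'",
         call. = FALSE)
  structure(
    list(D_hat = best$par[1L]^2, sigma_hat = best$par[2L]^2,
         loglik = -best$value,
         method = if (use_circulant) "circulant" else "direct",
         converged = best$convergence == 0L, n_frames = n),
    class = "mle_result"
  )
}

#' @export
print.mle_result <- function(x, ...) {
  cat(sprintf(
    "<mle_result: D = %.4g um^2/s, sigma = %.4g um, loglik = %.4g (%s%s)>\n",
    x$D_hat, x$sigma_hat, x$loglik, x$method,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
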