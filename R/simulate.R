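#' Simulation configuration for 2D Brownian trajectories
#'
#' Collects the ground-truth parameters of the trajectory generator:
#' diffusion coefficient, static localization error, frame time, trajectory
#' length and count, motion blur, and the random seed.
#'
#' The localization error `eps` is the per-axis standard deviation of the
#' Gaussian position noise (um), added once per frame after any blur
#' averaging (static detection noise). With blur on, each frame's exposure
#' is discretised into `n_substeps` Brownian substeps and the recorded
#' pre-noise position is the mean of the intra-exposure positions,
#' emulating a continuously open shutter; the effective blur coefficient of
#' the discretisation is [blur_coefficient_substeps()] and converges to 1/6
#' as `n_substeps` grows.
#'
#' @param D_true Diffusion coefficient in um^2/s (>= 0).
#' @param eps Localization error in um (>= 0), Gaussian SD per coordinate.
#' @param dt Frame time in seconds (> 0).
#' @param n_frames Frames per trajectory (>= 2).
#' @param n_traj Number of trajectories (>= 1).
#' @param blur Logical: simulate motion blur over the exposure?
#' @param n_substeps Substeps per exposure used when `blur = TRUE` (>= 2).
#' @param pixel_size Pixel size in um; metadata only, positions are not
#'   quantised to the pixel grid.
#' @param seed Integer seed; trajectory k uses an independent substream
#'   derived from `(seed, k)`, so the set is reproducible and
#'   order-insensitive.
#' @return An object of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(D_true = 0.15, eps = 0.1, dt = 0.033,
#'                   n_frames = 501, n_traj = 10, blur = TRUE, seed = 1)
#' @export
sim_config <- function(D_true, eps, dt, n_frames, n_traj = 1L,
                       blur = FALSE, n_substeps = 100L,
                       pixel_size = 0.16, seed = 1L) {
  stopifnot(is.numeric(D_true), length(D_true) == 1L, D_true >= 0,
            is.numeric(eps), length(eps) == 1L, eps >= 0,
            is.numeric(dt), length(dt) == 1L, dt > 0,
            n_frames >= 2L, n_traj >= 1L, is.logical(blur),
            n_substeps >= 1L, pixel_size > 0)
  if (blur && n_substeps < 2L)
    stop("blur requires n_substeps >= 2", call. = FALSE)
  structure(
    list(D_true = D_true, eps = eps, dt = dt,
         n_frames = as.integer(n_frames), n_traj = as.integer(n_traj),
         blur = blur, n_substeps = as.integer(n_substeps),
         pixel_size = pixel_size, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config: D = %g um^2/s, eps = %g um, dt = %g s, %d frames x %d traj, blur %s (K = %d), seed %d>\n",
    x$D_true, x$eps, x$dt, x$n_frames, x$n_traj,
    if (x$blur) "on" else "off", x$n_substeps, x$seed))
  invisible(x)
}

#' Effective blur coefficient of the substep discretisation
#'
#' Averaging a Brownian path over K equally spaced positions within the
#' exposure yields displacement statistics identical to the continuous
#' covariance model with blur coefficient R_K = (1/6) (1 - 1/K^2), which
#' approaches the continuous-illumination value 1/6 as K grows.
#'
#' @param n_substeps Number of substeps K (>= 1). K = 1 means sampling at
#'   the exposure end, i.e. no blur (R = 0).
#' @return The dimensionless blur coefficient of the finite discretisation.
#' @export
blur_coefficient_substeps <- function(n_substeps) {
  k <- as.numeric(n_substeps)
  stopifnot(all(k >= 1))
  (1 / 6) * (1 - 1 / k^2)
}

# deterministic per-trajectory substream seed; keeps values in 32-bit range
.traj_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483629)
}

#' Simulate one observed 2D Brownian trajectory
#'
#' True positions start at the origin and evolve with independent Gaussian
#' increments of variance `2 * D_true * dt` per axis per frame. With blur
#' off, the observed position is the true frame position plus Gaussian
#' noise of SD `eps` per axis. With blur on, each exposure is discretised
#' into `n_substeps` Brownian substeps; the recorded pre-noise position is
#' the mean of the substep positions within the exposure, then noise of SD
#' `eps` is added.
#'
#' @param config A [sim_config()].
#' @param stream Index of the trajectory substream (the k-th trajectory of
#'   a set uses `stream = k`); combined with `config$seed` to seed the RNG.
#' @return A [trajectory()] with frame indices `0:(n_frames - 1)`.
#' @export
simulate_trajectory <- function(config, stream = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.traj_seed(config$seed, stream))
  n <- config$n_frames
  if (config$D_true == 0) {
    px <- numeric(n)
    py <- numeric(n)
  } else if (config$blur) {
    k <- config$n_substeps
    step_sd <- sqrt(2 * config$D_true * config$dt / k)
    # frame i averages the path over its exposure ((i-1)*dt, i*dt]
    px <- colMeans(matrix(cumsum(stats::rnorm(n * k, sd = step_sd)), nrow = k))
    py <- colMeans(matrix(cumsum(stats::rnorm(n * k, sd = step_sd)), nrow = k))
  } else {
    step_sd <- sqrt(2 * config$D_true * config$dt)
    px <- cumsum(c(0, stats::rnorm(n - 1L, sd = step_sd)))
    py <- cumsum(c(0, stats::rnorm(n - 1L, sd = step_sd)))
  }
  if (config$eps > 0) {
    px <- px + stats::rnorm(n, sd = config$eps)
    py <- py + stats::rnorm(n, sd = config$eps)
  }
  trajectory(x = px, y = py, dt = config$dt, frame = 0:(n - 1L),
             id = sprintf("sim_%d", stream))
}

#' Simulate a set of independent Brownian trajectories
#'
#' @param config A [sim_config()]; `config$n_traj` trajectories are drawn.
#' @return A [trajectory_set()]. The same seed always reproduces the same
#'   coordinates bit-exactly; trajectory k depends only on `(seed, k)`.
#' @export
simulate_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  trajectory_set(lapply(seq_len(config$n_traj), function(k)
    simulate_trajectory(config, stream = k)))
}
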