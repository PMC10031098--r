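#' Time-averaged mean square displacement curve
#'
#' For lag m (in frames), the MSD at lag time m*dt is the average of
#' `(x[i+m] - x[i])^2 + (y[i+m] - y[i])^2` over all `N - m` overlapping
#' start frames i, where N is the number of frames.
#'
#' @param traj A gap-free [trajectory()].
#' @param max_lag Largest lag in frames (1 <= max_lag <= N - 1). Defaults
#'   to `n_frames - 1`.
#' @return An object of class `"msd_curve"`: data frame with columns
#'   `lag` (frames), `lag_time` (s), `msd` (um^2) and `n_pairs` (the
#'   `N - m` averaging counts).
#' @export
msd_curve <- function(traj, max_lag = n_frames(traj) - 1L) {
  stopifnot(inherits(traj, "trajectory"))
  if (any(diff(traj$frame) != 1L))
    stop("msd_curve requires a gap-free trajectory", call. = FALSE)
  n <- n_frames(traj)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L || max_lag >= n)
    stop("max_lag must be between 1 and n_frames - 1", call. = FALSE)
  m <- seq_len(max_lag)
  vals <- vapply(m, function(mm) {
    i <- seq_len(n - mm)
    mean((traj$x[i + mm] - traj$x[i])^2 + (traj$y[i + mm] - traj$y[i])^2)
  }, numeric(1))
  structure(
    data.frame(lag = m, lag_time = m * traj$dt, msd = vals, n_pairs = n - m),
    class = c("msd_curve", "data.frame"), dt = traj$dt
  )
}

#' Three-point linear fit to an MSD curve
#'
#' Fits an ordinary least squares line through the first three MSD points
#' (lags 1, 2, 3; no (0,0) anchor, unweighted). For 2D Brownian motion the
#' MSD slope equals 4D, so the estimate is `D = slope / 4`; the y-intercept
#' absorbs localization noise and blur. The sign of D is not constrained:
#' noisy short tracks can and do produce negative slopes, which are
#' reported as-is.
#'
#' @param curve An [msd_curve()] with at least 3 lags.
#' @param dt Frame interval in seconds; defaults to the one recorded in
#'   the curve.
#' @return An object of class `"msd_fit"`: list with `D` (um^2/s,
#'   sign-unconstrained), `intercept` (um^2, fitted value at lag 0) and
#'   `points_used` (the lags fitted, always 1:3).
#' @export
fit_msd_three_points <- function(curve, dt = attr(curve, "dt")) {
  stopifnot(inherits(curve, "msd_curve"))
  if (nrow(curve) < 3L)
    stop("three-point fit needs an MSD curve with at least 3 lags",
         call. = FALSE)
  if (is.null(dt)) stop("dt is required", call. = FALSE)
  tt <- curve$lag[1:3] * dt
  yy <- curve$msd[1:3]
  fit <- stats::lm.fit(cbind(1, tt), yy)
  structure(
    list(D = unname(fit$coefficients[2L]) / 4,
         intercept = unname(fit$coefficients[1L]),
         points_used = curve$lag[1:3]),
    class = "msd_fit"
  )
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("<msd_fit: D = %.4g um^2/s, intercept = %.4g um^2 (lags %s)>\n",
              x$D, x$intercept, paste(x$points_used, collapse = ",")))
  invisible(x)
}

#' MSD-based diffusion coefficient of a trajectory
#'
#' Convenience wrapper: computes the MSD curve to lag 3 and applies the
#' three-point fit.
#'
#' @param traj A gap-free [trajectory()] with at least 4 frames.
#' @return An `"msd_fit"` (see [fit_msd_three_points()]).
#' @export
fit_msd <- function(traj) {
  fit_msd_three_points(msd_curve(traj, max_lag = 3L))
}
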