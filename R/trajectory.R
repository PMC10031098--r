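#' Construct a single-particle trajectory
#'
#' A trajectory is one particle's time-ordered sequence of observed positions
#' in the image plane, together with the frame interval of the recording.
#' Positions are in micrometres, time in seconds.
#'
#' @param x,y Numeric vectors of observed coordinates (um), equal length >= 2.
#' @param dt Frame interval in seconds (> 0).
#' @param frame Integer frame indices, strictly increasing. Defaults to
#'   `0:(length(x) - 1)`. The indices are kept as emitted by the tracker;
#'   estimators require them to be gap-free (consecutive).
#' @param id Character label for the trajectory.
#' @param meta Named list of free-form labels (group, temperature, ...).
#'
#' @return An object of class `"trajectory"`: a list with elements
#'   `id`, `frame`, `x`, `y`, `dt`, `meta`.
#' @examples
#' tr <- trajectory(x = c(0, 0.1, 0.3), y = c(0, 0, 0.1), dt = 0.033)
#' n_frames(tr)
#' @export
trajectory <- function(x, y, dt, frame = seq_along(x) - 1L, id = "traj",
                       meta = list()) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  frame <- as.integer(frame)
  if (length(x) < 2L || length(x) != length(y) || length(x) != length(frame))
    stop("x, y and frame must have equal length >= 2", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("all coordinates must be finite", call. = FALSE)
  if (any(diff(frame) <= 0L))
    stop("frame indices must be strictly increasing", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (seconds)", call. = FALSE)
  structure(
    list(id = as.character(id), frame = frame, x = x, y = y,
         dt = as.numeric(dt), meta = as.list(meta)),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s': %d frames, dt = %g s>\n",
              x$id, length(x$x), x$dt))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  length(traj$x)
}

#' Construct a set of trajectories sharing one frame interval
#'
#' @param trajectories List of [trajectory()] objects; all must share the
#'   same `dt`.
#' @return An object of class `"trajectory_set"`: a list of trajectories
#'   with attribute `dt`.
#' @export
trajectory_set <- function(trajectories) {
  if (!is.list(trajectories))
    stop("trajectories must be a list", call. = FALSE)
  if (!all(vapply(trajectories, inherits, logical(1), "trajectory")))
    stop("all elements must be trajectory objects", call. = FALSE)
  if (length(trajectories) > 0L) {
    dts <- vapply(trajectories, `[[`, numeric(1), "dt")
    if (max(dts) - min(dts) > 0)
      stop("all trajectories in a set must share the same dt", call. = FALSE)
    dt <- dts[[1L]]
  } else {
    dt <- NA_real_
  }
  structure(trajectories, dt = dt, class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  lens <- vapply(unclass(x), function(t) length(t$x), integer(1))
  cat(sprintf("<trajectory_set: %d trajectories, dt = %g s, %d-%d frames>\n",
              length(x), attr(x, "dt"),
              if (length(lens)) min(lens) else NA_integer_,
              if (length(lens)) max(lens) else NA_integer_))
  invisible(x)
}

#' @export
`[.trajectory_set` <- function(x, i) {
  trajectory_set(unclass(x)[i])
}

#' Keep only trajectories with at least a minimum number of frames
#'
#' Short tracks give unreliable estimates and are routinely excluded in
#' single-molecule tracking; the conventional threshold is 15 frames.
#' The threshold is inclusive: a track of exactly `min_frames` frames is kept.
#'
#' @param set A [trajectory_set()].
#' @param min_frames Minimum frame count to keep (inclusive, >= 2).
#'   Default 15.
#' @param quiet Suppress the kept/removed message.
#' @return A [trajectory_set()] (possibly empty) with the surviving tracks
#'   in their original order.
#' @export
filter_by_length <- function(set, min_frames = 15L, quiet = FALSE) {
  stopifnot(inherits(set, "trajectory_set"))
  min_frames <- as.integer(min_frames)
  if (min_frames < 2L) stop("min_frames must be >= 2", call. = FALSE)
  lens <- vapply(unclass(set), function(t) length(t$x), integer(1))
  keep <- lens >= min_frames
  if (!quiet)
    message(sprintf("filter_by_length: kept %d, removed %d (min_frames = %d)",
                    sum(keep), sum(!keep), min_frames))
  trajectory_set(unclass(set)[keep])
}

#' Consecutive-frame displacement vectors
#'
#' Extracts the observed displacements dx\[k\] = x\[k+1\] - x\[k\] (and
#' likewise for y) from a trajectory. The displacement covariance model
#' assumes uniform sampling, so trajectories with frame gaps are rejected.
#'
#' @param traj A [trajectory()] with gap-free (consecutive) frame indices.
#' @return An object of class `"displacements"`: list with `dx`, `dy`
#'   (length `n_frames - 1`, in um) and `dt` (seconds).
#' @export
displacements <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (any(diff(traj$frame) != 1L))
    stop(sprintf("trajectory '%s' has frame gaps; displacements require uniform sampling",
                 traj$id), call. = FALSE)
  structure(
    list(dx = diff(traj$x), dy = diff(traj$y), dt = traj$dt),
    class = "displacements"
  )
}

#' Convex-hull area of a trajectory
#'
#' The area explored by a molecule is summarised as the area of the convex
#' hull of all its observed positions.
#'
#' @param traj A [trajectory()].
#' @return Hull area in um^2 (>= 0). Fewer than 3 points, or all points
#'   collinear, give 0 with a warning.
#' @export
hull_area <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  pts <- unique(cbind(traj$x, traj$y))
  if (nrow(pts) < 3L) {
    warning("fewer than 3 distinct points; hull area is 0", call. = FALSE)
    return(0)
  }
  idx <- grDevices::chull(pts[, 1L], pts[, 2L])
  if (length(idx) < 3L) {
    warning("points are collinear; hull area is 0", call. = FALSE)
    return(0)
  }
  hx <- pts[idx, 1L]
  hy <- pts[idx, 2L]
  # shoelace formula on the hull polygon
  a <- abs(sum(hx * c(hy[-1L], hy[1L]) - c(hx[-1L], hx[1L]) * hy)) / 2
  if (a == 0)
    warning("points are collinear; hull area is 0", call. = FALSE)
  a
}
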