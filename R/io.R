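#' Read trajectories from a long-format CSV file
#'
#' The file must contain a header with columns `traj_id`, `frame`, `x_um`,
#' `y_um` (UTF-8, '.' decimal separator). Any additional columns are treated
#' as per-trajectory metadata: their value must be constant within each
#' `traj_id` and is stored in the trajectory's `meta` list.
#'
#' Coordinates are expected in micrometres. Trackers that emit pixel units
#' can be accommodated with `pixel_size_um`, which multiplies x and y on
#' the way in.
#'
#' @param path Path to the CSV file.
#' @param dt Frame interval in seconds, attached to every trajectory. The
#'   file format does not carry it, and it is never guessed.
#' @param pixel_size_um Optional pixel size in um; when given, coordinates
#'   are converted from pixels to um at read time.
#' @return A [trajectory_set()] with one trajectory per distinct `traj_id`,
#'   rows sorted by frame within id.
#' @seealso [write_trajectories()]
#' @export
read_trajectories <- function(path, dt, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop("empty trajectory file: ", path, call. = FALSE)
  required <- c("traj_id", "frame", "x_um", "y_um")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("trajectory CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!is.null(pixel_size_um)) {
    df$x_um <- df$x_um * pixel_size_um
    df$y_um <- df$y_um * pixel_size_um
  }
  meta_cols <- setdiff(names(df), required)
  ids <- unique(df$traj_id)
  trajs <- lapply(ids, function(id) {
    rows <- df[df$traj_id == id, , drop = FALSE]
    rows <- rows[order(rows$frame), , drop = FALSE]
    if (anyDuplicated(rows$frame))
      stop(sprintf("duplicated frame index within trajectory '%s'", id),
           call. = FALSE)
    meta <- list()
    for (mc in meta_cols) {
      vals <- unique(rows[[mc]])
      if (length(vals) != 1L)
        stop(sprintf("metadata column '%s' is not constant within trajectory '%s'",
                     mc, id), call. = FALSE)
      meta[[mc]] <- vals
    }
    trajectory(x = rows$x_um, y = rows$y_um, dt = dt,
               frame = rows$frame, id = id, meta = meta)
  })
  trajectory_set(trajs)
}

#' Write trajectories to a long-format CSV file
#'
#' Inverse of [read_trajectories()]. Rows are ordered by trajectory id then
#' frame, and coordinates are written with 17 significant digits so that a
#' write/read round trip reproduces every double bit-exactly. Scalar
#' metadata shared by all trajectories' `meta` lists is written as extra
#' columns.
#'
#' @param set A non-empty [trajectory_set()].
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_trajectories <- function(set, path) {
  stopifnot(inherits(set, "trajectory_set"))
  if (length(set) == 0L)
    stop("cannot write an empty trajectory set", call. = FALSE)
  trajs <- unclass(set)
  ord <- order(vapply(trajs, `[[`, character(1), "id"))
  trajs <- trajs[ord]
  meta_names <- unique(unlist(lapply(trajs, function(t) names(t$meta))))
  rows <- lapply(trajs, function(t) {
    df <- data.frame(traj_id = t$id, frame = t$frame,
                     x_um = sprintf("%.17g", t$x),
                     y_um = sprintf("%.17g", t$y),
                     stringsAsFactors = FALSE)
    for (mn in meta_names)
      df[[mn]] <- if (!is.null(t$meta[[mn]])) t$meta[[mn]] else NA
    df
  })
  out <- do.call(rbind, rows)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("could not write trajectories to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}
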