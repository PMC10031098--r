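#' Estimate diffusion coefficients of every trajectory by both methods
#'
#' Applies the MSD three-point fit and the maximum-likelihood estimator to
#' each trajectory of a set and collects the results in one long table.
#' Per-trajectory failures (e.g. tracks too short for one of the methods)
#' are recorded with their ids and reported, never silently dropped: the
#' failing row keeps `NA` estimates.
#'
#' @param set A non-empty [trajectory_set()] (uniform dt by construction).
#' @param R Blur coefficient passed to [fit_mle()].
#' @param control [mle_control()] settings.
#' @param group Group label used for trajectories whose `meta` carries no
#'   `group` entry.
#' @return An `"estimate_table"`: data frame with one row per
#'   (trajectory, method), columns `traj_id`, `group`,
#'   `method` ("MSD"/"MLE"), `D` (um^2/s), `secondary` (um^2 intercept for
#'   MSD, um sigma_hat for MLE), `n_frames`. The attribute `"failures"`
#'   lists failed (traj_id, method) pairs with messages.
#' @export
run_method_comparison <- function(set, R = 1 / 6, control = mle_control(),
                                  group = "all") {
  stopifnot(inherits(set, "trajectory_set"))
  if (length(set) == 0L) stop("empty trajectory set", call. = FALSE)
  trajs <- unclass(set)
  failures <- list()
  rows <- lapply(trajs, function(tr) {
    g <- if (!is.null(tr$meta$group)) tr$meta$group else group
    n <- length(tr$x)
    msd <- tryCatch(fit_msd(tr), error = function(e) e)
    mle <- tryCatch(suppressWarnings(fit_mle(tr, R = R, control = control)),
                    error = function(e) e)
    if (inherits(msd, "error"))
      failures[[length(failures) + 1L]] <<-
        list(traj_id = tr$id, method = "MSD", message = conditionMessage(msd))
    if (inherits(mle, "error"))
      failures[[length(failures) + 1L]] <<-
        list(traj_id = tr$id, method = "MLE", message = conditionMessage(mle))
    data.frame(
      traj_id = tr$id, group = g, method = c("MSD", "MLE"),
      D = c(if (inherits(msd, "error")) NA_real_ else msd$D,
            if (inherits(mle, "error")) NA_real_ else mle$D_hat),
      secondary = c(if (inherits(msd, "error")) NA_real_ else msd$intercept,
                    if (inherits(mle, "error")) NA_real_ else mle$sigma_hat),
      n_frames = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (length(failures))
    message(sprintf("run_method_comparison: %d estimation failure(s): %s",
                    length(failures),
                    paste(vapply(failures, function(f)
                      paste0(f$traj_id, "/", f$method), character(1)),
                      collapse = ", ")))
  structure(out, failures = failures,
            class = c("estimate_table", "data.frame"))
}

#' Per-group summary statistics of diffusion estimates
#'
#' For each (group, method) cell: count, sample mean, sample SD (n - 1
#' denominator) and coefficient of variation CoV = SD / mean. Rows with
#' `NA` estimates (recorded failures) are excluded from the statistics but
#' counted in `n_failed`. The CoV is flagged `NA` when the mean is 0 and
#' the SD is `NA` for singleton groups.
#'
#' @param table An `"estimate_table"` from [run_method_comparison()], or
#'   any data frame with columns `group`, `method`, `D`.
#' @return A data frame with columns `group`, `method`, `n`, `n_failed`,
#'   `mean`, `sd`, `cov`.
#' @export
summarize_groups <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("group", "method", "D") %in% names(table)))
  if (nrow(table) == 0L) stop("empty estimate table", call. = FALSE)
  cells <- unique(table[, c("group", "method")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- table$group == cells$group[i] & table$method == cells$method[i]
    d <- table$D[sel]
    ok <- d[!is.na(d)]
    n <- length(ok)
    m <- if (n > 0L) mean(ok) else NA_real_
    s <- if (n > 1L) stats::sd(ok) else NA_real_
    data.frame(group = cells$group[i], method = cells$method[i],
               n = n, n_failed = sum(is.na(d)), mean = m, sd = s,
               cov = if (!is.na(s) && !is.na(m) && m != 0) s / m else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-sample Kolmogorov-Smirnov comparison of diffusion estimates
#'
#' Two-sided two-sample KS test between two vectors of per-trajectory
#' diffusion coefficients; the exact small-sample p-value is used whenever
#' `stats::ks.test` can compute it (no ties, moderate n).
#'
#' @param a,b Numeric vectors of D estimates, each of length >= 2.
#' @return The p-value, with the KS statistic attached as attribute
#'   `"statistic"`.
#' @export
compare_groups_ks <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples need at least 2 values", call. = FALSE)
  ht <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  structure(unname(ht$p.value), statistic = unname(ht$statistic))
}

#' Histogram of trajectory lengths
#'
#' Counts trajectory lengths (in frames) into right-closed bins
#' `(edge_i, edge_{i+1}]`.
#'
#' @param set A non-empty [trajectory_set()].
#' @param bin_edges Increasing numeric vector of bin edges covering all
#'   lengths.
#' @return Data frame with `bin_lo`, `bin_hi`, `count`; counts sum to the
#'   number of trajectories.
#' @export
length_histogram <- function(set, bin_edges) {
  stopifnot(inherits(set, "trajectory_set"), length(set) > 0L,
            length(bin_edges) >= 2L, !is.unsorted(bin_edges, strictly = TRUE))
  lens <- vapply(unclass(set), function(t) length(t$x), integer(1))
  h <- graphics::hist(lens, breaks = bin_edges, plot = FALSE, right = TRUE)
  data.frame(bin_lo = bin_edges[-length(bin_edges)],
             bin_hi = bin_edges[-1L], count = h$counts)
}

#' Simulation study comparing MSD and MLE across conditions
#'
#' For every combination of true diffusion coefficient and trajectory
#' length, simulates `n_traj` blurred, noisy Brownian trajectories,
#' estimates D for each by both methods, and summarises each
#' (condition, method) group. This is the machinery behind mean/SD-versus-
#' length and CoV-versus-length comparisons of the two estimators.
#'
#' @param D_values True diffusion coefficients (um^2/s).
#' @param lengths Trajectory lengths in frames.
#' @param eps Localization error in um (per-axis SD). Default 0.1 (100 nm).
#' @param dt Frame time in seconds. Default 0.033.
#' @param n_traj Trajectories per condition.
#' @param seed Master seed; every cell derives its own substream.
#' @param blur Simulate motion blur (default TRUE) with `n_substeps`.
#' @param n_substeps Blur discretisation.
#' @param R Blur coefficient assumed by the MLE (default 1/6).
#' @param control [mle_control()] settings.
#' @return An object of class `"sim_study"`: list with `summary` (one row
#'   per condition and method: `D_true`, `n_frames`, `method`, `n`,
#'   `n_failed`, `mean`, `sd`, `cov`, `se`), `estimates` (the pooled
#'   per-trajectory estimate table) and `config` (the resolved study
#'   parameters).
#' @export
run_simulation_study <- function(D_values, lengths, eps = 0.1, dt = 0.033,
                                 n_traj = 200L, seed = 1L, blur = TRUE,
                                 n_substeps = 100L, R = 1 / 6,
                                 control = mle_control()) {
  grid <- expand.grid(D_true = D_values, n_frames = lengths,
                      KEEP.OUT.ATTRS = FALSE)
  est_all <- vector("list", nrow(grid))
  sum_all <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell_seed <- (as.double(seed) * 1009 + i * 9973) %% 2147483629
    cfg <- sim_config(D_true = grid$D_true[i], eps = eps, dt = dt,
                      n_frames = grid$n_frames[i], n_traj = n_traj,
                      blur = blur, n_substeps = n_substeps,
                      seed = as.integer(cell_seed))
    set <- simulate_set(cfg)
    tab <- suppressMessages(run_method_comparison(set, R = R,
                                                  control = control))
    tab$D_true <- grid$D_true[i]
    est_all[[i]] <- tab
    sm <- summarize_groups(tab)
    sm$D_true <- grid$D_true[i]
    sm$n_frames <- grid$n_frames[i]
    sum_all[[i]] <- sm
  }
  summary <- do.call(rbind, sum_all)
  summary$se <- summary$sd / sqrt(summary$n)
  summary <- summary[, c("D_true", "n_frames", "method", "n", "n_failed",
                         "mean", "sd", "cov", "se")]
  structure(
    list(summary = summary,
         estimates = do.call(rbind, est_all),
         config = list(D_values = D_values, lengths = lengths, eps = eps,
                       dt = dt, n_traj = n_traj, blur = blur,
                       n_substeps = n_substeps, R = R, seed = seed)),
    class = "sim_study"
  )
}

#' @export
print.sim_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<sim_study: %d D values x %d lengths, n = %d per cell, eps = %g um, dt = %g s>\n",
    length(cfg$D_values), length(cfg$lengths), cfg$n_traj, cfg$eps, cfg$dt))
  print(utils::head(x$summary, 12L))
  invisible(x)
}
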