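#' Plot group mean and SD of diffusion estimates versus track length
#'
#' One panel per true diffusion coefficient; points are group means with
#' mean +/- SD error bars, split by estimation method, with a dashed line
#' at the true value.
#'
#' @param study A `"sim_study"` from [run_simulation_study()].
#' @return A ggplot object.
#' @export
plot_mean_sd <- function(study) {
  stopifnot(inherits(study, "sim_study"))
  sm <- study$summary
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$n_frames, y = .data$mean,
                                   colour = .data$method)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$D_true),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             position = ggplot2::position_dodge(width = 0.1)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~D_true, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "trajectory length (frames)",
                  y = expression(hat(D) ~ (mu * m^2 / s)),
                  colour = "method")
}

#' Plot coefficient of variation of diffusion estimates versus track length
#'
#' @param study A `"sim_study"` from [run_simulation_study()].
#' @return A ggplot object.
#' @export
plot_cov <- function(study) {
  stopifnot(inherits(study, "sim_study"))
  sm <- study$summary
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$n_frames, y = .data$cov,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~D_true, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "trajectory length (frames)",
                  y = "CoV of D estimates", colour = "method")
}
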