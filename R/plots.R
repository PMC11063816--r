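#' Box plot of retrieval dependency by condition
#'
#' One box per loop x delay cell of the per-subject dependency values, with
#' the zero line of the independent model.
#'
#' @param dep Tibble from [dependency_summary()].
#' @return A ggplot object.
#' @export
plot_dependency <- function(dep) {
  check_columns(dep, c("loop", "delay", "dependency"), "`dep`")
  dep %>%
    mutate(delay = factor(.data$delay, levels = c("no_delay", "delay"),
                          labels = c("no delay", "delay"))) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$delay, y = .data$dependency,
                                 fill = .data$loop)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(0.8),
                          width = 0.6, outlier.shape = 21) +
    ggplot2::scale_fill_manual(values = c(closed = "grey35",
                                          open = "white")) +
    ggplot2::labs(x = NULL, y = "retrieval dependency\n(data - independent model)",
                  fill = "loop") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Coupling scatter with fitted slopes
#'
#' Across-subject scatter of nontarget reinstatement against the
#' hippocampal closed-vs-open contrast, per delay condition, with the
#' model-implied lines of a [fit_glmm()] fit.
#'
#' @param object A `coupling_glmm` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coupling_glmm
#' @export
autoplot.coupling_glmm <- function(object, ...) {
  d <- object$data %>%
    mutate(condition = factor(.data$delay, levels = c("no_delay", "delay"),
                              labels = c("no delay", "delay")))
  cs <- object$contrasts
  pick <- function(nm) cs$estimate[cs$contrast == nm]
  lines <- tibble(
    condition = factor(c("no delay", "delay"),
                       levels = c("no delay", "delay")),
    intercept = c(pick("intercept_nodelay"), pick("intercept_delay")),
    slope = c(pick("slope_nodelay"), pick("slope_delay"))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hipp,
                                  y = .data$nontarget_contrast)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(intercept = .data$intercept,
                                      slope = .data$slope),
                         colour = "firebrick") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "hippocampal closed - open contrast (a.u.)",
                  y = "nontarget reinstatement (closed - open, a.u.)") +
    ggplot2::theme_bw()
}

#' Leave-k-out consistency curves
#'
#' Consistency of each contrast's significance decision with the
#' full-sample analysis, as a function of the number of removed
#' participants.
#'
#' @param object A `robustness_report` from [robustness_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot robustness_report
#' @export
autoplot.robustness_report <- function(object, ...) {
  as_tibble(object) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$k, y = .data$consistency,
                                 colour = .data$contrast)) +
    ggplot2::geom_hline(yintercept = 0.9, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "participants removed (k)",
                  y = "consistency with full-sample decision") +
    ggplot2::theme_bw()
}
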