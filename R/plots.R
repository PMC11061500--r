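#' Plot methods for ABC-RF results
#'
#' `autoplot()` methods: vote fractions for a single model choice, vote
#' means with SD error bars for a replicated analysis, posterior medians
#' with 5-95% intervals for parameter estimates, and a confusion-matrix
#' heatmap for a calibration run.
#'
#' @param object a fitted result object.
#' @param ... unused.
#' @return a ggplot object.
#' @name autoplot-hybridrf
NULL

#' @rdname autoplot-hybridrf
#' @method autoplot model_choice_result
#' @export
autoplot.model_choice_result <- function(object, ...) {
  d <- object$votes
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$scenario_id),
                                  y = .data$vote)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "scenario", y = "fraction of tree votes",
                  title = sprintf("Scenario choice (selected: S%d, posterior prob. %.2f)",
                                  object$selected, object$posterior_prob)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-hybridrf
#' @method autoplot replicate_summary
#' @export
autoplot.replicate_summary <- function(object, ...) {
  d <- object$vote_summary
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$scenario_id),
                                  y = .data$mean_vote)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_vote - .data$sd_vote,
                                        ymax = .data$mean_vote + .data$sd_vote),
                           width = 0.2) +
    ggplot2::labs(x = "scenario", y = "mean vote fraction (+- SD)",
                  title = sprintf("Scenario choice over %d replicates (selected: S%d)",
                                  object$n_replicates, object$selected)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-hybridrf
#' @method autoplot param_posterior
#' @export
autoplot.param_posterior <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$parameter, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q05, ymax = .data$q95)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "posterior median (5-95% interval)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-hybridrf
#' @method autoplot calibration_result
#' @export
autoplot.calibration_result <- function(object, ...) {
  cm <- object$confusion
  d <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(cm), true = rownames(cm)),
    cols = -"true", names_to = "selected", values_to = "n")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$selected, y = .data$true,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "selected scenario", y = "true scenario",
                  title = "POD scenario confusion") +
    ggplot2::theme_minimal()
}
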