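# ggplot2 displays for paths and study results.

#' Plot a regularization path
#'
#' Group-norm trajectories against log(lambda), with the selected tuning
#' parameter marked when a selector has been applied.
#'
#' @param object A `zinb_path`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.zinb_path <- function(object, ...) {
  ids <- vapply(object$groups, `[[`, character(1), "id")
  norms <- t(apply(object$theta, 2, function(th)
    vapply(object$groups, function(g) sqrt(sum(th[g$idx]^2)), numeric(1))))
  colnames(norms) <- ids
  df <- tibble::as_tibble(norms)
  df$lambda <- object$points$lambda
  long <- tidyr::pivot_longer(df, -"lambda", names_to = "group",
                              values_to = "norm")
  long$component <- sub(":.*", "", long$group)
  pl <- ggplot2::ggplot(long, ggplot2::aes(x = log(.data$lambda),
                                           y = .data$norm,
                                           colour = .data$group)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::facet_wrap(~.data$component) +
    ggplot2::labs(x = expression(log(lambda)), y = "group norm",
                  title = paste0(object$spec$family, " path (", object$mode,
                                 " mode)")) +
    ggplot2::theme_minimal()
  if (!is.null(object$selection)) {
    pl <- pl + ggplot2::geom_vline(xintercept = log(object$selection$lambda),
                                   linetype = 2)
  }
  pl
}

#' Plot selection criteria along a path
#'
#' @param path A `zinb_path` with a selection applied (see
#'   [select_lambda()]).
#' @return A ggplot object of the criterion against log(lambda).
#' @export
plot_criterion <- function(path) {
  if (is.null(path$selection)) {
    stop("apply a selection criterion first (select_lambda)", call. = FALSE)
  }
  df <- tibble::tibble(lambda = path$points$lambda,
                       criterion = path$selection$criterion)
  ggplot2::ggplot(df, ggplot2::aes(log(.data$lambda), .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(path$selection$lambda),
                        linetype = 2) +
    ggplot2::labs(x = expression(log(lambda)),
                  y = path$selection$criterion_name) +
    ggplot2::theme_minimal()
}

#' Plot study selection metrics
#'
#' Sensitivity, specificity and MCC per penalty and component from a
#' [run_study()] summary.
#'
#' @param object A `zinb_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.zinb_study <- function(object, ...) {
  long <- object$summary |>
    tidyr::pivot_longer(cols = c("sens_count", "spec_count", "mcc_count",
                                 "sens_zero", "spec_zero", "mcc_zero"),
                        names_to = "metric", values_to = "value") |>
    tidyr::separate_wider_delim("metric", "_", names = c("metric", "component"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$penalty, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(component ~ psi, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("group selection (", object$mode, " mode)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
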