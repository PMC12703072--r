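# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted ZINB MLE
#'
#' @param x A [fit_zinb_mle()] result.
#' @param ... Unused.
#' @return Tibble with `term`, `component` (`dispersion`/`count`/`zero`) and
#'   `estimate`; the dispersion row reports `phi` on its natural scale.
#' @export
tidy.zinb_mle <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("phi", "(Intercept)",
             paste0("x", seq_along(p$beta)), "(Intercept)",
             paste0("z", seq_along(p$gamma))),
    component = c("dispersion", rep("count", 1 + length(p$beta)),
                  rep("zero", 1 + length(p$gamma))),
    estimate = c(exp(p$log_phi), p$beta0, p$beta, p$gamma0, p$gamma))
}

#' @rdname tidy.zinb_mle
#' @exportS3Method generics::glance
glance.zinb_mle <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n, npar = x$dim,
                 converged = x$converged, n_iter = x$n_iter,
                 grad_norm = x$grad_norm)
}

#' Tidy a regularization path
#'
#' @param x A `zinb_path` from [fit_path()] or [grbar_path()].
#' @param ... Unused.
#' @return The per-lambda tibble (lambda, df, true log-likelihood,
#'   surrogate RSS, active-group count), with the criterion and selection
#'   flag when a selector has been applied.
#' @exportS3Method generics::tidy
tidy.zinb_path <- function(x, ...) {
  out <- x$points
  if (!is.null(x$selection)) {
    out$criterion <- x$selection$criterion
    out$selected <- seq_len(nrow(out)) == x$selection$index
  }
  out
}

#' @rdname tidy.zinb_path
#' @exportS3Method generics::glance
glance.zinb_path <- function(x, ...) {
  base <- tibble::tibble(penalty = x$spec$family, mode = x$mode,
                         n_lambda = nrow(x$points), nobs = x$n)
  if (is.null(x$selection)) return(base)
  dplyr::bind_cols(base, tibble::tibble(
    criterion = x$selection$criterion_name,
    lambda = x$selection$lambda, df = x$selection$df,
    loglik = x$selection$loglik,
    n_active = length(x$selection$active)))
}

#' Tidy a Monte-Carlo study
#'
#' @param x A `zinb_study` from [run_study()].
#' @param ... Unused.
#' @return The per-cell summary tibble (means of selection metrics, medians
#'   of prediction metrics).
#' @exportS3Method generics::tidy
tidy.zinb_study <- function(x, ...) x$summary

#' @rdname tidy.zinb_study
#' @exportS3Method generics::glance
glance.zinb_study <- function(x, ...) {
  tibble::tibble(mode = x$mode, criterion = x$criterion,
                 n_cells = nrow(x$summary),
                 n_replicates = nrow(x$replicates),
                 n_failed = sum(x$replicates$failed))
}
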