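# Tuning-parameter selection along a regularization path.
#
# The corrected criteria evaluate the fitted coefficients on the true ZINB
# log-likelihood:
#     BIC(lambda) = -2 l(theta_lambda) + log(n) df(lambda)
#     AIC(lambda) = -2 l(theta_lambda) + 2 df(lambda)
# with df(lambda) = number of active penalized groups plus the separately
# counted unpenalized terms (two intercepts and the dispersion).
#
# The quadratic-loss criterion of the original LSA framework,
#     BIC_LSA(lambda) = Q(theta_lambda) + (log n / n) df(lambda),
# is finite everywhere (no log-singularity at RSS = 0).
#
# The legacy Gaussian-surrogate criterion,
#     BIC(lambda) = n log(RSS(lambda)/n) + log(n) df(lambda),
# is provided to reproduce its documented failure mode: because the
# unpenalized MLE fits the surrogate with RSS = 0, this criterion diverges to
# -Inf as lambda -> 0 and is always minimized at the smallest lambda on the
# path, defeating sparsity.

criterion_df <- function(path, df_convention) {
  switch(df_convention,
         groups_plus_unpenalized = path$points$df,
         nonzero_coefficients = path$points$df_coef,
         stop("unknown df convention: ", df_convention, call. = FALSE))
}

finish_selection <- function(path, crit, name, df) {
  bad <- !is.finite(crit)
  if (any(bad)) {
    warning(sum(bad), " path point(s) with non-finite criterion excluded")
    crit[bad] <- Inf
  }
  # grid is in decreasing lambda order, so the first minimum is the sparser
  # (larger-lambda) choice on ties
  idx <- which.min(crit)
  sel <- list(index = idx, lambda = path$points$lambda[idx],
              criterion = crit, criterion_name = name,
              df = df[idx], loglik = path$points$loglik[idx],
              theta = path$theta[, idx],
              active = path$active[[idx]],
              active_by_component = active_by_component(path, idx))
  class(sel) <- "zinb_selection"
  path$selection <- sel
  path
}

#' Select the tuning parameter by BIC on the true ZINB likelihood
#'
#' @param path A `zinb_path` from [fit_path()] or [grbar_path()], with the
#'   true log-likelihood recorded at every point.
#' @param data Optional [zinb_data()] (only `n` is needed; taken from the
#'   path when omitted).
#' @param df_convention `"groups_plus_unpenalized"` (default; active groups
#'   + 3) or `"nonzero_coefficients"`.
#' @return The path with a `selection` element (`index`, `lambda`,
#'   `criterion` vector, selected coefficients and active groups). Ties are
#'   broken toward the larger lambda (sparser model).
#' @export
bic_true <- function(path, data = NULL,
                     df_convention = c("groups_plus_unpenalized",
                                       "nonzero_coefficients")) {
  df_convention <- match.arg(df_convention)
  n <- if (is.null(data)) path$n else data$n
  df <- criterion_df(path, df_convention)
  crit <- -2 * path$points$loglik + log(n) * df
  finish_selection(path, crit, "bic_true", df)
}

#' Select the tuning parameter by AIC on the true ZINB likelihood
#' @inheritParams bic_true
#' @return See [bic_true()].
#' @export
aic_true <- function(path, data = NULL,
                     df_convention = c("groups_plus_unpenalized",
                                       "nonzero_coefficients")) {
  df_convention <- match.arg(df_convention)
  df <- criterion_df(path, df_convention)
  crit <- -2 * path$points$loglik + 2 * df
  finish_selection(path, crit, "aic_true", df)
}

#' Select the tuning parameter by the quadratic-loss LSA criterion
#'
#' `BIC_LSA(lambda) = Q(theta_lambda) + (log n / n) df(lambda)` with `Q` the
#' quadratic form of the surrogate built at the MLE. Finite at every path
#' point, including lambda = 0 where it equals `(log n / n) * df_full`.
#'
#' @inheritParams bic_true
#' @param surrogate Optional [build_surrogate()] object (defaults to the one
#'   stored in the path).
#' @return See [bic_true()].
#' @export
bic_lsa <- function(path, surrogate = NULL, data = NULL,
                    df_convention = c("groups_plus_unpenalized",
                                      "nonzero_coefficients")) {
  df_convention <- match.arg(df_convention)
  if (is.null(surrogate)) surrogate <- path$surrogate
  n <- if (is.null(data)) path$n else data$n
  df <- criterion_df(path, df_convention)
  Q <- unname(apply(path$theta, 2, function(th) quadratic_loss(surrogate, th)))
  crit <- Q + (log(n) / n) * df
  finish_selection(path, crit, "bic_lsa", df)
}

#' Legacy Gaussian-surrogate BIC (degenerate selector)
#'
#' `n log(RSS(lambda)/n) + log(n) df(lambda)` computed on the surrogate
#' residual sum of squares. Implemented to reproduce its failure: RSS(0) = 0
#' makes the criterion diverge to -Inf at the unpenalized end, so it is
#' minimized at the smallest lambda on any path that approaches the MLE and
#' returns an essentially unpenalized, dense model. The RSS is floored at
#' `1e-12 * n` to keep the criterion finite; floored points are flagged.
#'
#' @inheritParams bic_true
#' @return See [bic_true()]; the selection carries `n_floored`.
#' @export
bic_surrogate_legacy <- function(path, data = NULL,
                                 df_convention = c("groups_plus_unpenalized",
                                                   "nonzero_coefficients")) {
  df_convention <- match.arg(df_convention)
  n <- if (is.null(data)) path$n else data$n
  df <- criterion_df(path, df_convention)
  eps <- 1e-12 * n
  rss <- path$points$surrogate_rss
  floored <- rss < eps
  crit <- n * log(pmax(rss, eps) / n) + log(n) * df
  path <- finish_selection(path, crit, "bic_surrogate_legacy", df)
  path$selection$n_floored <- sum(floored)
  path
}

#' Select the tuning parameter along a fitted path
#'
#' Dispatcher over the implemented criteria.
#'
#' @inheritParams bic_true
#' @param criterion One of `"bic"` (true-likelihood BIC, default), `"aic"`,
#'   `"bic_lsa"`, `"bic_surrogate_legacy"`.
#' @return The path with its `selection` element filled in.
#' @export
select_lambda <- function(path, criterion = c("bic", "aic", "bic_lsa",
                                              "bic_surrogate_legacy"),
                          data = NULL,
                          df_convention = c("groups_plus_unpenalized",
                                            "nonzero_coefficients")) {
  criterion <- match.arg(criterion)
  df_convention <- match.arg(df_convention)
  switch(criterion,
         bic = bic_true(path, data, df_convention),
         aic = aic_true(path, data, df_convention),
         bic_lsa = bic_lsa(path, NULL, data, df_convention),
         bic_surrogate_legacy = bic_surrogate_legacy(path, data, df_convention))
}

#' @export
print.zinb_selection <- function(x, ...) {
  cat("<zinb_selection> ", x$criterion_name, ": lambda = ",
      format(x$lambda, digits = 4), ", df = ", x$df,
      ", logLik = ", format(x$loglik, digits = 8), "\n", sep = "")
  cat("active groups:", if (length(x$active)) paste(x$active, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
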