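# Group majorization-minimization (MM) descent on the LSA surrogate.
#
# The surrogate loss 1/2 ||y* - X* theta||^2 is quadratic with curvature
# H = X*'X*. Each sweep updates group 0 (both intercepts and log-dispersion)
# by exact unpenalized least squares on its partial residual, then each
# penalized group by a thresholding step under a quadratic majorization with
# per-group curvature equal to the largest eigenvalue of the group's block
# of H. Because X* = C is dense and square, per-block spectral constants are
# used instead of within-group orthonormalization, which would destroy the
# exact group-0 update.

solver_workspace <- function(surrogate, groups) {
  H <- surrogate$H
  d <- nrow(H)
  pen_idx <- unlist(lapply(groups, `[[`, "idx"))
  i0 <- setdiff(seq_len(d), pen_idx)
  steps <- vapply(groups, function(g) {
    B <- H[g$idx, g$idx, drop = FALSE]
    if (length(g$idx) == 1) B[1, 1] else max(eigen((B + t(B)) / 2,
                                                   symmetric = TRUE,
                                                   only.values = TRUE)$values)
  }, numeric(1))
  list(H = H, b = drop(H %*% surrogate$target), d = d, i0 = i0,
       H00 = H[i0, i0, drop = FALSE], steps = pmax(steps, 1e-12),
       yss = drop(crossprod(surrogate$target, H %*% surrogate$target)))
}

default_solver_control <- function(control = list()) {
  utils::modifyList(list(conv_tol = 1e-7, max_sweeps = 10000,
                         zero_tol = 1e-8, update_group0 = TRUE,
                         n_lambda = 100, lambda_min_ratio = 1e-3), control)
}

#' Smallest lambda with a fully sparse penalized solution
#'
#' Fits the unpenalized block (group 0) alone, then converts the residual
#' correlation of each penalized group into the smallest tuning parameter at
#' which every penalized group is thresholded to zero.
#'
#' @param surrogate A [build_surrogate()] object.
#' @param groups Penalized group layout as produced by the fitting functions:
#'   a list of lists with elements `idx` (coordinate indices) and `size`.
#' @param spec A [penalty_spec()].
#' @return Positive scalar (0, with a warning, if the penalized gradient is
#'   identically zero).
#' @export
lambda_max <- function(surrogate, groups, spec) {
  ws <- solver_workspace(surrogate, groups)
  theta <- numeric(ws$d)
  theta[ws$i0] <- solve(ws$H00, ws$b[ws$i0])
  v <- drop(ws$H %*% theta)
  w <- alasso_weights(spec, groups)
  k0 <- penalty_slope0_factor(spec)
  lams <- vapply(seq_along(groups), function(k) {
    ck <- sqrt(sum((ws$b[groups[[k]]$idx] - v[groups[[k]]$idx])^2))
    sc <- w[k] * k0 * (if (spec$group_size_scaling) sqrt(groups[[k]]$size) else 1)
    ck / sc
  }, numeric(1))
  lm <- max(lams)
  if (lm <= 0) warning("penalized gradient is zero at the null model; lambda_max = 0")
  lm
}

alasso_weights <- function(spec, groups) {
  if (spec$family == "grALASSO") {
    if (is.null(spec$adaptive_weights)) {
      stop("grALASSO requires adaptive_weights (one per penalized group); ",
           "fit_path computes them from the MLE", call. = FALSE)
    }
    stopifnot(length(spec$adaptive_weights) == length(groups))
    spec$adaptive_weights
  } else rep(1, length(groups))
}

#' Solve the penalized surrogate at one tuning-parameter value
#'
#' @inheritParams lambda_max
#' @param lambda Nonnegative tuning parameter.
#' @param warm_start Optional full parameter vector to start from.
#' @param control List: `conv_tol` (relative coefficient-change tolerance,
#'   default 1e-7), `max_sweeps` (default 10000), `zero_tol` (active-group
#'   norm threshold, 1e-8), `update_group0` (`FALSE` freezes the intercepts
#'   and dispersion at the surrogate target, emulating plug-in handling of
#'   unpenalized terms).
#' @return A list (one "path point"): `lambda`, `theta`, `active` (character
#'   ids of active penalized groups), `df` (active groups + number of
#'   unpenalized coordinates), `df_coef` (nonzero-coefficient convention),
#'   `surrogate_rss`, `n_sweeps`, `converged`.
#' @export
fit_at_lambda <- function(surrogate, groups, spec, lambda, warm_start = NULL,
                          control = list()) {
  ctl <- default_solver_control(control)
  ws <- solver_workspace(surrogate, groups)
  fit_at_lambda_ws(surrogate, groups, spec, lambda, ws, warm_start, ctl)
}

fit_at_lambda_ws <- function(surrogate, groups, spec, lambda, ws,
                             warm_start = NULL, ctl = default_solver_control()) {
  stopifnot(lambda >= 0)
  d <- ws$d
  spec_l <- spec
  spec_l$lambda <- lambda
  w <- alasso_weights(spec, groups)
  if (!is.null(warm_start)) {
    theta <- as.numeric(warm_start)
  } else {
    theta <- numeric(d)
    theta[ws$i0] <- if (ctl$update_group0) solve(ws$H00, ws$b[ws$i0]) else
      surrogate$target[ws$i0]
  }
  if (!ctl$update_group0) theta[ws$i0] <- surrogate$target[ws$i0]
  v <- drop(ws$H %*% theta)

  pen_total <- function(th) {
    s <- 0
    for (k in seq_along(groups)) {
      s <- s + penalty_value(spec_l, sqrt(sum(th[groups[[k]]$idx]^2)),
                             groups[[k]]$size, w[k])
    }
    s
  }
  objective <- function(th, vth) {
    0.5 * (sum(th * vth) - 2 * sum(th * ws$b) + ws$yss) + pen_total(th)
  }
  obj <- objective(theta, v)
  converged <- FALSE
  sweep <- 0L
  while (sweep < ctl$max_sweeps) {
    sweep <- sweep + 1L
    max_change <- 0
    if (ctl$update_group0) {
      i0 <- ws$i0
      rhs <- ws$b[i0] - v[i0] + drop(ws$H00 %*% theta[i0])
      new0 <- drop(solve(ws$H00, rhs))
      delta <- new0 - theta[i0]
      if (any(delta != 0)) {
        v <- v + drop(ws$H[, i0, drop = FALSE] %*% delta)
        theta[i0] <- new0
        max_change <- max(max_change, max(abs(delta)))
      }
    }
    for (k in seq_along(groups)) {
      idx <- groups[[k]]$idx
      st <- ws$steps[k]
      zvec <- theta[idx] + (ws$b[idx] - v[idx]) / st
      cur_norm <- sqrt(sum(theta[idx]^2))
      unew <- group_threshold(spec_l, zvec, st, weight = w[k],
                              lla_at = cur_norm)
      delta <- unew - theta[idx]
      if (any(delta != 0)) {
        v <- v + drop(ws$H[, idx, drop = FALSE] %*% delta)
        theta[idx] <- unew
        max_change <- max(max_change, max(abs(delta)))
      }
    }
    new_obj <- objective(theta, v)
    if (new_obj > obj + 1e-8 * (1 + abs(obj))) {
      stop("internal_error: MM objective increased (", format(obj),
           " -> ", format(new_obj), "); majorization is broken", call. = FALSE)
    }
    obj <- new_obj
    if (max_change <= ctl$conv_tol * max(1, max(abs(theta)))) {
      converged <- TRUE
      break
    }
  }
  path_point(theta, lambda, groups, ws, ctl, converged, sweep)
}

path_point <- function(theta, lambda, groups, ws, ctl, converged, sweeps) {
  norms <- vapply(groups, function(g) sqrt(sum(theta[g$idx]^2)), numeric(1))
  active <- which(norms > ctl$zero_tol)
  rss <- max(0, sum(theta * drop(ws$H %*% theta)) - 2 * sum(theta * ws$b) + ws$yss)
  nz_coef <- sum(vapply(groups[active], function(g)
    sum(abs(theta[g$idx]) > 0), numeric(1)))
  list(lambda = lambda, theta = theta,
       active = vapply(groups, `[[`, character(1), "id")[active],
       group_norms = norms,
       df = length(active) + length(ws$i0),
       df_coef = nz_coef + length(ws$i0),
       surrogate_rss = rss, n_sweeps = sweeps, converged = converged)
}

#' Regularization path of one-step LSA group-penalized fits
#'
#' Fits the unpenalized ZINB MLE, builds the quadratic surrogate at it, lays
#' a log-spaced grid of tuning parameters from [lambda_max()] down to
#' `lambda_min_ratio * lambda_max`, and solves each point with warm starts.
#' The true ZINB log-likelihood is recorded at every point so selection
#' criteria can be evaluated on the original model.
#'
#' @param data A [zinb_data()] object.
#' @param spec A [penalty_spec()] (`grBAR` has its own path function,
#'   [grbar_path()]).
#' @param control Solver control list; additionally `n_lambda` (default 100)
#'   and `lambda_min_ratio` (default 1e-3). Set `update_group0 = FALSE` to
#'   emulate plug-in handling of intercepts and dispersion (held at their
#'   full-model MLE values during the penalized fit).
#' @param mle Optional precomputed [fit_zinb_mle()] result.
#' @return A `zinb_path` object: tibble `points` (lambda, df, loglik,
#'   surrogate_rss, ...), matrix `theta` (one column per path point), the
#'   surrogate, layout and MLE.
#' @export
fit_path <- function(data, spec, control = list(), mle = NULL) {
  stopifnot(inherits(data, "zinb_data"), inherits(spec, "penalty_spec"))
  if (spec$family == "grBAR") {
    return(grbar_path(data, control = control, mle = mle))
  }
  ctl <- default_solver_control(control)
  if (is.null(mle)) mle <- fit_zinb_mle(data)
  H <- stabilize_information(observed_information(mle$theta, data), quiet = TRUE)
  surrogate <- build_surrogate(mle$theta, H, target = mle$theta)
  groups <- group_layout(data)
  if (spec$family == "grALASSO" && is.null(spec$adaptive_weights)) {
    spec$adaptive_weights <- vapply(groups, function(g)
      1 / max(sqrt(sum(mle$theta[g$idx]^2)), 1e-8), numeric(1))
  }
  lmax <- lambda_max(surrogate, groups, spec)
  lgrid <- exp(seq(log(lmax), log(lmax * ctl$lambda_min_ratio),
                   length.out = ctl$n_lambda))
  ws <- solver_workspace(surrogate, groups)
  pts <- vector("list", length(lgrid))
  warm <- NULL
  for (j in seq_along(lgrid)) {
    pts[[j]] <- fit_at_lambda_ws(surrogate, groups, spec, lgrid[j], ws,
                                 warm_start = warm, ctl = ctl)
    warm <- pts[[j]]$theta
  }
  new_zinb_path(pts, data, spec, surrogate, groups, mle,
                mode = if (ctl$update_group0) "corrected" else "legacy")
}

new_zinb_path <- function(pts, data, spec, surrogate, groups, mle, mode) {
  loglik <- vapply(pts, function(pp)
    tryCatch(zinb_loglik(pp$theta, data), error = function(e) -Inf),
    numeric(1))
  points <- tibble::tibble(
    lambda = vapply(pts, `[[`, numeric(1), "lambda"),
    df = vapply(pts, `[[`, numeric(1), "df"),
    df_coef = vapply(pts, `[[`, numeric(1), "df_coef"),
    loglik = loglik,
    surrogate_rss = vapply(pts, `[[`, numeric(1), "surrogate_rss"),
    n_active = vapply(pts, function(pp) length(pp$active), integer(1)),
    n_sweeps = vapply(pts, function(pp) as.integer(pp$n_sweeps), integer(1)),
    converged = vapply(pts, `[[`, logical(1), "converged"))
  theta <- vapply(pts, `[[`, numeric(length(pts[[1]]$theta)), "theta")
  structure(list(points = points, theta = theta,
                 active = lapply(pts, `[[`, "active"),
                 spec = spec, surrogate = surrogate, groups = groups,
                 mle = mle, n = data$n, mode = mode, selection = NULL),
            class = "zinb_path")
}

#' @export
print.zinb_path <- function(x, ...) {
  cat("<zinb_path> ", x$spec$family, " (", x$mode, " mode), ",
      nrow(x$points), " lambda values\n", sep = "")
  print(utils::head(x$points, 4))
  if (!is.null(x$selection)) {
    cat("selected:", x$selection$criterion_name, "at lambda =",
        format(x$selection$lambda, digits = 4), "df =",
        x$selection$df, "\n")
  }
  invisible(x)
}

# active penalized-group labels per component at a path point index
active_by_component <- function(path, index) {
  ids <- path$active[[index]]
  parse_ids <- function(prefix) {
    as.integer(sub(paste0(prefix, ":"), "", ids[startsWith(ids, prefix)]))
  }
  list(count = parse_ids("count"), zero = parse_ids("zero"))
}
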