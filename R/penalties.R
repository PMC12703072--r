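# Group penalty families, evaluated on the Euclidean norm t = ||theta_Ak||
# of a coefficient group, and the corresponding group thresholding
# (proximal) operators used inside the MM sweeps.
#
# By default the tuning parameter is scaled by sqrt(group size), the usual
# group-penalty convention, so groups of different sizes are penalized
# comparably; disable with group_size_scaling = FALSE.

PENALTY_FAMILIES <- c("grLASSO", "grALASSO", "grSCAD", "grMCP", "grSELO",
                      "grSICA", "grBAR", "ridge", "none")

#' Specify a group penalty
#'
#' @param family One of `"grLASSO"`, `"grALASSO"`, `"grSCAD"`, `"grMCP"`,
#'   `"grSELO"`, `"grSICA"`, `"grBAR"`, `"ridge"`, `"none"`.
#' @param lambda Nonnegative tuning parameter (set per path point by the
#'   solver; the value here is a default).
#' @param shape Family-specific shape: SCAD `a` (> 2, default 3.7), MCP `a`
#'   (> 1, default 3), SELO/SICA `tau` (> 0, default 0.01). Ignored
#'   otherwise.
#' @param adaptive_weights Optional positive per-group weights for
#'   `grALASSO`; when omitted they are computed as the inverse group norms of
#'   the unpenalized MLE.
#' @param group_size_scaling Multiply lambda by `sqrt(group size)` (default
#'   `TRUE`).
#' @return A `penalty_spec` object.
#' @export
penalty_spec <- function(family, lambda = 0, shape = NULL,
                         adaptive_weights = NULL, group_size_scaling = TRUE) {
  family <- match.arg(family, PENALTY_FAMILIES)
  if (is.null(shape)) {
    shape <- switch(family, grSCAD = 3.7, grMCP = 3, grSELO = 0.01,
                    grSICA = 0.01, NA_real_)
  }
  if (lambda < 0) stop("invalid_lambda: lambda must be >= 0", call. = FALSE)
  if (family == "grSCAD" && shape <= 2) stop("invalid_shape: SCAD a must be > 2", call. = FALSE)
  if (family == "grMCP" && shape <= 1) stop("invalid_shape: MCP a must be > 1", call. = FALSE)
  if (family %in% c("grSELO", "grSICA") && shape <= 0) {
    stop("invalid_shape: SELO/SICA tau must be > 0", call. = FALSE)
  }
  if (!is.null(adaptive_weights) &&
      (any(!is.finite(adaptive_weights)) || any(adaptive_weights <= 0))) {
    stop("invalid_weights: adaptive weights must be finite and > 0", call. = FALSE)
  }
  structure(list(family = family, lambda = lambda, shape = shape,
                 adaptive_weights = adaptive_weights,
                 group_size_scaling = isTRUE(group_size_scaling)),
            class = "penalty_spec")
}

# effective lambda for a group: base lambda, sqrt(m) scaling, adaptive weight
lambda_effective <- function(spec, lambda, group_size, weight = 1) {
  lam <- lambda * weight
  if (spec$group_size_scaling) lam <- lam * sqrt(group_size)
  lam
}

# scalar penalty f(t; lam, shape) on the group norm t (lam already effective)
penalty_scalar <- function(family, t, lam, shape) {
  switch(family,
    grLASSO = ,
    grALASSO = lam * t,
    grSCAD = {
      a <- shape
      ifelse(t <= lam, lam * t,
             ifelse(t <= a * lam,
                    (2 * a * lam * t - t^2 - lam^2) / (2 * (a - 1)),
                    lam^2 * (a + 1) / 2))
    },
    grMCP = {
      a <- shape
      ifelse(t <= a * lam, lam * t - t^2 / (2 * a), a * lam^2 / 2)
    },
    grSELO = (lam / log(2)) * log(t / (t + shape) + 1),
    grSICA = lam * (shape + 1) * t / (t + shape),
    ridge = lam * t^2,
    none = 0,
    stop("penalty_scalar not defined for family ", family, call. = FALSE)
  )
}

# derivative f'(t) of the scalar penalty (lam effective); used for the
# local-linear-approximation weights of SELO/SICA and for lambda_max
penalty_scalar_deriv <- function(family, t, lam, shape) {
  switch(family,
    grLASSO = ,
    grALASSO = rep(lam, length(t)),
    grSCAD = {
      a <- shape
      ifelse(t <= lam, lam, ifelse(t <= a * lam, (a * lam - t) / (a - 1), 0))
    },
    grMCP = pmax(lam - t / shape, 0),
    grSELO = (lam / log(2)) * shape / ((2 * t + shape) * (t + shape)),
    grSICA = lam * (shape + 1) * shape / (t + shape)^2,
    stop("derivative not defined for family ", family, call. = FALSE)
  )
}

# ratio f'(0)/lam_effective: converts a KKT bound into a lambda_max
penalty_slope0_factor <- function(spec) {
  switch(spec$family,
    grSELO = 1 / (spec$shape * log(2)),
    grSICA = (spec$shape + 1) / spec$shape,
    1)
}

#' Evaluate a group penalty at a group norm
#'
#' @param spec A [penalty_spec()].
#' @param group_norm Euclidean norm of the coefficient group (>= 0).
#' @param group_size Number of coefficients in the group.
#' @param weight Adaptive weight for this group (`grALASSO`; default 1).
#' @return Nonnegative penalty value; 0 at `group_norm = 0` and nondecreasing.
#' @export
penalty_value <- function(spec, group_norm, group_size = 1, weight = 1) {
  stopifnot(inherits(spec, "penalty_spec"), all(group_norm >= 0))
  lam <- lambda_effective(spec, spec$lambda, group_size, weight)
  penalty_scalar(spec$family, group_norm, lam, spec$shape)
}

#' Group thresholding (proximal) operator
#'
#' Returns `argmin_u (step/2) ||u - z||^2 + f(||u||)` for the group penalty
#' `f`. The minimizer is parallel to `z`, so the problem reduces to a scalar
#' one on the norm: group soft-thresholding for grLASSO/grALASSO, the
#' firm-thresholding forms for grSCAD/grMCP (solved exactly by evaluating the
#' piecewise-quadratic profile at its regime stationary points and
#' boundaries), and for the nonconvex grSELO/grSICA a one-step
#' local-linear-approximation: soft-thresholding with slope `f'(||z||)`.
#'
#' @param spec A [penalty_spec()] carrying `lambda` and `shape`.
#' @param z Unpenalized group solution (numeric vector).
#' @param step Positive curvature constant of the quadratic majorization.
#' @param weight Adaptive weight (grALASSO).
#' @param lla_at Optional norm at which to take the SELO/SICA linearization
#'   slope (the solver passes the current iterate's group norm, the proper MM
#'   majorization point); defaults to `||z||`.
#' @return Numeric vector of the same length as `z`.
#' @export
group_threshold <- function(spec, z, step, weight = 1, lla_at = NULL) {
  stopifnot(inherits(spec, "penalty_spec"), step > 0)
  t <- sqrt(sum(z^2))
  m <- length(z)
  lam <- lambda_effective(spec, spec$lambda, m, weight)
  if (t == 0 || spec$family == "none" || lam == 0) {
    v <- if (spec$family == "ridge" && lam > 0) step * t / (step + 2 * lam) else t
    if (t == 0) return(z * 0)
    return((v / t) * z)
  }
  v <- switch(spec$family,
    grLASSO = ,
    grALASSO = max(0, t - lam / step),
    grSCAD = prox_piecewise_scad(t, lam, spec$shape, step),
    grMCP = prox_piecewise_mcp(t, lam, spec$shape, step),
    grSELO = ,
    grSICA = {
      at <- if (is.null(lla_at)) t else lla_at
      slope <- penalty_scalar_deriv(spec$family, at, lam, spec$shape)
      max(0, t - slope / step)
    },
    ridge = step * t / (step + 2 * lam),
    stop("no thresholding operator for family ", spec$family,
         " (grBAR is solved by ridge matrix iteration)", call. = FALSE)
  )
  (v / t) * z
}

# exact scalar prox of SCAD / MCP under curvature `step`: evaluate the
# piecewise objective at every regime's clipped stationary point and at the
# regime boundaries, take the argmin. Robust for any step > 0.
prox_piecewise_scad <- function(t, lam, a, step) {
  h <- function(v) step / 2 * (v - t)^2 + penalty_scalar("grSCAD", v, lam, a)
  cand <- c(0, min(max(t - lam / step, 0), lam), lam, a * lam, max(t, a * lam))
  den <- step * (a - 1) - 1
  if (abs(den) > 1e-12) {
    v2 <- (step * (a - 1) * t - a * lam) / den
    cand <- c(cand, min(max(v2, lam), a * lam))
  }
  cand[which.min(h(cand))]
}

prox_piecewise_mcp <- function(t, lam, a, step) {
  h <- function(v) step / 2 * (v - t)^2 + penalty_scalar("grMCP", v, lam, a)
  cand <- c(0, a * lam, max(t, a * lam))
  den <- a * step - 1
  if (abs(den) > 1e-12) {
    v1 <- a * (step * t - lam) / den
    cand <- c(cand, min(max(v1, 0), a * lam))
  }
  cand[which.min(h(cand))]
}

#' Broken-adaptive-ridge group weight
#'
#' Weight `1 / ||previous||^2` used in the ridge reweighting of the grBAR
#' iteration; `+Inf` (the group is frozen at zero and deleted) once the
#' previous iterate's group norm falls below the deletion tolerance.
#'
#' @param previous_group_estimate Numeric vector, the group's coefficients at
#'   the previous iteration.
#' @param delete_tol Norm below which the group is deleted (default 1e-6).
#' @return Nonnegative scalar or `Inf`.
#' @export
bar_weight <- function(previous_group_estimate, delete_tol = 1e-6) {
  nrm <- sqrt(sum(previous_group_estimate^2))
  if (nrm < delete_tol) Inf else 1 / nrm^2
}
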