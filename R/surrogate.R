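# One-step least-squares approximation (LSA) of the ZINB log-likelihood.
# With H the observed information at the expansion point and C its symmetric
# square root (H = C'C), the pseudo-design is X* = C and the pseudo-response
# y* = C %*% target, so that 1/2 ||y* - X* theta||^2 equals the quadratic
# expansion 1/2 (theta - target)' H (theta - target). The unpenalized
# least-squares solution is exactly `target` with zero residual.

#' Build the quadratic (LSA) surrogate
#'
#' @param theta_exp Full parameter vector at which the expansion is taken
#'   (ordering `(log_phi, beta0, beta, gamma0, gamma)`; dispersion on the log
#'   scale).
#' @param H Symmetric positive-definite information matrix at `theta_exp`.
#' @param target The vector reproduced exactly by the unpenalized surrogate
#'   fit. For the one-step LSA this is the MLE (= `theta_exp`); the iterative
#'   grBAR scheme passes the Newton-step point instead.
#' @return An object of class `zinb_surrogate` with elements `theta_exp`,
#'   `H`, `C` (symmetric square root), `X_star` (= `C`), `y_star`
#'   (= `C %*% target`), `target` and `coord_note`.
#' @export
build_surrogate <- function(theta_exp, H, target = theta_exp) {
  d <- length(theta_exp)
  stopifnot(is.matrix(H), nrow(H) == d, ncol(H) == d, length(target) == d)
  if (max(abs(H - t(H))) > 1e-8 * max(abs(H))) {
    stop("asymmetric_information: H must be symmetric", call. = FALSE)
  }
  ee <- eigen((H + t(H)) / 2, symmetric = TRUE)
  tol <- 1e-10 * max(abs(ee$values))
  if (min(ee$values) < -tol) {
    stop("indefinite_information: H has a negative eigenvalue (",
         format(min(ee$values), digits = 3), "); ridge-stabilize it first ",
         "(see stabilize_information)", call. = FALSE)
  }
  C <- ee$vectors %*% (sqrt(pmax(ee$values, 0)) * t(ee$vectors))
  C <- (C + t(C)) / 2
  structure(list(theta_exp = as.numeric(theta_exp), H = (H + t(H)) / 2,
                 C = C, X_star = C, y_star = drop(C %*% target),
                 target = as.numeric(target),
                 coord_note = "dispersion coordinate is log_phi"),
            class = "zinb_surrogate")
}

#' Quadratic LSA loss
#'
#' Evaluates `Q(theta) = (theta - target)' H (theta - target)`, the quadratic
#' form of the surrogate; equals `||y* - X* theta||^2` and is zero exactly at
#' the target.
#'
#' @param surrogate A [build_surrogate()] object.
#' @param theta Full parameter vector.
#' @return Nonnegative scalar.
#' @export
quadratic_loss <- function(surrogate, theta) {
  d <- length(surrogate$target)
  if (length(theta) != d) {
    stop("dimension_mismatch: theta has length ", length(theta),
         ", surrogate dimension is ", d, call. = FALSE)
  }
  delta <- unname(theta - surrogate$target)
  max(0, as.numeric(crossprod(delta, surrogate$H %*% delta)))
}

# residual sum of squares on the surrogate at theta
surrogate_rss <- function(surrogate, theta) quadratic_loss(surrogate, theta)
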