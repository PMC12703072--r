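# ZINB probability model: pmf, log-likelihood, analytic gradient and observed
# information in the (log_phi, beta0, beta, gamma0, gamma) parameterization,
# and unpenalized maximum likelihood via Newton's method with line search.
#
# Mixture: Pr(Y=0)   = p + (1-p) (phi/(mu+phi))^phi
#          Pr(Y=y>0) = (1-p) NB(y; mu, phi)
# with log mu = x'beta(full), logit p = z'gamma(full). The dispersion is
# carried as log_phi so the parameter space is unconstrained.

# linear predictors and common per-observation quantities
zinb_linpred <- function(theta, data) {
  ix <- theta_index(data)
  bfull <- theta[c(ix$beta0, ix$beta)]
  gfull <- theta[c(ix$gamma0, ix$gamma)]
  eta <- drop(data$X %*% bfull)
  zeta <- drop(data$Z %*% gfull)
  if (any(!is.finite(eta)) || any(!is.finite(zeta))) {
    bad <- which(!is.finite(eta) | !is.finite(zeta))[1]
    stop("nonfinite_linear_predictor: row ", bad, call. = FALSE)
  }
  list(eta = eta, zeta = zeta, log_phi = theta[ix$log_phi])
}

# log(mu + phi) computed stably from eta = log mu and lphi = log phi
log_mu_plus_phi <- function(eta, lphi) {
  m <- pmax(eta, lphi)
  m + log(exp(eta - m) + exp(lphi - m))
}

#' Structural-zero probability and total zero mass
#'
#' Evaluates, for one observation, the structural-zero probability
#' `p = logistic(z'gamma)` and the total probability of observing a zero,
#' `p + (1-p) (phi/(mu+phi))^phi`.
#'
#' @param params A [zinb_params()] object.
#' @param x_row,z_row Covariate rows including the leading 1 for the
#'   intercept.
#' @return Named numeric vector with elements `p` (structural-zero
#'   probability) and `pr_zero` (total zero probability), both in \[0, 1\].
#' @export
#' @examples
#' pr <- zinb_zero_prob(zinb_params(beta0 = 0, gamma0 = 0, log_phi = 0), 1, 1)
#' pr["pr_zero"]  # 0.5 + 0.5 * (1/2) = 0.75
zinb_zero_prob <- function(params, x_row, z_row) {
  eta <- sum(x_row * c(params$beta0, params$beta))
  zeta <- sum(z_row * c(params$gamma0, params$gamma))
  if (!is.finite(eta) || !is.finite(zeta)) {
    stop("nonfinite_linear_predictor: row 1", call. = FALSE)
  }
  lphi <- params$log_phi
  phi <- exp(lphi)
  p <- stats::plogis(zeta)
  lse <- log_mu_plus_phi(eta, lphi)
  la <- stats::plogis(zeta, log.p = TRUE)          # log p
  lb <- stats::plogis(-zeta, log.p = TRUE) + phi * (lphi - lse)
  m <- pmax(la, lb)
  pr0 <- exp(m + log(exp(la - m) + exp(lb - m)))
  c(p = p, pr_zero = min(pr0, 1))
}

#' ZINB log-likelihood
#'
#' Sum of log probabilities of the observed counts under the zero-inflated
#' negative binomial mixture. The zero branch is evaluated in a
#' log-sum-exp-stable mixture form. Returns `-Inf` (not an error) if an
#' observed count has probability zero.
#'
#' @param params A [zinb_params()] object or a full parameter vector in the
#'   documented ordering `(log_phi, beta0, beta, gamma0, gamma)`.
#' @param data A [zinb_data()] object.
#' @return Scalar log-likelihood.
#' @export
zinb_loglik <- function(params, data) {
  theta <- as_theta(params, data)
  lp <- zinb_linpred(theta, data)
  eta <- lp$eta; zeta <- lp$zeta; lphi <- lp$log_phi
  phi <- exp(lphi)
  y <- data$y
  lse <- log_mu_plus_phi(eta, lphi)
  l1mp <- stats::plogis(-zeta, log.p = TRUE)       # log(1-p)
  ll <- numeric(data$n)
  z0 <- y == 0
  if (any(z0)) {
    la <- stats::plogis(zeta[z0], log.p = TRUE)
    lb <- l1mp[z0] + phi * (lphi - lse[z0])
    m <- pmax(la, lb)
    ll[z0] <- m + log(exp(la - m) + exp(lb - m))
  }
  if (any(!z0)) {
    yi <- y[!z0]
    ll[!z0] <- l1mp[!z0] + lgamma(phi + yi) - lgamma(yi + 1) - lgamma(phi) +
      yi * (eta[!z0] - lse[!z0]) + phi * (lphi - lse[!z0])
  }
  sum(ll)
}

# Per-observation first and second derivative weights of the log-likelihood
# with respect to (eta, zeta, xi), xi = log_phi. Used by both the gradient
# and the observed information.
zinb_deriv_weights <- function(theta, data) {
  lp <- zinb_linpred(theta, data)
  eta <- lp$eta; zeta <- lp$zeta; lphi <- lp$log_phi
  phi <- exp(lphi)
  y <- data$y
  n <- data$n
  mu <- exp(eta)
  lse <- log_mu_plus_phi(eta, lphi)
  denom <- exp(lse)                      # mu + phi
  mu_frac <- exp(eta - lse)              # mu/(mu+phi)
  phi_frac <- exp(lphi - lse)            # phi/(mu+phi)
  p <- stats::plogis(zeta)
  u <- stats::plogis(-zeta)              # 1 - p

  w_eta <- w_zeta <- w_xi <- numeric(n)
  h_ee <- h_zz <- h_ez <- h_ex <- h_zx <- h_xx <- numeric(n)

  z0 <- y == 0
  if (any(z0)) {
    i <- which(z0)
    r <- exp(phi * (lphi - lse[i]))      # (phi/(mu+phi))^phi in (0,1]
    s <- p[i] + u[i] * r                 # zero probability
    D <- lphi - lse[i] + mu_frac[i]
    L_e <- -phi * mu_frac[i]
    L_x <- phi * D
    L_ee <- -phi * mu_frac[i] * phi_frac[i]
    L_ex <- -phi * mu_frac[i]^2
    L_xx <- phi * (D + mu_frac[i]^2)
    s_e <- u[i] * r * L_e
    s_x <- u[i] * r * L_x
    s_z <- (1 - r) * p[i] * u[i]
    s_ee <- u[i] * r * (L_e^2 + L_ee)
    s_ex <- u[i] * r * (L_e * L_x + L_ex)
    s_xx <- u[i] * r * (L_x^2 + L_xx)
    s_ze <- -p[i] * u[i] * r * L_e
    s_zx <- -p[i] * u[i] * r * L_x
    s_zz <- (1 - r) * p[i] * u[i] * (u[i] - p[i])
    w_eta[i] <- s_e / s
    w_zeta[i] <- s_z / s
    w_xi[i] <- s_x / s
    h_ee[i] <- s_ee / s - (s_e / s)^2
    h_ez[i] <- s_ze / s - (s_z / s) * (s_e / s)
    h_ex[i] <- s_ex / s - (s_e / s) * (s_x / s)
    h_zz[i] <- s_zz / s - (s_z / s)^2
    h_zx[i] <- s_zx / s - (s_z / s) * (s_x / s)
    h_xx[i] <- s_xx / s - (s_x / s)^2
  }
  if (any(!z0)) {
    i <- which(!z0)
    yi <- y[i]
    w_eta[i] <- yi - (yi + phi) * mu_frac[i]
    w_zeta[i] <- -p[i]
    g <- digamma(phi + yi) - digamma(phi) + lphi + 1 - lse[i] -
      (yi + phi) / denom[i]
    w_xi[i] <- phi * g
    h_ee[i] <- -(yi + phi) * mu_frac[i] * phi_frac[i]
    h_zz[i] <- -p[i] * u[i]
    h_ex[i] <- phi * mu[i] * (yi - mu[i]) / denom[i]^2
    gp <- trigamma(phi + yi) - trigamma(phi) + 1 / phi - 1 / denom[i] -
      (mu[i] - yi) / denom[i]^2
    h_xx[i] <- w_xi[i] + phi^2 * gp
  }
  list(w_eta = w_eta, w_zeta = w_zeta, w_xi = w_xi,
       h_ee = h_ee, h_zz = h_zz, h_ez = h_ez, h_ex = h_ex, h_zx = h_zx,
       h_xx = h_xx)
}

# Gradient of the log-likelihood in the full theta ordering.
zinb_gradient <- function(theta, data) {
  w <- zinb_deriv_weights(theta, data)
  c(sum(w$w_xi),
    drop(crossprod(data$X, w$w_eta)),
    drop(crossprod(data$Z, w$w_zeta)))
}

# gradient and observed information from a single derivative-weight pass
zinb_score_info <- function(theta, data) {
  w <- zinb_deriv_weights(theta, data)
  g <- c(sum(w$w_xi),
         drop(crossprod(data$X, w$w_eta)),
         drop(crossprod(data$Z, w$w_zeta)))
  X <- data$X; Z <- data$Z
  d <- theta_dim(data)
  H <- matrix(0, d, d)
  ib <- 1L + seq_len(1L + data$p)
  ig <- 2L + data$p + seq_len(1L + data$q)
  H[1, 1] <- sum(w$h_xx)
  hbx <- drop(crossprod(X, w$h_ex)); H[1, ib] <- hbx; H[ib, 1] <- hbx
  hgx <- drop(crossprod(Z, w$h_zx)); H[1, ig] <- hgx; H[ig, 1] <- hgx
  H[ib, ib] <- crossprod(X, X * w$h_ee)
  H[ig, ig] <- crossprod(Z, Z * w$h_zz)
  Hbg <- crossprod(X, Z * w$h_ez)
  H[ib, ig] <- Hbg; H[ig, ib] <- t(Hbg)
  I <- -(H + t(H)) / 2
  list(gradient = g, information = I)
}

#' Observed information matrix
#'
#' Negative Hessian of the ZINB log-likelihood at `params`, in the full
#' parameter ordering `(log_phi, beta0, beta, gamma0, gamma)`. The dispersion
#' occupies the log scale, so the matrix is the curvature of the
#' unconstrained problem.
#'
#' @inheritParams zinb_loglik
#' @return Symmetric matrix of dimension `3 + p + q`.
#' @export
observed_information <- function(params, data) {
  theta <- as_theta(params, data)
  if (any(!is.finite(theta))) stop("nonfinite_parameters", call. = FALSE)
  w <- zinb_deriv_weights(theta, data)
  X <- data$X; Z <- data$Z
  Hbb <- crossprod(X, X * w$h_ee)
  Hgg <- crossprod(Z, Z * w$h_zz)
  Hbg <- crossprod(X, Z * w$h_ez)
  Hbx <- drop(crossprod(X, w$h_ex))
  Hgx <- drop(crossprod(Z, w$h_zx))
  Hxx <- sum(w$h_xx)
  d <- theta_dim(data)
  H <- matrix(0, d, d)
  ib <- 1L + seq_len(1L + data$p)
  ig <- 2L + data$p + seq_len(1L + data$q)
  H[1, 1] <- Hxx
  H[1, ib] <- Hbx; H[ib, 1] <- Hbx
  H[1, ig] <- Hgx; H[ig, 1] <- Hgx
  H[ib, ib] <- Hbb
  H[ig, ig] <- Hgg
  H[ib, ig] <- Hbg; H[ig, ib] <- t(Hbg)
  I <- -H
  dimnames(I) <- list(theta_names(data), theta_names(data))
  (I + t(I)) / 2
}

theta_names <- function(data) {
  c("log_phi", paste0("count_", colnames(data$X)), paste0("zero_", colnames(data$Z)))[
    c(1L, 1L + seq_len(1L + data$p), 2L + data$p + seq_len(1L + data$q))]
}

# Ridge-stabilize an information matrix so its smallest eigenvalue is at
# least pd_tol (default 1e-10 * trace/dim). Needed because the LSA surrogate
# requires H > 0 and near-singularity occurs with separated zero components.
stabilize_information <- function(H, pd_tol = NULL, quiet = FALSE) {
  d <- nrow(H)
  if (is.null(pd_tol)) pd_tol <- 1e-10 * sum(diag(H)) / d
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  lam_min <- min(ev)
  if (lam_min < pd_tol) {
    if (!quiet) {
      warning("information matrix stabilized: min eigenvalue ",
              format(lam_min, digits = 3), " < pd_tol; adding diagonal ridge",
              call. = FALSE)
    }
    H <- H + diag(pd_tol - min(lam_min, 0) , d)
  }
  H
}

# solve A x = b for symmetric positive (semi-)definite A, escalating a
# diagonal ridge when the system is numerically singular
solve_spd <- function(A, b) {
  out <- tryCatch(solve(A, b), error = function(e) NULL)
  eps <- 1e-10 * max(abs(diag(A)), 1)
  while (is.null(out) && eps < 1e6 * max(abs(diag(A)), 1)) {
    out <- tryCatch(solve(A + diag(eps, nrow(A)), b), error = function(e) NULL)
    eps <- eps * 100
  }
  if (is.null(out)) stop("singular_system: could not solve even with ridge",
                         call. = FALSE)
  out
}

# deterministic, cheap initial values: logistic regression of 1(y==0) on Z
# for gamma, Poisson regression of y on X for beta, log_phi = 0
zinb_init <- function(data) {
  g <- tryCatch(
    suppressWarnings(stats::glm.fit(data$Z, as.numeric(data$y == 0),
                                    family = stats::binomial())$coefficients),
    error = function(e) NULL)
  if (is.null(g) || any(!is.finite(g))) {
    g <- c(stats::qlogis(min(max(mean(data$y == 0), 0.02), 0.98)),
           rep(0, data$q))
  }
  b <- tryCatch(
    suppressWarnings(stats::glm.fit(data$X, data$y,
                                    family = stats::poisson())$coefficients),
    error = function(e) NULL)
  if (is.null(b) || any(!is.finite(b))) {
    b <- c(log(mean(data$y) + 0.1), rep(0, data$p))
  }
  # damp extreme separation in the zero-model init
  g <- pmin(pmax(g, -4), 4)
  zinb_params(beta0 = b[1], beta = b[-1], gamma0 = g[1], gamma = g[-1],
              log_phi = 0)
}

#' Unpenalized ZINB maximum likelihood
#'
#' Newton's method with backtracking line search on the full parameter vector
#' (dispersion on the log scale). When the observed information is not
#' positive definite at an iterate, a ridge-stabilized step is taken.
#'
#' @inheritParams zinb_loglik
#' @param init Optional [zinb_params()] starting point; by default the count
#'   part is initialized from a Poisson regression, the zero part from a
#'   logistic regression of `1(y == 0)` on `Z`, and `log_phi = 0`.
#' @param control List of `grad_tol` (max-norm gradient tolerance, default
#'   1e-8), `max_iter` (default 200) and `pd_tol`.
#' @return A list of class `zinb_mle`: `params` (a `zinb_params`), `theta`
#'   (packed vector), `loglik`, `converged`, `n_iter`, `grad_norm` and the
#'   `data` dimensions.
#' @export
fit_zinb_mle <- function(data, init = NULL, control = list()) {
  stopifnot(inherits(data, "zinb_data"))
  ctl <- utils::modifyList(list(grad_tol = 1e-8, max_iter = 200,
                                pd_tol = NULL), control)
  if (all(data$y == 0) || all(data$y > 0)) {
    stop("unidentified_model: y must contain at least one zero and one ",
         "positive count", call. = FALSE)
  }
  d <- theta_dim(data)
  if (data$n <= d) {   # n must exceed total design columns + 1 = d
    stop("insufficient_sample: need n > number of design columns + 1",
         call. = FALSE)
  }
  theta <- if (is.null(init)) theta_pack(zinb_init(data)) else as_theta(init, data)
  ll <- zinb_loglik(theta, data)
  converged <- FALSE
  it <- 0L
  g <- zinb_gradient(theta, data)
  while (it < ctl$max_iter) {
    it <- it + 1L
    if (max(abs(g)) <= ctl$grad_tol) { converged <- TRUE; break }
    I <- observed_information(theta, data)
    ch <- tryCatch(chol(I), error = function(e) NULL)
    if (is.null(ch)) {
      I2 <- stabilize_information(I, pd_tol = max(1e-6 * sum(diag(I)) / d, 1e-8),
                                  quiet = TRUE)
      ch <- tryCatch(chol(I2), error = function(e) NULL)
      if (is.null(ch)) {               # last resort: gradient ascent direction
        step <- g / max(1, sqrt(sum(g^2)))
      } else step <- backsolve(ch, forwardsolve(t(ch), g))
    } else {
      step <- backsolve(ch, forwardsolve(t(ch), g))
    }
    # backtracking line search on the log-likelihood
    t_ls <- 1
    ok <- FALSE
    for (h in 1:40) {
      cand <- theta + t_ls * step
      llc <- tryCatch(zinb_loglik(cand, data), error = function(e) -Inf)
      if (is.finite(llc) && llc >= ll - 1e-12) { ok <- TRUE; break }
      t_ls <- t_ls / 2
    }
    if (!ok) break
    if (abs(llc - ll) < 1e-14 && max(abs(t_ls * step)) < 1e-12) {
      theta <- cand; ll <- llc
      g <- zinb_gradient(theta, data)
      converged <- max(abs(g)) <= ctl$grad_tol
      break
    }
    theta <- cand; ll <- llc
    g <- zinb_gradient(theta, data)
  }
  if (!converged && max(abs(g)) <= ctl$grad_tol) converged <- TRUE
  out <- list(params = theta_unpack(theta, data), theta = theta,
              loglik = ll, converged = converged, n_iter = it,
              grad_norm = max(abs(g)), n = data$n, dim = d)
  class(out) <- "zinb_mle"
  out
}

#' @export
print.zinb_mle <- function(x, ...) {
  cat("<zinb_mle> logLik =", format(x$loglik, digits = 8),
      " phi =", format(exp(x$params$log_phi), digits = 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Predicted mean response
#'
#' Expected count `E(Y | x, z) = (1 - p) * mu` with `p` the structural-zero
#' probability and `mu` the NB mean.
#'
#' @param params A [zinb_params()] object.
#' @param X_new,Z_new Design matrices including the leading intercept column.
#' @return Nonnegative numeric vector of predicted means.
#' @export
predict_response <- function(params, X_new, Z_new) {
  X_new <- as.matrix(X_new); Z_new <- as.matrix(Z_new)
  if (ncol(X_new) != 1 + length(params$beta) ||
      ncol(Z_new) != 1 + length(params$gamma)) {
    stop("dimension_mismatch: new designs must match the fitted coefficient ",
         "dimensions", call. = FALSE)
  }
  mu <- exp(drop(X_new %*% c(params$beta0, params$beta)))
  p <- stats::plogis(drop(Z_new %*% c(params$gamma0, params$gamma)))
  (1 - p) * mu
}
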