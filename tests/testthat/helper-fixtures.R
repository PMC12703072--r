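# Fixtures are built in code at test time.

# small random grouped ZINB dataset with known truth
make_fixture <- function(n = 150, seed = 1, phi = 1.5,
                         beta = c(0.5, 0.3, -0.2), gamma = c(-0.5, 0.6),
                         groups_b = c(1, 2), groups_g = 1) {
  set.seed(seed)
  p <- length(beta) - 1
  q <- length(gamma) - 1
  X <- cbind(1, matrix(stats::rnorm(n * p), n))
  Z <- cbind(1, matrix(stats::rnorm(n * q), n))
  mu <- exp(drop(X %*% beta))
  pr <- stats::plogis(drop(Z %*% gamma))
  y <- ifelse(stats::runif(n) < pr, 0, stats::rnbinom(n, size = phi, mu = mu))
  # guarantee identifiability on tiny draws
  if (all(y == 0)) y[1] <- 1
  if (all(y > 0)) y[1] <- 0
  new_zinb_data(y, X, Z, groups_b, groups_g)
}

# independent log-likelihood oracle: direct pmf sum via dnbinom
oracle_loglik <- function(theta, data) {
  p <- theta_len_split(theta, data)
  mu <- exp(drop(data$X %*% c(p$beta0, p$beta)))
  pr <- stats::plogis(drop(data$Z %*% c(p$gamma0, p$gamma)))
  phi <- exp(p$log_phi)
  pmf <- ifelse(data$y == 0,
                pr + (1 - pr) * stats::dnbinom(0, size = phi, mu = mu),
                (1 - pr) * stats::dnbinom(data$y, size = phi, mu = mu))
  sum(log(pmf))
}

theta_len_split <- function(theta, data) {
  p <- data$p; q <- data$q
  list(log_phi = theta[1], beta0 = theta[2],
       beta = if (p) theta[2 + seq_len(p)] else numeric(0),
       gamma0 = theta[3 + p],
       gamma = if (q) theta[3 + p + seq_len(q)] else numeric(0))
}

# train half of a generated study-style dataset
sim_train <- function(seed, n = 200, psi = 0.3, rho = 0.4, ...) {
  des <- sim_design(n = n, psi = psi, rho = rho, seed = seed, ...)
  gen <- generate_dataset(des, 2 * n)
  d <- gen$data
  idx <- seq_len(n)
  list(train = new_zinb_data(d$y[idx], d$X[idx, , drop = FALSE],
                             d$Z[idx, , drop = FALSE],
                             d$beta_groups, d$gamma_groups),
       truth = gen$truth,
       X_test = d$X[-idx, , drop = FALSE], y_test = d$y[-idx])
}

# hand-built group layout for matrix-level solver tests
toy_layout <- function(idx_list, component = "count") {
  lapply(seq_along(idx_list), function(k)
    list(id = paste0(component, ":", k), component = component, label = k,
         idx = idx_list[[k]], size = length(idx_list[[k]])))
}

# random symmetric positive-definite matrix
random_spd <- function(d, seed = 1, cond = 10) {
  set.seed(seed)
  A <- matrix(stats::rnorm(d * d), d)
  ev <- seq(1, cond, length.out = d)
  Q <- qr.Q(qr(A))
  Q %*% (ev * t(Q))
}
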