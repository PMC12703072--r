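test_that("zero probability matches the mixture pmf", {
  # logistic(0) = 1/2 and (phi/(mu+phi))^phi = 1/2 at mu = phi = 1
  pr <- zinb_zero_prob(zinb_params(beta0 = 0, gamma0 = 0, log_phi = 0), 1, 1)
  expect_equal(unname(pr["p"]), 0.5)
  expect_equal(unname(pr["pr_zero"]), 0.75)

  # degenerate no-inflation limit: zero mass collapses to the NB zero mass
  pr <- zinb_zero_prob(zinb_params(beta0 = log(3), gamma0 = -30, log_phi = log(2)),
                       1, 1)
  expect_equal(unname(pr["pr_zero"]), dnbinom(0, size = 2, mu = 3),
               tolerance = 1e-12)

  # direct-pmf oracle at mu = 2, phi = 3, p = 0.2
  pr <- zinb_zero_prob(zinb_params(beta0 = log(2), gamma0 = qlogis(0.2),
                                   log_phi = log(3)), 1, 1)
  expect_equal(unname(pr["pr_zero"]),
               0.2 + 0.8 * dnbinom(0, size = 3, mu = 2), tolerance = 1e-12)

  expect_error(zinb_zero_prob(zinb_params(beta0 = Inf, gamma0 = 0), 1, 1),
               "nonfinite_linear_predictor")
})

test_that("log-likelihood agrees with a direct pmf-sum oracle", {
  d1 <- new_zinb_data(0, matrix(1, 1, 1), matrix(1, 1, 1),
                      integer(0), integer(0))
  expect_equal(zinb_loglik(c(0, 0, 0), d1), log(0.75), tolerance = 1e-12)

  # y = (0, 2, 5) fixture against independent Gamma-term evaluation
  X <- cbind(1, c(-0.5, 0.2, 1)); Z <- cbind(1, c(0.3, -1, 0.4))
  d3 <- new_zinb_data(c(0, 2, 5), X, Z, 1L, 1L)
  th <- c(log(1.7), 0.4, -0.3, -0.8, 0.5)
  expect_equal(zinb_loglik(th, d3), oracle_loglik(th, d3), tolerance = 1e-12)

  # several random parameter points on a larger fixture
  d <- make_fixture(n = 60, seed = 4)
  set.seed(9)
  for (i in 1:5) {
    th <- rnorm(3 + d$p + d$q, sd = 0.4)
    expect_equal(zinb_loglik(th, d), oracle_loglik(th, d), tolerance = 1e-10)
  }
})

test_that("ZINB collapses to plain NB when inflation is switched off", {
  d <- make_fixture(n = 100, seed = 2)
  th <- c(log(1.5), 0.5, 0.3, -0.2, -30, 0)
  mu <- exp(drop(d$X %*% c(0.5, 0.3, -0.2)))
  nb <- sum(dnbinom(d$y, size = 1.5, mu = mu, log = TRUE))
  expect_lt(abs(zinb_loglik(th, d) - nb), 1e-9)
})

test_that("pmf normalizes and the log-likelihood is additive and exchangeable", {
  for (cfg in list(c(p = 0.3, mu = 1, phi = 1), c(p = 0.1, mu = 8, phi = 0.7),
                   c(p = 0.6, mu = 3, phi = 4))) {
    ybig <- ceiling(cfg["mu"] + 20 * sqrt(cfg["mu"] + cfg["mu"]^2 / cfg["phi"]))
    pars <- zinb_params(beta0 = log(cfg["mu"]), gamma0 = qlogis(cfg["p"]),
                        log_phi = log(cfg["phi"]))
    total <- unname(zinb_zero_prob(pars, 1, 1)["pr_zero"])
    for (k in seq_len(ybig)) {
      dk <- new_zinb_data(k, matrix(1, 1, 1), matrix(1, 1, 1),
                          integer(0), integer(0))
      total <- total + exp(zinb_loglik(c(log(cfg["phi"]), log(cfg["mu"]),
                                         qlogis(cfg["p"])), dk))
    }
    expect_gte(total, 1 - 1e-8)
    expect_lte(total, 1 + 1e-12)
  }

  d <- make_fixture(n = 80, seed = 3)
  th <- c(log(1.2), 0.4, 0.2, -0.1, -0.6, 0.3)
  perm <- sample(d$n)
  dperm <- new_zinb_data(d$y[perm], d$X[perm, ], d$Z[perm, ],
                         d$beta_groups, d$gamma_groups)
  expect_equal(zinb_loglik(th, dperm), zinb_loglik(th, d), tolerance = 1e-12)
  d1 <- new_zinb_data(d$y[1:30], d$X[1:30, ], d$Z[1:30, ],
                      d$beta_groups, d$gamma_groups)
  d2 <- new_zinb_data(d$y[31:80], d$X[31:80, ], d$Z[31:80, ],
                      d$beta_groups, d$gamma_groups)
  expect_equal(zinb_loglik(th, d1) + zinb_loglik(th, d2),
               zinb_loglik(th, d), tolerance = 1e-10)
})

test_that("MLE agrees with a generic box-constrained optimizer", {
  for (seed in 1:5) {
    d <- make_fixture(n = 150, seed = seed)
    fit <- fit_zinb_mle(d)
    nll <- function(th) -zinb_loglik(th, d)
    gen <- optim(fit$theta + 0.05, nll, method = "L-BFGS-B",
                 control = list(factr = 10, maxit = 2000))
    expect_lte(max(abs(fit$theta - gen$par)), 1e-4)
    expect_lte(fit$loglik - (-gen$value) + 1e-8, 1e-6)  # ours at least as good
  }
})

test_that("MLE recovers the generating parameters at large n", {
  set.seed(11)
  n <- 5000
  beta <- c(1, 0.4, -0.3); gamma <- c(-0.6, 0.5)
  X <- cbind(1, matrix(rnorm(n * 2), n)); Z <- cbind(1, rnorm(n))
  mu <- exp(drop(X %*% beta)); pr <- plogis(drop(Z %*% gamma))
  y <- ifelse(runif(n) < pr, 0, rnbinom(n, size = 2, mu = mu))
  d <- new_zinb_data(y, X, Z, 1:2, 1)
  fit <- fit_zinb_mle(d)
  expect_true(fit$converged)
  se <- sqrt(diag(solve(observed_information(fit$theta, d))))
  truth <- c(log(2), beta, gamma)
  expect_true(all(abs(fit$theta - truth) <= 3 * se))
})

test_that("degenerate responses raise identifiability errors", {
  X <- cbind(1, rnorm(20))
  expect_error(fit_zinb_mle(new_zinb_data(rep(0, 20), X, X, 1, 1)),
               "unidentified_model")
  expect_error(fit_zinb_mle(new_zinb_data(rep(2, 20), X, X, 1, 1)),
               "unidentified_model")
  expect_error(fit_zinb_mle(make_fixture(n = 5, seed = 1)),
               "insufficient_sample")
})

test_that("observed information matches finite differences and is additive", {
  skip_if_not_installed("pracma")
  d <- make_fixture(n = 50, seed = 7)
  th <- c(log(1.3), 0.4, 0.2, -0.1, -0.3, 0.4)
  H <- -observed_information(th, d)
  Hfd <- pracma::hessian(function(t) zinb_loglik(t, d), th)
  expect_lt(max(abs(H - Hfd)) / max(abs(Hfd)), 1e-5)
  expect_equal(H, t(H))

  # duplicating every row doubles the information (additivity over obs)
  d2 <- new_zinb_data(c(d$y, d$y), rbind(d$X, d$X), rbind(d$Z, d$Z),
                      d$beta_groups, d$gamma_groups)
  expect_equal(observed_information(th, d2), 2 * observed_information(th, d),
               tolerance = 1e-10)

  # positive definite at an interior maximum
  fit <- fit_zinb_mle(d)
  ev <- eigen(observed_information(fit$theta, d), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("predicted response is (1 - p) * mu", {
  pars <- zinb_params(beta0 = log(4), beta = numeric(0),
                      gamma0 = 0, gamma = numeric(0), log_phi = 0)
  X1 <- matrix(1, 3, 1)
  expect_equal(predict_response(pars, X1, X1), rep(2, 3))  # p = 0.5, mu = 4
  pars$gamma0 <- -50
  expect_equal(predict_response(pars, X1, X1), rep(4, 3), tolerance = 1e-12)
  pars$gamma0 <- 50
  expect_equal(predict_response(pars, X1, X1), rep(0, 3), tolerance = 1e-12)
  expect_error(predict_response(pars, cbind(X1, X1), X1), "dimension_mismatch")
})
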