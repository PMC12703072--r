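# hand-built path objects isolate the criteria from the solver
fake_path <- function(lambda, df, loglik, rss, n = 200, theta = NULL,
                      active = NULL, surrogate = NULL) {
  k <- length(lambda)
  if (is.null(theta)) theta <- matrix(0, 3, k)
  if (is.null(active)) active <- rep(list(character(0)), k)
  structure(list(
    points = tibble::tibble(lambda = lambda, df = df, df_coef = df,
                            loglik = loglik, surrogate_rss = rss,
                            n_active = lengths(active),
                            n_sweeps = 1L, converged = TRUE),
    theta = theta, active = active, spec = penalty_spec("grLASSO"),
    surrogate = surrogate, groups = list(), mle = NULL, n = n,
    mode = "corrected", selection = NULL), class = "zinb_path")
}

test_that("true-likelihood BIC and AIC match their formulas exactly", {
  pa <- fake_path(lambda = c(3, 2, 1), df = c(4, 5, 7),
                  loglik = c(-520.3, -512.8, -509.1), rss = c(4, 2, 1))
  sel <- bic_true(pa)$selection
  expect_equal(sel$criterion,
               -2 * c(-520.3, -512.8, -509.1) + log(200) * c(4, 5, 7),
               tolerance = 1e-12)
  expect_equal(sel$index, which.min(sel$criterion))
  sela <- aic_true(pa)$selection
  expect_equal(sela$criterion,
               -2 * c(-520.3, -512.8, -509.1) + 2 * c(4, 5, 7),
               tolerance = 1e-12)
})

test_that("equal likelihoods resolve toward the sparser model", {
  pa <- fake_path(lambda = c(2, 1), df = c(5, 4), loglik = c(-100, -100),
                  rss = c(1, 1))
  expect_equal(bic_true(pa)$selection$df, 4)
  # exact criterion ties go to the larger lambda
  pb <- fake_path(lambda = c(2, 1), df = c(4, 4), loglik = c(-100, -100),
                  rss = c(1, 1))
  expect_equal(bic_surrogate_legacy(pb)$selection$lambda, 2)
})

test_that("the legacy surrogate BIC is minimized at the smallest lambda", {
  # RSS decreasing to (numerically) zero as lambda -> 0; the log term
  # diverges and swamps the df penalty
  lam <- exp(seq(log(4), log(1e-4), length.out = 30))
  rss <- lam^2 * 3
  pa <- fake_path(lambda = lam, df = seq(3, 32, length.out = 30),
                  loglik = rep(-100, 30), rss = rss)
  sel <- bic_surrogate_legacy(pa)$selection
  expect_equal(sel$index, 30)
  # criterion at the floored end lies below every other path value
  expect_true(all(sel$criterion[30] < sel$criterion[-30]))
  pa$points$surrogate_rss[30] <- 0
  sel0 <- bic_surrogate_legacy(pa)$selection
  expect_equal(sel0$index, 30)
  expect_gte(sel0$n_floored, 1)
})

test_that("the quadratic-loss criterion is finite and exact at lambda = 0", {
  H <- random_spd(3, seed = 61)
  target <- c(0.4, -1, 2)
  s <- build_surrogate(target, H, target)
  th <- cbind(c(0, 0, 0), c(0.2, -0.5, 1), target)
  pa <- fake_path(lambda = c(2, 1, 1e-9), df = c(3, 4, 5),
                  loglik = c(-120, -110, -105), rss = c(3, 1, 0),
                  theta = th, surrogate = s)
  sel <- bic_lsa(pa)$selection
  qs <- unname(apply(th, 2, function(t) quadratic_loss(s, t)))
  expect_equal(sel$criterion, qs + (log(200) / 200) * c(3, 4, 5),
               tolerance = 1e-12)
  expect_true(all(is.finite(sel$criterion)))
  # at the unpenalized end Q = 0, leaving only the df term
  expect_equal(sel$criterion[3], (log(200) / 200) * 5, tolerance = 1e-12)
})

test_that("AIC never selects a sparser model than BIC when log(n) > 2", {
  set.seed(62)
  for (i in 1:20) {
    k <- 15
    lam <- sort(runif(k, 0.01, 3), decreasing = TRUE)
    df <- cumsum(c(3, rbinom(k - 1, 1, 0.6)))       # nondecreasing as lambda drops
    ll <- -200 + cumsum(abs(rnorm(k, 2)))            # nondecreasing
    pa <- fake_path(lambda = lam, df = df, loglik = ll, rss = rev(seq_len(k)))
    expect_gte(aic_true(pa)$selection$df, bic_true(pa)$selection$df)
  }
})

test_that("non-finite path points are excluded with a warning", {
  pa <- fake_path(lambda = c(3, 2, 1), df = c(3, 4, 5),
                  loglik = c(-100, -Inf, -90), rss = c(2, 1, 0.5))
  expect_warning(sel <- bic_true(pa)$selection, "non-finite")
  expect_true(sel$index %in% c(1, 3))
})

test_that("surrogate selection degenerates while true-likelihood selection
           stays interior on fitted paths", {
  for (seed in c(71, 72, 73)) {
    fx <- sim_train(seed = seed, n = 200)
    mle <- fit_zinb_mle(fx$train)
    legacy <- fit_path(fx$train, penalty_spec("grLASSO"),
                       control = list(n_lambda = 25, update_group0 = FALSE),
                       mle = mle)
    sel_legacy <- bic_surrogate_legacy(legacy)$selection
    expect_equal(sel_legacy$index, 25)          # smallest lambda, dense model
    expect_equal(length(sel_legacy$active), 22)
    corrected <- fit_path(fx$train, penalty_spec("grLASSO"),
                          control = list(n_lambda = 25), mle = mle)
    sel_true <- bic_true(corrected,
                         df_convention = "nonzero_coefficients")$selection
    expect_lt(sel_true$index, 25)               # interior lambda
    expect_lt(length(sel_true$active), 22)      # null groups removed
  }
})
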