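# matrix-level fixtures exercise the solver directly on a synthetic
# quadratic surrogate; data-level fixtures use the study generator

test_that("lambda_max bounds the fully sparse region (KKT dead zone)", {
  # orthonormal design, one penalized group, explicit group-0 block
  d <- 5
  H <- diag(d)
  target <- c(0.5, -0.2, 1, 2, -1)   # coords 1:2 unpenalized, 3:5 one group
  s <- build_surrogate(target, H, target)
  groups <- toy_layout(list(3:5))
  sp <- penalty_spec("grLASSO", lambda = 1)
  lmax <- lambda_max(s, groups, sp)
  # identity H: group-0 fit leaves residual b_k = target_k on the group
  expect_equal(lmax, sqrt(sum(target[3:5]^2)) / sqrt(3), tolerance = 1e-10)
  hi <- fit_at_lambda(s, groups, sp, 1.01 * lmax)
  expect_length(hi$active, 0)
  lo <- fit_at_lambda(s, groups, sp, 0.95 * lmax)
  expect_gt(length(lo$active), 0)
})

test_that("the unpenalized fit recovers the surrogate target with zero RSS", {
  H <- random_spd(8, seed = 41, cond = 30)
  target <- rnorm(8)
  s <- build_surrogate(target, H, target)
  groups <- toy_layout(list(3:4, 5:8))
  pt <- fit_at_lambda(s, groups, penalty_spec("grLASSO"), 0,
                      control = list(conv_tol = 1e-11))
  expect_equal(pt$theta, target, tolerance = 1e-6)
  expect_lt(pt$surrogate_rss, 1e-10 * max(1, sum(target^2)))
})

test_that("group-lasso solutions match an independent proximal-gradient oracle", {
  set.seed(42)
  for (rep in 1:3) {
    d <- 8
    H <- random_spd(d, seed = 42 + rep, cond = 20)
    target <- rnorm(d)
    s <- build_surrogate(target, H, target)
    groups <- toy_layout(list(3:5, 6:8))
    lmax <- lambda_max(s, groups, penalty_spec("grLASSO"))
    for (lam in c(0.5, 0.15) * lmax) {
      sp <- penalty_spec("grLASSO", lambda = lam)
      pt <- fit_at_lambda(s, groups, sp, lam,
                          control = list(conv_tol = 1e-12))
      # independent oracle: full-gradient ISTA with fixed step 1/L
      b <- drop(H %*% target)
      L <- max(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
      th <- numeric(d)
      for (it in 1:20000) {
        gr <- drop(H %*% th) - b
        th <- th - gr / L
        for (g in groups) {
          nz <- sqrt(sum(th[g$idx]^2))
          thr <- lam * sqrt(g$size) / L
          th[g$idx] <- if (nz <= thr) 0 else (1 - thr / nz) * th[g$idx]
        }
      }
      obj <- function(t) 0.5 * drop(crossprod(t - target, H %*% (t - target))) +
        sum(vapply(groups, function(g)
          lam * sqrt(g$size) * sqrt(sum(t[g$idx]^2)), numeric(1)))
      expect_lt(abs(obj(pt$theta) - obj(th)), 1e-6 * max(1, abs(obj(th))))
      expect_lte(obj(pt$theta), obj(th) + 1e-8)
    }
  }
})

test_that("fitted paths satisfy the group-lasso KKT conditions", {
  fx <- sim_train(seed = 8, n = 200)
  path <- fit_path(fx$train, penalty_spec("grLASSO"),
                   control = list(n_lambda = 20, conv_tol = 1e-10))
  s <- path$surrogate
  b <- drop(s$H %*% s$target)
  scale <- max(abs(b))
  for (j in seq_len(nrow(path$points))) {
    th <- path$theta[, j]
    lam <- path$points$lambda[j]
    v <- drop(s$H %*% th)
    for (g in path$groups) {
      ck <- b[g$idx] - v[g$idx]
      nk <- sqrt(sum(th[g$idx]^2))
      if (nk > 1e-8) {
        resid <- ck - lam * sqrt(g$size) * th[g$idx] / nk
        expect_lt(max(abs(resid)), 1e-5 * scale)
      } else {
        expect_lte(sqrt(sum(ck^2)), lam * sqrt(g$size) + 1e-5 * scale)
      }
    }
    # group 0 never thresholded: intercepts and dispersion stay estimable
    i0 <- setdiff(seq_len(nrow(s$H)), unlist(lapply(path$groups, `[[`, "idx")))
    expect_gt(sqrt(sum(th[i0]^2)), 0)
  }
})

test_that("path endpoints and monotonicity behave as the surrogate predicts", {
  fx <- sim_train(seed = 9, n = 200)
  path <- fit_path(fx$train, penalty_spec("grLASSO"),
                   control = list(n_lambda = 25, lambda_min_ratio = 1e-6))
  pts <- path$points
  expect_equal(pts$n_active[1], 0L)            # fully sparse at lambda_max
  expect_lt(pts$surrogate_rss[nrow(pts)],      # exact fit as lambda -> 0
            1e-6 * max(1, sum(path$surrogate$y_star^2)))
  # RSS nondecreasing in lambda (path stored in decreasing lambda order)
  expect_true(all(diff(pts$surrogate_rss) <= 1e-8 * max(pts$surrogate_rss)))
  # active-set size nonincreasing in lambda on >= 90% of adjacent pairs
  ok <- mean(diff(pts$n_active) >= 0)
  expect_gte(ok, 0.9)
  expect_true(all(pts$converged))
})

test_that("unit-weight adaptive group lasso reproduces the group lasso path", {
  fx <- sim_train(seed = 10, n = 200)
  mle <- fit_zinb_mle(fx$train)
  p1 <- fit_path(fx$train, penalty_spec("grLASSO"),
                 control = list(n_lambda = 12), mle = mle)
  sp <- penalty_spec("grALASSO",
                     adaptive_weights = rep(1, length(p1$groups)))
  p2 <- fit_path(fx$train, sp, control = list(n_lambda = 12), mle = mle)
  expect_equal(p2$theta, p1$theta, tolerance = 1e-12)
  expect_equal(p2$points$lambda, p1$points$lambda)
})

test_that("plug-in mode freezes group 0 at the expansion point", {
  fx <- sim_train(seed = 12, n = 200)
  path <- fit_path(fx$train, penalty_spec("grLASSO"),
                   control = list(n_lambda = 8, update_group0 = FALSE))
  i0 <- setdiff(seq_len(nrow(path$surrogate$H)),
                unlist(lapply(path$groups, `[[`, "idx")))
  for (j in seq_len(nrow(path$points))) {
    expect_equal(path$theta[i0, j], path$surrogate$target[i0])
  }
  expect_identical(path$mode, "legacy")
})
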