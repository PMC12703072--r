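families_prox <- c("grLASSO", "grALASSO", "grSCAD", "grMCP", "grSELO", "grSICA")

test_that("penalty values vanish at zero and match closed forms", {
  for (fam in families_prox) {
    sp <- penalty_spec(fam, lambda = 0.7)
    expect_equal(penalty_value(sp, 0, group_size = 3), 0)
  }
  sp <- penalty_spec("grLASSO", lambda = 1, group_size_scaling = FALSE)
  expect_equal(penalty_value(sp, 2, group_size = 1), 2)
  sp <- penalty_spec("grLASSO", lambda = 1)
  expect_equal(penalty_value(sp, 2, group_size = 4), 4)  # sqrt(m) scaling
})

test_that("MCP plateau equals the integral of its derivative", {
  a <- 3; lam <- 0.8
  sp <- penalty_spec("grMCP", lambda = lam, shape = a,
                     group_size_scaling = FALSE)
  plateau <- penalty_value(sp, 10, group_size = 1)
  expect_equal(plateau, a * lam^2 / 2, tolerance = 1e-12)
  intg <- integrate(function(t) pmax(lam - t / a, 0), 0, 10,
                    rel.tol = 1e-10)$value
  expect_equal(plateau, intg, tolerance = 1e-8)
})

test_that("group soft-threshold has the documented closed form", {
  sp <- penalty_spec("grLASSO", lambda = 1, group_size_scaling = FALSE)
  # dead zone
  expect_equal(group_threshold(sp, c(0.3, 0.4), step = 1), c(0, 0))
  # ||z|| = 5, threshold 1 -> shrink by factor 4/5
  expect_equal(group_threshold(sp, c(3, 4), step = 1), c(2.4, 3.2),
               tolerance = 1e-12)
})

test_that("thresholding matches a dense 1-D numeric minimization oracle", {
  set.seed(31)
  for (i in 1:50) {
    fam <- sample(families_prox, 1)
    m <- sample(1:4, 1)
    z <- rnorm(m, sd = 2)
    lam <- runif(1, 0.05, 2)
    step <- runif(1, 0.3, 3)
    shape <- switch(fam, grSCAD = runif(1, 2.2, 5), grMCP = runif(1, 1.2, 4),
                    grSELO = runif(1, 0.005, 0.5),
                    grSICA = runif(1, 0.005, 0.5), NULL)
    w <- if (fam == "grALASSO") runif(1, 0.3, 3) else 1
    sp <- penalty_spec(fam, lambda = lam, shape = shape)
    out <- group_threshold(sp, z, step, weight = w)
    tnorm <- sqrt(sum(z^2))
    lam_eff <- lam * w * sqrt(m)
    profile <- if (fam %in% c("grSELO", "grSICA")) {
      # the operator is defined through one LLA weight at ||z||
      slope <- grpzinb:::penalty_scalar_deriv(fam, tnorm, lam_eff, sp$shape)
      function(v) step / 2 * (v - tnorm)^2 + slope * v
    } else {
      function(v) step / 2 * (v - tnorm)^2 +
        grpzinb:::penalty_scalar(fam, v, lam_eff, sp$shape)
    }
    # dense oracle: global scan + local polish
    grid <- seq(0, tnorm + 1, length.out = 4001)
    v0 <- grid[which.min(vapply(grid, profile, numeric(1)))]
    opt <- optimize(profile, c(max(0, v0 - 0.01), v0 + 0.01), tol = 1e-12)
    vstar <- if (profile(0) <= opt$objective) 0 else opt$minimum
    expect_equal(sqrt(sum(out^2)), vstar, tolerance = 1e-6)
    # direction preserved
    if (sqrt(sum(out^2)) > 0) {
      expect_equal(out / sqrt(sum(out^2)), z / tnorm, tolerance = 1e-10)
    }
  }
})

test_that("thresholding contracts, is monotone in lambda, and SCAD/MCP are
           unbiased beyond their plateaus", {
  set.seed(32)
  z <- c(1.5, -2, 0.7)
  for (fam in families_prox) {
    prev <- Inf
    for (lam in c(0.1, 0.5, 1, 2)) {
      sp <- penalty_spec(fam, lambda = lam)
      out <- group_threshold(sp, z, step = 1)
      expect_lte(sqrt(sum(out^2)), sqrt(sum(z^2)) + 1e-12)
      expect_lte(sqrt(sum(out^2)), prev + 1e-10)
      prev <- sqrt(sum(out^2))
    }
  }
  for (fam in c("grSCAD", "grMCP")) {
    lam <- 0.4
    sp <- penalty_spec(fam, lambda = lam, group_size_scaling = FALSE)
    zbig <- c(30, -40)  # far beyond a*lambda
    expect_equal(group_threshold(sp, zbig, step = 1), zbig, tolerance = 1e-12)
  }
})

test_that("adaptive group LASSO with unit weights is the group LASSO", {
  set.seed(33)
  for (i in 1:10) {
    z <- rnorm(3); lam <- runif(1, 0.1, 1.5); step <- runif(1, 0.5, 2)
    a <- group_threshold(penalty_spec("grALASSO", lambda = lam), z, step,
                         weight = 1)
    b <- group_threshold(penalty_spec("grLASSO", lambda = lam), z, step)
    expect_identical(a, b)
  }
})

test_that("BAR weights invert squared norms and delete vanished groups", {
  expect_identical(bar_weight(c(0, 0, 0)), Inf)
  expect_equal(bar_weight(c(2, 0)), 0.25)
  expect_identical(bar_weight(c(1e-7, 0)), Inf)  # below delete_tol
})

test_that("invalid penalty specifications are rejected", {
  expect_error(penalty_spec("grSCAD", shape = 2), "invalid_shape")
  expect_error(penalty_spec("grMCP", shape = 1), "invalid_shape")
  expect_error(penalty_spec("grSELO", shape = 0), "invalid_shape")
  expect_error(penalty_spec("grLASSO", lambda = -1), "invalid_lambda")
  expect_error(penalty_spec("grALASSO", adaptive_weights = c(1, -1)),
               "invalid_weights")
})
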