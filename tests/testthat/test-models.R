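## Independent oracle: solve the torque balance by bisection rather than
## with the closed form used by msm_equilibrium.
eq_by_bisection <- function(u1, u2, p) {
  stats::uniroot(function(th) msm_torque(u1, u2, th, p),
                 interval = c(-20, 20), tol = 1e-12)$root
}

test_that("torque follows the antagonist spring model", {
  p_sym <- msm_params(a = c(1, -1), k0 = c(1, 1), k1 = c(1e-12, 1e-12),
                      l0 = c(1, 1), l1 = c(1e-12, 1e-12))
  expect_equal(msm_torque(0, 0, 0, p_sym), 0, tolerance = 1e-9)
  p <- msm_params(a = c(1, -0.5), k0 = c(1, 2), k1 = c(1, 1),
                  l0 = c(1, 1), l1 = c(0.5, 0.5))
  expect_equal(msm_torque(0.4, 0.1, 0.2, p), 0.1925)
  ## torque vanishes at the equilibrium angle by definition
  th_eq <- msm_equilibrium(0.4, 0.1, p)
  expect_equal(msm_torque(0.4, 0.1, th_eq, p), 0)
  expect_error(msm_params(a = c(-1, -1), k0 = c(1, 1), k1 = c(1, 1),
                          l0 = c(1, 1), l1 = c(1, 1)), "a1 > 0")
  expect_error(msm_torque(-0.1, 0, 0, p), "non-negative")
})

test_that("equilibrium is the exact root of the torque equation", {
  ## asymmetric stiffness: frozen value from the bisection oracle (1/3);
  ## note the naive stiffness-weighted form would give 1 instead
  p2 <- msm_params(a = c(1, -1), k0 = c(2, 1), k1 = c(1e-9, 1e-9),
                   l0 = c(1, 1), l1 = c(1e-9, 1e-9))
  expect_equal(msm_equilibrium(0, 0, p2), 1 / 3, tolerance = 1e-6)
  p <- msm_params(a = c(1, -0.5), k0 = c(1, 2), k1 = c(1, 1),
                  l0 = c(1, 1), l1 = c(0.5, 0.5))
  expect_equal(msm_equilibrium(0.4, 0.1, p), 0.3)
  expect_equal(eq_by_bisection(0.4, 0.1, p), 0.3, tolerance = 1e-9)
  ## identical antagonists at equal activation balance at zero
  p_sym <- msm_params(a = c(1, -1), k0 = c(1, 1), k1 = c(0.5, 0.5),
                      l0 = c(1, 1), l1 = c(0.7, 0.7))
  expect_equal(msm_equilibrium(0.3, 0.3, p_sym), 0)
})

test_that("equilibrium properties hold over random parameter draws", {
  set.seed(99)
  for (i in 1:1000) {
    p <- rand_params()
    u1 <- runif(1, 0, 1); u2 <- runif(1, 0, 1)
    th <- msm_equilibrium(u1, u2, p)
    expect_lt(abs(msm_torque(u1, u2, th, p)), 1e-8)
  }
  ## invariance under joint rescaling of all stiffness constants
  set.seed(100)
  for (i in 1:50) {
    p <- rand_params()
    s <- runif(1, 0.1, 10)
    ps <- msm_params(a = p$a, k0 = s * p$k0, k1 = s * p$k1,
                     l0 = p$l0, l1 = p$l1)
    u1 <- runif(1); u2 <- runif(1)
    expect_lt(abs(msm_equilibrium(u1, u2, p) - msm_equilibrium(u1, u2, ps)),
              1e-10)
  }
  ## agreement with the bisection oracle on a sample
  set.seed(101)
  for (i in 1:25) {
    p <- rand_params()
    u1 <- runif(1); u2 <- runif(1)
    expect_equal(msm_equilibrium(u1, u2, p), eq_by_bisection(u1, u2, p),
                 tolerance = 1e-8)
  }
})

test_that("equilibrium moves with the pulling muscle over generator ranges", {
  ## sampled monotonicity: more flexor -> larger angle, more extensor ->
  ## smaller, for parameters like those the generator draws
  set.seed(7)
  sub <- cached_subject()
  for (f in finger_names()) {
    p <- sub$params[[f]]
    u <- seq(0.02, 1, length.out = 25)
    expect_true(all(diff(msm_equilibrium(u, 0.02, p)) > 0))
    expect_true(all(diff(msm_equilibrium(0.02, u, p)) < 0))
  }
})

test_that("MSM fitting recovers predictions from noiseless data", {
  sub <- cached_subject()
  cfg <- tiny_cfg()
  dec <- seq(1, ncol(sub$train[[1]]$truth$angles), by = 32)   # 16 Hz
  for (f in c("Thumb", "Ring")) {
    tr <- sub$train[[match(f, finger_names())]]
    te <- sub$test[[1]]
    u <- tr$truth$activations
    fit <- fit_msm(u$u_flex[f, dec], u$u_ext[f, dec],
                   tr$truth$angles[f, dec], restarts = 6, seed = 2)
    ## constraints hold on the returned parameters
    p <- fit$params
    expect_true(p$a[1] > 0 && p$a[2] < 0)
    expect_true(all(c(p$k0, p$k1, p$l0, p$l1) > 0))
    expect_equal(p$k0[1], 1)
    ## held-out prediction on the mixed test experiment
    dte <- seq(1, ncol(te$truth$angles), by = 32)
    ue <- te$truth$activations
    pred <- predict_angle(fit, ue$u_flex[f, dte], ue$u_ext[f, dte])
    expect_gte(correlation_coefficient(pred, te$truth$angles[f, dte]), 0.99)
    expect_lte(rmse(pred, te$truth$angles[f, dte]), 0.02)
    expect_lt(fit$diagnostics$max_abs_torque, 1e-6)
  }
})

test_that("degenerate constant inputs are flagged, not fatal", {
  n <- 120
  fit <- fit_msm(rep(0.3, n), rep(0.3, n), rep(0.5, n), restarts = 2,
                 seed = 1)
  expect_true(fit$degenerate)
  expect_lt(rmse(fit$predicted, rep(0.5, n)), 0.05)
})

test_that("linear model matches exact and rank-deficient oracles", {
  set.seed(11)
  u1 <- runif(200); u2 <- runif(200)
  th <- 0.5 + 2 * u1 - u2
  fit <- fit_lrm(u1, u2, th)
  expect_equal(fit$params$beta, c(0.5, 2, -1), tolerance = 1e-8)
  expect_false(fit$params$collinear)
  ## equals the closed-form normal equations on full-rank input
  th2 <- 0.2 + 0.7 * u1 - 0.3 * u2 + rnorm(200, 0, 0.05)
  X <- cbind(1, u1, u2)
  beta_ne <- solve(t(X) %*% X, t(X) %*% th2)
  expect_equal(fit_lrm(u1, u2, th2)$params$beta, unname(drop(beta_ne)),
               tolerance = 1e-10)
  ## collinearity flag
  fitc <- fit_lrm(u1, u1, 1 + u1)
  expect_true(fitc$params$collinear)
  ## constant response
  fit0 <- fit_lrm(u1, u2, rep(0.7, 200))
  expect_equal(fit0$params$beta, c(0.7, 0, 0), tolerance = 1e-10)
  expect_error(fit_lrm(u1[1:2], u2[1:2], th[1:2]), "3 samples")
})

test_that("linear prediction applies the coefficients without error term", {
  p <- lrm_params(c(0.5, 2, -1))
  expect_equal(lrm_predict(p, 0.3, 0.1), 1.0)
  expect_equal(lrm_predict(lrm_params(c(0, 1, 0)), c(0.2, 0.9), c(1, 1)),
               c(0.2, 0.9))
  expect_equal(lrm_predict(p, 0, 0), 0.5)
})
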