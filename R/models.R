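#' Musculoskeletal model parameters for one finger joint
#'
#' The joint is driven by an antagonist flexor (muscle 1) / extensor
#' (muscle 2) pair of spring-like muscles.  Each muscle `n` has a signed
#' moment arm `a_n` (flexor positive, extensor negative), stiffness
#' constants `k0_n`, `k1_n` and rest-length constants `l0_n`, `l1_n`, all
#' positive.  Because the equilibrium angle is invariant to a common
#' rescaling of all stiffness constants, fitted parameter sets are
#' normalized with `k0_1 = 1`.
#'
#' @param a Length-2 numeric `c(a1, a2)` with `a1 > 0`, `a2 < 0`.
#' @param k0,k1,l0,l1 Length-2 positive numerics (flexor, extensor).
#' @return An object of class `ff_msm_params`.
#' @export
msm_params <- function(a, k0, k1, l0, l1) {
  p <- list(a = as.numeric(a), k0 = as.numeric(k0), k1 = as.numeric(k1),
            l0 = as.numeric(l0), l1 = as.numeric(l1))
  if (any(lengths(p) != 2L)) stop("all parameter vectors must have length 2")
  if (!(p$a[1] > 0 && p$a[2] < 0)) stop("need a1 > 0 and a2 < 0")
  if (any(c(p$k0, p$k1, p$l0, p$l1) <= 0))
    stop("k0, k1, l0, l1 must all be positive")
  structure(p, class = "ff_msm_params")
}

#' Joint torque of the antagonist muscle pair
#'
#' Total torque at activation `(u1, u2)` and joint angle `theta`:
#' `tau = sum_n a_n (k0_n + k1_n u_n) (l0_n + l1_n u_n - a_n theta)`.
#' At the equilibrium angle the two muscle torques cancel and `tau = 0`.
#'
#' @param u1,u2 Non-negative flexor/extensor activations (scalars or
#'   equal-length series).
#' @param theta Joint angle in radians (scalar or series).
#' @param p An [msm_params()] object.
#' @return Torque in model units, broadcast over the inputs.
#' @export
msm_torque <- function(u1, u2, theta, p) {
  stopifnot(inherits(p, "ff_msm_params"))
  if (any(u1 < 0) || any(u2 < 0)) stop("activations must be non-negative")
  K1 <- p$k0[1] + p$k1[1] * u1
  K2 <- p$k0[2] + p$k1[2] * u2
  L1 <- p$l0[1] + p$l1[1] * u1
  L2 <- p$l0[2] + p$l1[2] * u2
  p$a[1] * K1 * (L1 - p$a[1] * theta) + p$a[2] * K2 * (L2 - p$a[2] * theta)
}

#' Equilibrium joint angle of the antagonist muscle pair
#'
#' The angle at which the flexor and extensor torques balance, i.e. the
#' exact root of [msm_torque()] in `theta`:
#' `theta_eq = sum_n a_n K_n L_n / sum_n a_n^2 K_n` with
#' `K_n = k0_n + k1_n u_n`, `L_n = l0_n + l1_n u_n`.  The denominator is a
#' positivity-weighted sum of squares, so it can never vanish under the
#' parameter invariants.
#'
#' @inheritParams msm_torque
#' @return Equilibrium angle(s) in radians.
#' @export
msm_equilibrium <- function(u1, u2, p) {
  stopifnot(inherits(p, "ff_msm_params"))
  if (any(u1 < 0) || any(u2 < 0)) stop("activations must be non-negative")
  K1 <- p$k0[1] + p$k1[1] * u1
  K2 <- p$k0[2] + p$k1[2] * u2
  L1 <- p$l0[1] + p$l1[1] * u1
  L2 <- p$l0[2] + p$l1[2] * u2
  (p$a[1] * K1 * L1 + p$a[2] * K2 * L2) / (p$a[1]^2 * K1 + p$a[2]^2 * K2)
}

## log-parameter vector <-> ff_msm_params with k0_1 pinned to 1
msm_from_log <- function(x) {
  msm_params(a = c(exp(x[1]), -exp(x[2])),
             k0 = c(1, exp(x[3])),
             k1 = exp(x[4:5]),
             l0 = exp(x[6:7]),
             l1 = exp(x[8:9]))
}

#' Fit the musculoskeletal equilibrium-point model
#'
#' Estimates the muscle parameters that minimize the RMSE between the
#' model's equilibrium angle and the observed joint angle, under the sign
#' and positivity constraints.  Constraints are enforced by fitting in
#' log-parameters (`k`, `l`, `a1 = exp(.)`, `a2 = -exp(.)`), with `k0_1`
#' pinned to 1 to remove the global stiffness-scaling flat direction.
#' Levenberg--Marquardt least squares is restarted from seeded log-uniform
#' draws and the best training fit is returned.
#'
#' @param u_flex,u_ext Non-negative activation series (flexor, extensor).
#' @param theta Observed joint-angle series in radians (same length).
#' @param restarts Number of random restarts (default 10) in addition to a
#'   unit start (all parameters 1).
#' @param seed Seed for the restart draws.
#' @param maxit Maximum Levenberg--Marquardt iterations per restart.
#' @return An `ff_model_fit` with elements `kind = "msm"`, `params`
#'   ([msm_params()]), `predicted`, `residuals`, `rmse_train`, `degenerate`
#'   and `diagnostics` (per-restart RMSE trace, seed, max |torque| at the
#'   fitted equilibrium).
#' @export
fit_msm <- function(u_flex, u_ext, theta, restarts = 10L, seed = 1L,
                    maxit = 100L) {
  n <- length(theta)
  stopifnot(length(u_flex) == n, length(u_ext) == n)
  if (n < 90L) stop("need at least 10 samples per free parameter (90)")
  degenerate <- stats::sd(theta) < 1e-12 &&
    stats::sd(u_flex) < 1e-12 && stats::sd(u_ext) < 1e-12
  resid_fun <- function(x) msm_equilibrium(u_flex, u_ext, msm_from_log(x)) - theta
  starts <- with_seed(seed, c(
    list(rep(0, 9)),
    lapply(seq_len(restarts), function(i) stats::runif(9, -2, 2))
  ))
  best <- NULL
  trace <- numeric(0)
  for (x0 in starts) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = x0, fn = resid_fun,
                           control = minpack.lm::nls.lm.control(maxiter = maxit))),
      error = function(e) NULL)
    if (is.null(fit)) next
    r <- sqrt(mean(resid_fun(fit$par)^2))
    trace <- c(trace, r)
    if (is.null(best) || r < best$rmse) best <- list(par = fit$par, rmse = r)
  }
  if (is.null(best)) stop("all optimizer restarts failed")
  params <- msm_from_log(best$par)
  pred <- msm_equilibrium(u_flex, u_ext, params)
  structure(list(
    kind = "msm", params = params, predicted = pred,
    residuals = theta - pred, rmse_train = best$rmse,
    degenerate = degenerate,
    diagnostics = list(
      restart_rmse = trace, restarts = length(starts), seed = seed,
      max_abs_torque = max(abs(msm_torque(u_flex, u_ext, pred, params))))),
    class = "ff_model_fit")
}

#' Linear regression model coefficients
#'
#' @param beta Length-3 numeric: intercept (rad), flexor coefficient,
#'   extensor coefficient.
#' @param residual_sd Residual standard deviation (rad), non-negative.
#' @param collinear Logical flag: design was rank-deficient and the
#'   minimum-norm solution was returned.
#' @return An object of class `ff_lrm_params`.
#' @export
lrm_params <- function(beta, residual_sd = 0, collinear = FALSE) {
  beta <- as.numeric(beta)
  if (length(beta) != 3L || any(!is.finite(beta))) stop("beta must be 3 finite values")
  if (residual_sd < 0) stop("residual_sd must be >= 0")
  structure(list(beta = beta, residual_sd = residual_sd,
                 collinear = isTRUE(collinear)), class = "ff_lrm_params")
}

#' Fit the linear regression decoding model
#'
#' Ordinary least squares for `theta = b0 + b1 u_flex + b2 u_ext`.  A
#' rank-deficient design (e.g. identical flexor and extensor inputs) is
#' solved by the minimum-norm solution and flagged as collinear.
#'
#' @inheritParams fit_msm
#' @return An `ff_model_fit` with `kind = "lrm"` and `params` an
#'   [lrm_params()] object.
#' @export
fit_lrm <- function(u_flex, u_ext, theta) {
  n <- length(theta)
  stopifnot(length(u_flex) == n, length(u_ext) == n)
  if (n < 3L) stop("need at least 3 samples")
  X <- cbind(1, u_flex, u_ext)
  qrX <- qr(X)
  if (qrX$rank == 3L) {
    beta <- qr.coef(qrX, theta)
    collinear <- FALSE
  } else {
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% theta) / sv$d[pos])
    beta <- drop(beta)
    collinear <- TRUE
  }
  beta <- unname(beta)
  pred <- drop(X %*% beta)
  res <- theta - pred
  rdf <- max(1L, n - sum(qrX$rank))
  params <- lrm_params(beta, residual_sd = sqrt(sum(res^2) / rdf),
                       collinear = collinear)
  structure(list(kind = "lrm", params = params, predicted = pred,
                 residuals = res, rmse_train = sqrt(mean(res^2)),
                 degenerate = FALSE,
                 diagnostics = list(rank = qrX$rank)),
            class = "ff_model_fit")
}

#' Predict finger angle from the linear regression model
#'
#' Applies `theta_hat = b0 + b1 u_flex + b2 u_ext` (no error term).
#'
#' @param p An [lrm_params()] object.
#' @param u_flex,u_ext Activation series.
#' @return Predicted angle series in radians.
#' @export
lrm_predict <- function(p, u_flex, u_ext) {
  stopifnot(inherits(p, "ff_lrm_params"))
  p$beta[1] + p$beta[2] * u_flex + p$beta[3] * u_ext
}

#' Predict finger angle from a fitted model
#'
#' Dispatches on the fit kind: equilibrium angle for the musculoskeletal
#' model, linear predictor for the regression model.
#'
#' @param fit An `ff_model_fit` from [fit_msm()] or [fit_lrm()].
#' @param u_flex,u_ext Activation series.
#' @return Predicted angle series in radians.
#' @export
predict_angle <- function(fit, u_flex, u_ext) {
  stopifnot(inherits(fit, "ff_model_fit"))
  if (fit$kind == "msm") msm_equilibrium(u_flex, u_ext, fit$params)
  else lrm_predict(fit$params, u_flex, u_ext)
}
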