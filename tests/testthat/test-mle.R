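test_that("blur coefficient: continuous 1/6, instantaneous 0, ramp vs oracle", {
  expect_equal(motion_blur_coefficient(function(t) rep(1, length(t)), T = 1),
               1 / 6, tolerance = 1e-8)
  # result is shape-dependent only, not exposure-length dependent
  expect_equal(motion_blur_coefficient(function(t) rep(1 / 0.033, length(t)),
                                       T = 0.033), 1 / 6, tolerance = 1e-8)
  # Dirac shutter at t = 0: S = 1 on (0, T]
  expect_equal(motion_blur_coefficient(cumulative = function(t)
    as.numeric(t > 0)), 0, tolerance = 1e-12)
  # linear ramp s(t) = 2t/T^2: closed form S = t^2, integral of S(1-S) = 1/3 - 1/5
  expect_equal(motion_blur_coefficient(function(t) 2 * t, T = 1),
               1 / 3 - 1 / 5, tolerance = 1e-8)
  # quadrature refinement oracle
  coarse <- motion_blur_coefficient(function(t) 2 * t, T = 1, n_grid = 20001)
  fine <- motion_blur_coefficient(function(t) 2 * t, T = 1, n_grid = 200001)
  expect_equal(coarse, fine, tolerance = 1e-8)
  expect_error(motion_blur_coefficient(function(t) rep(2, length(t)), T = 1),
               "not normalised")
})

test_that("covariance matrix entries follow the three tridiagonal cases", {
  D <- 0.15; s <- 0.1; dt <- 0.033; R <- 1 / 6
  m <- covariance_model(D, s, dt, R, N = 5)
  S <- covariance_matrix(m)
  expect_equal(diag(S), rep(2 * D * dt - 2 * (2 * D * R * dt - s^2), 5))
  expect_equal(S[1, 2], 2 * D * R * dt - s^2)
  expect_equal(S[1, 3], 0)
  expect_true(isSymmetric(S))

  # model collapse: sigma = 0, R = 0 -> iid displacements
  S0 <- covariance_matrix(covariance_model(D, 0, dt, 0, N = 4))
  expect_equal(S0, diag(2 * D * dt, 4))
  # pure noise: D = 0 -> diagonal 2 sigma^2, off-diagonal -sigma^2
  Sn <- covariance_matrix(covariance_model(0, s, dt, R, N = 4))
  expect_equal(diag(Sn), rep(2 * s^2, 4))
  expect_equal(Sn[2, 3], -s^2)

  expect_error(covariance_model(0, 0, dt, R, N = 4), "degenerate")
  expect_error(covariance_model(0.1, 0.1, dt, 0.3, N = 4))
})

test_that("direct likelihood: 1x1 closed form and quadratic-term structure", {
  dt <- 0.05; D <- 0.2; a <- 0.3; b <- -0.1
  m <- covariance_model(D, 0, dt, 0, N = 1)
  d <- structure(list(dx = a, dy = b, dt = dt), class = "displacements")
  expect_equal(log_likelihood_direct(d, m),
               -log(2 * D * dt) - (a^2 + b^2) / (4 * D * dt),
               tolerance = 1e-12)
  # zero displacements leave only -log|Sigma|
  m5 <- covariance_model(0.15, 0.1, 0.033, 1 / 6, N = 5)
  z <- structure(list(dx = rep(0, 5), dy = rep(0, 5), dt = 0.033),
                 class = "displacements")
  expect_equal(log_likelihood_direct(z, m5),
               -as.numeric(determinant(covariance_matrix(m5))$modulus),
               tolerance = 1e-10)
})

test_that("direct likelihood matches the dense determinant+inverse oracle", {
  set.seed(5)
  for (rep in 1:100) {
    n <- sample(1:50, 1)
    D <- runif(1, 0.001, 0.5)
    s <- runif(1, 0, 0.2)
    if (D == 0 && s == 0) s <- 0.1
    R <- runif(1, 0, 0.25)
    m <- covariance_model(D, s, 0.033, R, N = n)
    d <- structure(list(dx = rnorm(n, sd = 0.1), dy = rnorm(n, sd = 0.1),
                        dt = 0.033), class = "displacements")
    expect_equal(log_likelihood_direct(d, m),
                 oracle_loglik_dense(d$dx, d$dy, m$alpha, m$beta),
                 tolerance = 1e-9)
  }
})

test_that("circulant likelihood: exact when diagonal, O(1/N) otherwise", {
  set.seed(6)
  # beta = 0 (sigma = 0, R = 0): circulant equals direct by Parseval
  n <- 32
  m <- covariance_model(0.15, 0, 0.033, 0, N = n)
  d <- structure(list(dx = rnorm(n, sd = 0.1), dy = rnorm(n, sd = 0.1),
                      dt = 0.033), class = "displacements")
  expect_equal(log_likelihood_circulant(d, m), log_likelihood_direct(d, m),
               tolerance = 1e-10)

  # approximation error is a boundary effect: O(1) in total, so the
  # per-displacement error halves every time N doubles
  ns <- c(64, 128, 256, 512)
  errs <- vapply(ns, function(nn) {
    mm <- covariance_model(0.15, 0.1, 0.033, 1 / 6, N = nn)
    dd <- structure(list(dx = rep(0, nn), dy = rep(0, nn), dt = 0.033),
                    class = "displacements")
    abs(log_likelihood_circulant(dd, mm) - log_likelihood_direct(dd, mm))
  }, numeric(1))
  expect_true(all(errs < 0.5))
  expect_equal(errs[-1] / ns[-1], (errs / ns)[-4] / 2, tolerance = 0.05)
})

test_that("MLE with clean iid data matches the closed-form argmax", {
  # sigma = 0, R = 0: argmax_D of the iid likelihood is sum(dx^2+dy^2)/(4 N dt)
  cfg <- sim_config(0.15, 0, 0.033, 301, seed = 41)
  tr <- simulate_trajectory(cfg)
  d <- displacements(tr)
  closed <- sum(d$dx^2 + d$dy^2) / (4 * length(d$dx) * tr$dt)
  # argmax over D alone (sigma pinned at 0) equals the analytic form
  prof <- stats::optimize(function(D) log_likelihood_direct(
    d, covariance_model(D, 0, tr$dt, 0, length(d$dx))),
    interval = c(1e-4, 2), maximum = TRUE, tol = 1e-10)
  expect_equal(prof$maximum, closed, tolerance = 1e-5)
  # the joint fit (sigma free) lands close to the same point
  fit <- fit_mle(tr, R = 0)
  expect_true(fit$converged)
  expect_equal(fit$D_hat, closed, tolerance = 0.05)
  expect_lt(fit$sigma_hat, 0.02)
})

test_that("fit_mle reported loglik agrees with the exported likelihood", {
  cfg <- sim_config(0.05, 0.1, 0.033, 201, blur = TRUE, seed = 42)
  tr <- simulate_trajectory(cfg)
  fit <- fit_mle(tr)
  m <- covariance_model(fit$D_hat, fit$sigma_hat, tr$dt, 1 / 6,
                        n_frames(tr) - 1L)
  expect_equal(fit$loglik, log_likelihood_direct(displacements(tr), m),
               tolerance = 1e-8)
  expect_identical(fit$method, "direct")
})

test_that("estimates honour the box constraints on every input", {
  set.seed(43)
  cfgs <- list(sim_config(0, 0.1, 0.033, 51, blur = TRUE, seed = 51),
               sim_config(0.01, 0.1, 0.033, 51, blur = TRUE, seed = 52),
               sim_config(0.5, 0, 0.033, 51, seed = 53))
  for (cfg in cfgs) for (k in 1:20) {
    fit <- fit_mle(simulate_trajectory(cfg, stream = k))
    expect_gte(fit$D_hat, 0)
    expect_gte(fit$sigma_hat, 0)
  }
})

test_that("degenerate inputs: too short, all-zero displacements", {
  expect_error(fit_mle(trajectory(x = 0:1, y = 0:1, dt = 1)), "3 frames")
  flat <- trajectory(x = rep(0, 10), y = rep(0, 10), dt = 0.033)
  expect_warning(fit <- fit_mle(flat), "boundary")
  expect_equal(fit$D_hat, 0)
  expect_equal(fit$sigma_hat, 0)
})

test_that("likelihood method switches at the configured frame count", {
  cfg <- sim_config(0.15, 0.1, 0.033, 1500, blur = TRUE, seed = 61)
  tr <- simulate_trajectory(cfg)
  direct <- fit_mle(tr, control = mle_control(switch_frames = 100000L))
  circ <- fit_mle(tr, control = mle_control(switch_frames = 3L))
  expect_identical(direct$method, "direct")
  expect_identical(circ$method, "circulant")
  expect_equal(circ$D_hat, direct$D_hat, tolerance = 0.01)
  # default constant: 1000 frames direct, 1001 frames circulant
  t1000 <- simulate_trajectory(sim_config(0.15, 0.1, 0.033, 1000,
                                          blur = TRUE, seed = 62))
  t1001 <- simulate_trajectory(sim_config(0.15, 0.1, 0.033, 1001,
                                          blur = TRUE, seed = 62))
  expect_identical(fit_mle(t1000)$method, "direct")
  expect_identical(fit_mle(t1001)$method, "circulant")
})

test_that("true parameters beat perturbed parameters in average likelihood", {
  set.seed(44)
  cfg <- sim_config(0.1, 0.08, 0.033, 201, blur = TRUE, seed = 71)
  diffs <- vapply(1:20, function(k) {
    tr <- simulate_trajectory(cfg, stream = k)
    d <- displacements(tr)
    n <- length(d$dx)
    lt <- log_likelihood_direct(d, covariance_model(0.1, 0.08, 0.033,
                                                    1 / 6, n))
    lp <- log_likelihood_direct(d, covariance_model(0.2, 0.12, 0.033,
                                                    1 / 6, n))
    lt - lp
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
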