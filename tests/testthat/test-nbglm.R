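test_that("intercept-only fit recovers log of the mean exactly", {
  set.seed(1)
  y <- rnbinom(300, mu = 5, size = 2)
  f <- fit_negbin(y, matrix(1, 300, 1, dimnames = list(NULL, "int")))
  expect_equal(unname(coef(f)), log(mean(y)), tolerance = 1e-6)
  expect_true(f$converged)
})

test_that("engine agrees with MASS::glm.nb and a generic optimizer", {
  set.seed(2)
  n <- 400
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  y <- rnbinom(n, size = 1.5, mu = exp(1 + 0.3 * x1 - 0.2 * x2))
  X <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2)
  f <- fit_negbin(y, X)
  g <- MASS::glm.nb(y ~ x1 + x2)
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-5)
  expect_equal(f$theta, g$theta, tolerance = 1e-4)
  expect_equal(f$logLik, as.numeric(logLik(g)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(f$vcov))),
               unname(sqrt(diag(vcov(g)))), tolerance = 1e-4)

  # direct likelihood maximization as an independent oracle
  o <- optim(c(coef(f), log(f$theta)), nb_ll_direct, y = y, X = X,
             method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
  expect_equal(unname(coef(f)), unname(o$par[1:3]), tolerance = 1e-4)
  expect_equal(-o$value, f$logLik, tolerance = 1e-6)

  # score equations hold at the optimum
  expect_lt(max(abs(expowas:::nb_score(f))), 1e-4)
})

test_that("fixed-dispersion fits match the fixed-theta GLM family", {
  set.seed(3)
  n <- 300
  x <- rnorm(n)
  y <- rnbinom(n, size = 2, mu = exp(1 + 0.2 * x))
  X <- cbind(1, x)
  f <- fit_negbin(y, X, theta = 2)
  g <- suppressWarnings(glm.fit(X, y,
                                family = MASS::negative.binomial(2)))
  expect_equal(unname(coef(f)), unname(g$coefficients), tolerance = 1e-6)
  expect_true(f$theta_fixed)
  expect_equal(f$theta, 2)
})

test_that("equidispersed data drives theta large, matching Poisson", {
  set.seed(4)
  n <- 800
  x <- rnorm(n)
  y <- rpois(n, exp(1.3 + 0.25 * x))
  X <- cbind(1, x)
  f <- fit_negbin(y, X)
  expect_gt(f$theta, 100)
  gp <- glm.fit(X, y, family = stats::poisson())
  se <- sqrt(diag(f$vcov))
  expect_true(all(abs(coef(f) - gp$coefficients) < 2 * se))
})

test_that("degenerate designs are rejected with a useful message", {
  y <- rpois(50, 5)
  X <- cbind(a = rep(1, 50), b = rnorm(50))
  expect_error(fit_negbin(y, cbind(X, b2 = X[, "b"])), "b2")
  expect_error(fit_negbin(c(y[-1], -1), X), "non-negative")
  expect_error(fit_negbin(y[-1], X), "nrow")
})

test_that("nb_fit methods are coherent", {
  set.seed(5)
  y <- rnbinom(200, mu = 4, size = 2)
  X <- cbind(`(Intercept)` = 1, x = rnorm(200))
  f <- fit_negbin(y, X)
  expect_equal(predict(f, type = "response"), f$fitted.values)
  expect_equal(exp(predict(f)[1]), predict(f, type = "response")[1])
  s <- summary(f)
  expect_equal(unname(s$coefficients[, "IRR"]), unname(exp(coef(f))))
  r <- residuals(f)
  expect_length(r, 200)
  sim <- simulate(f, nsim = 2, seed = 1)
  expect_true(all(sim >= 0) && ncol(sim) == 2)
})

test_that("restricted cubic spline basis has the right structure", {
  set.seed(6)
  x <- rnorm(500)
  b3 <- rcs_basis(x, 3)
  expect_equal(ncol(b3$basis), 2L)
  expect_equal(unname(b3$knots),
               unname(quantile(x, c(0.1, 0.5, 0.9), type = 7)))
  b5 <- rcs_basis(x, 5)
  expect_equal(ncol(b5$basis), 4L)
  expect_error(rcs_basis(rep(1, 100), 3), "knots")

  # linear tails: zero second difference beyond the boundary knots
  lo <- b3$knots[1]; hi <- b3$knots[3]
  grid_lo <- seq(lo - 3, lo - 0.5, length.out = 20)
  grid_hi <- seq(hi + 0.5, hi + 3, length.out = 20)
  B <- splines::ns(c(grid_lo, grid_hi), knots = b3$knots[2],
                   Boundary.knots = c(lo, hi))
  for (j in 1:2) {
    d2_lo <- diff(diff(B[1:20, j]))
    d2_hi <- diff(diff(B[21:40, j]))
    expect_lt(max(abs(c(d2_lo, d2_hi))), 1e-8)
  }
})

test_that("linearity test behaves for linear and quadratic truth", {
  set.seed(7)
  n <- 708
  x <- rnorm(n)
  y_lin <- rnbinom(n, size = 2, mu = exp(1.5 + 0.2 * x))
  X0 <- matrix(1, n, 1, dimnames = list(NULL, "int"))
  p_lin <- test_linearity(y_lin, X0, x)
  expect_true(is.finite(p_lin) && p_lin > 0 && p_lin <= 1)
  # nesting: the spline model's likelihood cannot be lower
  lrt <- attr(p_lin, "lrt")
  expect_gte(lrt, -1e-6)
  # strong curvature is detected
  y_quad <- rnbinom(n, size = 2, mu = exp(1.5 + 0.2 * x - 0.25 * x^2))
  p_quad <- test_linearity(y_quad, X0, x)
  expect_lt(p_quad, 0.01)
})

test_that("variance inflation factors match the closed form", {
  set.seed(8)
  n <- 200
  z1 <- rnorm(n); z2 <- rnorm(n)
  # exactly centered, mutually orthogonal columns via QR against 1
  Q <- qr.Q(qr(cbind(1, z1, z2)))[, 2:3]
  X <- Q
  colnames(X) <- c("u", "v")
  expect_equal(unname(vif(X)), c(1, 1), tolerance = 1e-10)
  # exact correlation 0.97 between two centered orthonormal columns
  a <- Q[, 1]; b <- Q[, 2]
  x2 <- 0.97 * a + sqrt(1 - 0.97^2) * b
  Xc <- cbind(p = as.numeric(a), q = as.numeric(x2))
  expect_equal(unname(vif(Xc)), rep(1 / (1 - 0.97^2), 2),
               tolerance = 1e-6)
  # duplicated column is infinite
  Xd <- cbind(r = z1, s = z1)
  expect_true(all(is.infinite(vif(Xd))))
})
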