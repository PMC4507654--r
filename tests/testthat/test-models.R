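test_that("fixed MAA ratios are componentwise means", {
  one <- maa_fixed_ratios(list(list(sbpr = 0.6, dbpr = 0.8)))
  expect_equal(one$sbpr, 0.6)
  expect_equal(one$dbpr, 0.8)

  two <- maa_fixed_ratios(list(list(sbpr = 0.5, dbpr = 0.7),
                               list(sbpr = 0.7, dbpr = 0.9)))
  expect_equal(two$sbpr, 0.6)
  expect_equal(two$dbpr, 0.8)

  set.seed(4)
  s <- runif(100, 0.3, 0.9); d <- runif(100, 0.5, 0.95)
  many <- maa_fixed_ratios(data.frame(sbpr = s, dbpr = d))
  expect_equal(many$sbpr, fold_left_mean(s), tolerance = 1e-12)
  expect_equal(many$dbpr, fold_left_mean(d), tolerance = 1e-12)

  expect_error(maa_fixed_ratios(list()), "empty")
})

test_that("ratio inversion follows the triangular envelope geometry", {
  tri <- triangle_owe(apex_cp = 100, apex_amp = 3, lo = 50, hi = 140)
  est <- estimate_bp_from_ratios(tri, structure(list(sbpr = 0.5, dbpr = 0.5),
                                                class = "ratio_pair"))
  expect_equal(est$sbp, 120, tolerance = 0.1)
  expect_equal(est$dbp, 75, tolerance = 0.1)

  # a systolic ratio of 1 degenerates to the envelope maximum
  est1 <- estimate_bp_from_ratios(tri, structure(list(sbpr = 1, dbpr = 0.5),
                                                 class = "ratio_pair"))
  expect_equal(est1$sbp, est1$map)

  expect_error(estimate_bp_from_ratios(
    tri, structure(list(sbpr = 1.2, dbpr = 0.5), class = "ratio_pair")),
    "\\(0, 1\\]")
  # an envelope truncated above the ratio level cannot be inverted there
  cp <- seq(80, 140, by = 2)
  trunc <- fit_spline(data.frame(
    cp = cp, amplitude = gg_envelope(cp, 100, 3, 25, 25, 1.5),
    t = (180 - cp) / 2.5))
  expect_error(estimate_bp_from_ratios(
    trunc, structure(list(sbpr = 0.5, dbpr = 0.2), class = "ratio_pair")),
    "truncated")
})

test_that("reference ratios and ratio inversion are mutual inverses", {
  for (seed in c(3, 7, 12)) {
    owe <- random_owe(seed)
    pr <- attr(owe, "params")
    rs_sbp <- pr$map + pr$wr * 0.8
    rs_dbp <- pr$map - pr$wl * 0.7
    r <- reference_ratios(owe, rs_sbp, rs_dbp)
    est <- estimate_bp_from_ratios(owe, r)
    expect_lt(abs(est$sbp - rs_sbp), 0.05)
    expect_lt(abs(est$dbp - rs_dbp), 0.05)
  }
})

test_that("MLR recovers a noiseless line and matches the normal equations", {
  set.seed(1)
  x <- rnorm(20)
  X <- cbind(1, x)
  m <- fit_mlr(X, 2 * x + 1)
  expect_equal(m$intercept, 1, tolerance = 1e-10)
  expect_equal(m$weights, 2, tolerance = 1e-10)

  X <- cbind(1, matrix(rnorm(150), 50, 3))
  colnames(X) <- c("i", "a", "b", "c")
  y <- drop(X %*% c(0.3, 1, -2, 0.5)) + rnorm(50, 0, 0.2)
  m <- fit_mlr(X, y)
  beta <- drop(normal_equations(X, y))
  expect_equal(c(m$intercept, m$weights), unname(beta), tolerance = 1e-8)
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  set.seed(2)
  x <- rnorm(30)
  X <- cbind(`(Intercept)` = 1, a = x, b = x)
  expect_error(fit_mlr(X, rnorm(30)), "collinear.*(a|b)")
  expect_error(fit_mlr(cbind(1, matrix(rnorm(4), 2)), rnorm(2)), "fewer rows")
  expect_error(fit_mlr(cbind(2, rnorm(10)), rnorm(10)), "intercept")
})

test_that("linear nu-SVR approaches the least-squares line on clean data", {
  set.seed(3)
  x <- matrix(runif(30, -1, 1), ncol = 1, dimnames = list(NULL, "x"))
  y <- 0.5 * x[, 1]
  svr <- fit_nusvr(x, y, C = 100, nu = 0.5)
  mlr <- fit_mlr(cbind(1, x), y)
  xq <- matrix(seq(-1, 1, by = 0.2), ncol = 1, dimnames = list(NULL, "x"))
  expect_lt(max(abs(predict_linear(svr, xq) - predict_linear(mlr, xq))),
            0.02)
})

test_that("nu-SVR validates its hyperparameters", {
  x <- matrix(rnorm(20), ncol = 1)
  y <- rnorm(20)
  expect_error(fit_nusvr(x, y, nu = -1.89), "nu must lie in")
  expect_error(fit_nusvr(x, y, nu = 1.5), "nu must lie in")
  expect_error(fit_nusvr(x, y, C = -2), "C must be positive")
})

test_that("the support-vector fraction respects the nu lower bound", {
  set.seed(5)
  x <- matrix(rnorm(100), ncol = 1, dimnames = list(NULL, "x"))
  y <- 0.4 * x[, 1] + rnorm(100, 0, 0.3)
  for (nu in c(0.3, 0.6)) {
    svr <- fit_nusvr(x, y, C = 10, nu = nu)
    expect_gte(svr$hyperparams$sv_fraction, nu - 0.1)
  }
})

test_that("linear prediction is intercept plus dot product", {
  m <- structure(list(kind = "mlr", feature_names = c("a", "b"),
                      weights = c(0, 0), intercept = 0.7),
                 class = "bp_linear_model")
  X <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict_linear(m, X), rep(0.7, 5))

  set.seed(6)
  W <- c(1.2, -0.4)
  m$weights <- W
  manual <- 0.7 + drop(X %*% W)
  expect_equal(predict_linear(m, X), manual, tolerance = 1e-12)

  expect_error(predict_linear(m, matrix(1, 2, 3)), "dimension mismatch")

  # round trip on a noiseless training fit
  x <- rnorm(20)
  fit <- fit_mlr(cbind(1, x = x), 2 * x + 1)
  expect_equal(predict_linear(fit, cbind(x = x)), 2 * x + 1,
               tolerance = 1e-8)
})

test_that("predicted ratios are clipped into the invertible range", {
  r <- c(0.02, 0.5, 1.4)
  expect_message(out <- clip_ratios(r), "clipped")
  expect_equal(attr(out, "n_clipped"), 2)
  expect_true(all(out > 0.05 - 1e-9 & out <= 1))
  expect_equal(out[2], 0.5)
})
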