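test_that("RE-zero prediction is expit of the fixed-effect linear predictor", {
  nd <- data.frame(x1 = c(0, 0), x2 = c(0, 0))
  expect_equal(predict(stub_ri_fit(), nd, type = "re_zero")$risk,
               c(0.5, 0.5))
  expect_equal(predict(stub_ri_fit(alpha = 1), nd, type = "re_zero")$risk,
               rep(plogis(1), 2), tolerance = 1e-12)
  expect_error(predict(stub_ri_fit(), data.frame(x1 = 1)), "x2")
})

test_that("zero variance collapses all three marginal methods", {
  fit <- stub_ri_fit(alpha = 1, beta = c(0.5, -0.5))
  nd <- data.frame(x1 = seq(-3, 3, 0.5), x2 = rep(0.3, 13))
  z <- predict(fit, nd, type = "re_zero")$risk
  expect_equal(predict(fit, nd, type = "re_integ")$risk, z,
               tolerance = 1e-12)
  expect_equal(predict(fit, nd, type = "re_approx")$risk, z,
               tolerance = 1e-12)
  ## near-zero variance: sup-norm agreement on the grid
  fit$sigma_u2 <- 1e-10
  expect_lt(max(abs(predict(fit, nd, type = "re_integ")$risk - z),
                abs(predict(fit, nd, type = "re_approx")$risk - z)), 1e-6)
})

test_that("Zeger attenuation factor has the closed form and is monotone", {
  expect_identical(zeger_attenuation(0), 1)
  cc <- 16 * sqrt(3) / (15 * pi)
  expect_equal(zeger_attenuation(1.41), 1 / sqrt(cc^2 * 1.41 + 1),
               tolerance = 1e-12)
  expect_equal(zeger_attenuation(1.41), 0.8199, tolerance = 1e-4)
  f <- zeger_attenuation(c(0.5, 1, 2))
  expect_true(all(diff(f) < 0))
  expect_error(zeger_attenuation(-0.1), "non-negative")
})

test_that("integrated marginal risk matches the integration oracle", {
  fit <- stub_ri_fit(alpha = 1, beta = c(0, 0), sigma_u2 = 1.41)
  nd <- data.frame(x1 = 0, x2 = 0)
  r <- predict(fit, nd, type = "re_integ", order = 41)$risk
  expect_equal(r, oracle_marginal_risk(1, 1.41), tolerance = 1e-8)
  expect_lt(r, plogis(1))  # attenuation toward 1/2

  ## 100 random (eta, sigma2) pairs
  set.seed(41)
  eta <- runif(100, -4, 4)
  s2 <- runif(100, 0, 2)
  for (i in seq_len(100)) {
    f <- stub_ri_fit(alpha = eta[i], sigma_u2 = s2[i])
    expect_equal(predict(f, nd, type = "re_integ", order = 41)$risk,
                 oracle_marginal_risk(eta[i], s2[i]), tolerance = 1e-7)
  }
})

test_that("symmetric mixing keeps eta = 0 at risk one half", {
  nd <- data.frame(x1 = 0, x2 = 0)
  for (s2 in c(0, 0.2, 1, 3)) {
    f <- stub_ri_fit(sigma_u2 = s2)
    expect_equal(predict(f, nd, type = "re_integ")$risk, 0.5,
                 tolerance = 1e-10)
    expect_equal(predict(f, nd, type = "re_approx")$risk, 0.5,
                 tolerance = 1e-12)
  }
})

test_that("Zeger approximation tracks the integral within 0.01", {
  fit <- stub_ri_fit(beta = c(1, 0), sigma_u2 = 1.41)
  nd <- data.frame(x1 = seq(-4, 4, by = 0.1), x2 = 0)
  ri <- predict(fit, nd, type = "re_integ", order = 61)$risk
  ra <- predict(fit, nd, type = "re_approx")$risk
  expect_lt(max(abs(ri - ra)), 0.01)
})

test_that("integrated risk is monotone in eta and attenuated toward 1/2", {
  fit <- stub_ri_fit(beta = c(1, 0), sigma_u2 = 1.2)
  nd <- data.frame(x1 = seq(-4, 4, by = 0.25), x2 = 0)
  ri <- predict(fit, nd, type = "re_integ")$risk
  rz <- predict(fit, nd, type = "re_zero")$risk
  expect_true(all(diff(ri) > 0))
  pos <- nd$x1 > 0
  expect_true(all(ri[pos] < rz[pos]))
  expect_true(all(ri[nd$x1 < 0] > rz[nd$x1 < 0]))
})

test_that("prediction sets serialise to CSV", {
  fit <- stub_ri_fit(beta = c(1, 0), sigma_u2 = 1)
  nd <- data.frame(cluster = c(1, 2), x1 = c(-1, 1), x2 = 0)
  p <- predict(fit, nd, type = "re_integ")
  path <- tempfile(fileext = ".csv")
  write_predictions_csv(p, path)
  back <- read.csv(path)
  expect_equal(back$risk, p$risk, tolerance = 1e-12)
  expect_equal(unique(back$method), "re_integ")
})
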