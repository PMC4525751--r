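## brute-force posterior of u on a fine trapezoid grid
oracle_posterior <- function(alpha, beta, sigma_u2, y, X,
                             npt = 1e5, lim = 10) {
  u <- seq(-lim, lim, length.out = npt)
  eta0 <- alpha + drop(as.matrix(X) %*% beta)
  lw <- dnorm(u, 0, sqrt(sigma_u2), log = TRUE) +
    vapply(u, function(ui)
      sum(dbinom(y, 1, plogis(eta0 + ui), log = TRUE)), numeric(1))
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  list(u = u, w = w, mean = sum(w * u))
}

test_that("zero variance gives a degenerate posterior at zero", {
  fit <- stub_ri_fit(alpha = 0.3, beta = c(1, 0), sigma_u2 = 0)
  post <- ranef_posterior(fit)
  expect_equal(post[["1"]], list(nodes = 0, weights = 1, mean = 0, mode = 0))
})

test_that("a single event tilts the posterior to positive u", {
  d <- data.frame(cluster = 1, y = 1, x1 = 0, x2 = 0)
  fit <- stub_ri_fit(sigma_u2 = 1)
  post <- ranef_posterior(fit, newdata = d)
  expect_gt(post[["1"]]$mean, 0)
})

test_that("posterior mean matches a brute-force grid to 1e-6", {
  set.seed(51)
  y <- rbinom(5, 1, 0.6)
  X <- cbind(x1 = rnorm(5), x2 = rnorm(5))
  fit <- stub_ri_fit(alpha = 0.2, beta = c(0.8, -0.4), sigma_u2 = 0.9)
  d <- data.frame(cluster = 9, y = y, X)
  post <- ranef_posterior(fit, newdata = d, grid_size = 61)
  oracle <- oracle_posterior(0.2, c(0.8, -0.4), 0.9, y, X)
  expect_equal(post[["9"]]$mean, oracle$mean, tolerance = 1e-6)
})

test_that("conditional predictions follow the posterior-predictive oracle", {
  ## single history record, alpha = beta = 0: integrated conditional risk
  ## for a new x = 0 record is E_post[plogis(u)]
  hist <- data.frame(cluster = 1, y = 1, x1 = 0, x2 = 0)
  fit <- stub_ri_fit(sigma_u2 = 1)
  fit$data <- clustered_data(hist)
  nd <- data.frame(cluster = 1, x1 = 0, x2 = 0)
  got <- predict(fit, nd, type = "conditional", order = 61)$risk
  o <- oracle_posterior(0, c(0, 0), 1, 1, matrix(0, 1, 2))
  expect_equal(got, sum(o$w * plogis(o$u)), tolerance = 1e-6)

  ## plugin uses the posterior mean
  plug <- predict(fit, nd, type = "conditional",
                  conditional_mode = "plugin")$risk
  expect_equal(plug, plogis(o$mean), tolerance = 1e-6)
  expect_false(isTRUE(all.equal(got, plug)))

  ## Jensen-type contraction: the integrated risk is less extreme than the
  ## plug-in at the posterior mean
  expect_lte(abs(qlogis(got)), abs(qlogis(plug)) + 1e-8)
})

test_that("zero variance collapses conditional onto RE-zero", {
  fit <- stub_ri_fit(alpha = 0.5, beta = c(1, -1), sigma_u2 = 0)
  nd <- data.frame(cluster = 1, x1 = c(-1, 0, 1), x2 = 0.2)
  z <- predict(fit, nd, type = "re_zero")$risk
  expect_equal(predict(fit, nd, type = "conditional")$risk, z,
               tolerance = 1e-12)
  expect_equal(predict(fit, nd, type = "conditional",
                       conditional_mode = "plugin")$risk, z,
               tolerance = 1e-12)
})

test_that("unknown clusters are pointed at marginal prediction", {
  fit <- stub_ri_fit(sigma_u2 = 1)
  nd <- data.frame(cluster = 99, x1 = 0, x2 = 0)
  expect_error(predict(fit, nd, type = "conditional"), "marginal")
  expect_error(predict(fit, data.frame(x1 = 0, x2 = 0),
                       type = "conditional"), "cluster")
})
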