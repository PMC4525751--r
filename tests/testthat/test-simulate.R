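test_that("config validation enforces the generator contract", {
  expect_error(sim_config(), "exactly one")
  expect_error(sim_config(icc = 0.3, sigma_u2 = 1), "exactly one")
  expect_error(sim_config(icc = 1), "icc")
  expect_error(sim_config(icc = 0.3, coefficients = 1), "coefficient")
  cfg <- sim_config(icc = 0.30)
  expect_equal(cfg$sigma_u2, 1.41, tolerance = 1e-2)
  expect_equal(sim_config(sigma_u2 = 0.17)$icc, 0.0491, tolerance = 1e-3)
})

test_that("covariates have the configured prevalences and spreads", {
  set.seed(71)
  pop <- generate_source_population(sim_config(icc = 0.05))
  d <- pop$data
  n <- nrow(d)
  for (j in 1:3) {
    prev <- c(0.2, 0.3, 0.4)[j]
    se <- sqrt(prev * (1 - prev) / n)
    expect_lt(abs(mean(d[[paste0("x", j + 3)]]) - prev), 3 * se)
    expect_true(all(d[[paste0("x", j + 3)]] %in% c(0, 1)))
  }
  expect_equal(sd(d$x1), 1, tolerance = 0.05)
  expect_equal(sd(d$x2), 0.3, tolerance = 0.02)
  expect_equal(sd(d$x3), 0.2, tolerance = 0.02)
})

test_that("cluster sizes follow the Poisson-lognormal law", {
  set.seed(72)
  cfg <- sim_config(icc = 0.05)
  sizes <- unlist(replicate(10, as.vector(table(
    generate_source_population(cfg)$data$cluster)), simplify = FALSE))
  ## lognormal mean exp(5.7 + 0.3^2/2) ~ 312.1; sd of one size ~ 96
  expect_lt(abs(mean(sizes) - exp(5.7 + 0.3^2 / 2)), 10)
  expect_true(all(sizes > 0))
})

test_that("true linear predictors and probabilities are stored coherently", {
  set.seed(73)
  pop <- generate_source_population(sim_config(icc = 0.15))
  d <- pop$data
  X <- as.matrix(d[, paste0("x", 1:6)])
  expect_equal(pop$eta, rowSums(X) + pop$u[d$cluster], tolerance = 1e-12)
  expect_equal(pop$prob, plogis(pop$eta), tolerance = 1e-12)
  ## with sigma_u2 = 0 the random intercepts vanish
  pop0 <- generate_source_population(sim_config(sigma_u2 = 0))
  expect_true(all(pop0$u == 0))
})

test_that("latent ICC of the generated random intercepts matches", {
  set.seed(74)
  cfg <- sim_config(sigma_u2 = 0.17, n_source_clusters = 3000,
                    lambda_mean = 0.7)
  for (s2 in c(0.17, 1.41)) {
    cfg$sigma_u2 <- s2
    cfg$icc <- icc_from_sigma2(s2)
    u <- generate_source_population(cfg)$u
    expect_equal(icc_from_sigma2(var(u)), icc_from_sigma2(s2),
                 tolerance = 0.1)
  }
})

test_that("two-stage sampling respects its contract", {
  set.seed(75)
  cfg <- sim_config(icc = 0.30)
  pop <- generate_source_population(cfg)
  sp <- draw_training_validation(pop, cfg)
  expect_equal(nrow(sp$training), 1000L)
  expect_lte(length(unique(sp$training$cluster)), 20L)
  expect_equal(length(unique(sp$validation$cluster)), 80L)
  expect_length(intersect(unique(sp$training$cluster),
                          unique(sp$validation$cluster)), 0)
  expect_equal(nrow(sp$training) + nrow(sp$validation),
               nrow(pop$data) -
                 sum(pop$data$cluster %in% sp$sampled_clusters) + 1000L)
  ## determinism under a fixed seed
  set.seed(123); a <- draw_training_validation(pop, cfg)
  set.seed(123); b <- draw_training_validation(pop, cfg)
  expect_identical(a, b)
})

test_that("Dirichlet-multinomial training sets have the right size law", {
  set.seed(76)
  cfg <- sim_config(icc = 0.30)
  sizes <- replicate(200, as.vector(table(factor(
    draw_training_dirichlet(cfg)$cluster, levels = 1:20))))
  expect_true(all(colSums(sizes) == 1000))
  expect_equal(mean(sizes), 50, tolerance = 2)
  ## Dirichlet mixing inflates the size variance far beyond
  ## Multinomial(1000, 1/20), whose variance is 47.5
  expect_gt(var(as.vector(sizes)), 5 * 47.5)
})

test_that("outcome prevalence is stable across seeds", {
  prev <- vapply(1:20, function(s) {
    set.seed(s)
    mean(generate_source_population(sim_config(icc = 0.05))$data$y)
  }, numeric(1))
  expect_lt(sd(prev) / mean(prev), 0.05)
})

test_that("clustered data round-trips through CSV", {
  set.seed(78)
  d <- make_clustered(K = 3, n_per = 5)
  path <- tempfile(fileext = ".csv")
  write_clustered_csv(d, path)
  back <- read_clustered_csv(path)
  expect_equal(back$y, d$y)
  expect_equal(back$x1, d$x1, tolerance = 1e-12)
  expect_equal(attr(back, "covariates"), c("x1", "x2"))
})
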