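## small simulated clustered datasets used across the tests

## generic clustered logistic data with known parameters
make_clustered <- function(K = 20, n_per = 50, beta = c(1, -0.5),
                           alpha = 0, sigma_u2 = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- K * n_per
  cluster <- rep(seq_len(K), each = n_per)
  X <- matrix(rnorm(n * length(beta)), n, length(beta),
              dimnames = list(NULL, paste0("x", seq_along(beta))))
  u <- rnorm(K, 0, sqrt(sigma_u2))
  eta <- alpha + drop(X %*% beta) + u[cluster]
  data.frame(cluster = cluster, y = rbinom(n, 1, plogis(eta)), X)
}

## brute-force log of integral exp(h(u)) dnorm(u; 0, s) du via stats::integrate
oracle_cluster_loglik <- function(alpha, beta, sigma_u2, y, X) {
  eta0 <- alpha + drop(as.matrix(X) %*% beta)
  f <- function(u) vapply(u, function(ui) {
    exp(sum(dbinom(y, 1, plogis(eta0 + ui), log = TRUE))) *
      dnorm(ui, 0, sqrt(sigma_u2))
  }, numeric(1))
  log(stats::integrate(f, -Inf, Inf, rel.tol = 1e-12)$value)
}

## brute-force marginal risk E[plogis(eta + u)], u ~ N(0, s2)
oracle_marginal_risk <- function(eta, sigma_u2) {
  vapply(eta, function(e)
    stats::integrate(function(u) plogis(e + u) * dnorm(u, 0, sqrt(sigma_u2)),
                     -Inf, Inf, rel.tol = 1e-12)$value, numeric(1))
}

## a tiny sim config that keeps property tests fast
small_config <- function(...) {
  sim_config(n_source_clusters = 40, lambda_mean = 3.4, lambda_sd = 0.3,
             n_sampled_clusters = 10, training_size = 200,
             n_replicates = 2, ...)
}

## a hand-built ri_fit, bypassing estimation, for closed-form checks
stub_ri_fit <- function(alpha = 0, beta = c(0, 0), sigma_u2 = 0) {
  d <- data.frame(cluster = c(1, 1, 2, 2), y = c(0, 1, 0, 1),
                  x1 = c(-1, 1, -1, 1), x2 = c(1, -1, 1, -1))
  cf <- c("(Intercept)" = alpha, x1 = beta[1], x2 = beta[2])
  structure(list(coef = cf, sigma_u2 = sigma_u2, loglik = -1,
                 converged = TRUE, quadrature_order = 41, adaptive = FALSE,
                 fixed_sigma = FALSE, n_obs = 4, n_clusters = 2,
                 covariates = c("x1", "x2"), data = clustered_data(d)),
            class = "ri_fit")
}

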