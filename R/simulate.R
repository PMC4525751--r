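## Synthetic clustered source population and training/validation sampling.
##
## The generator emulates a multicentre study: 100 centres whose sizes are
## Poisson-lognormal, six patient-level predictors (three Normal, three
## Bernoulli), unit coefficients, zero fixed intercept and a Normal centre
## effect whose variance sets the latent-scale ICC.

#' Simulation configuration
#'
#' Collects and validates the generator parameters.  The defaults define
#' the study conditions used throughout the package: a source population of
#' 100 centres with sizes `N_i ~ Poisson(exp(lambda_i))`,
#' `lambda_i ~ N(5.7, 0.3^2)`; three continuous predictors
#' `N(0, sd)` with sds 1, 0.3, 0.2; three binary predictors with
#' prevalences 0.2, 0.3, 0.4; all regression coefficients 1 and intercept
#' 0; and a centre-level random intercept `u_i ~ N(0, sigma_u2)`.  Exactly
#' one of `icc` and `sigma_u2` must be given; the other is derived through
#' the latent-scale ICC formula (see [icc_from_sigma2()]).
#'
#' @param icc latent-scale intra-cluster correlation in `[0, 1)`.
#' @param sigma_u2 random-intercept variance (alternative to `icc`).
#' @param n_source_clusters number of centres in the source population.
#' @param lambda_mean,lambda_sd mean and sd of the log cluster-size rate.
#' @param normal_sds sds of the continuous predictors.
#' @param bernoulli_prevalences prevalences of the binary predictors.
#' @param coefficients regression coefficients, one per predictor.
#' @param intercept fixed intercept of the linear predictor.
#' @param n_sampled_clusters centres drawn at stage 1 of two-stage
#'   sampling.
#' @param training_size members drawn at stage 2 (pooled across the
#'   sampled centres).
#' @param n_replicates replicate training draws for the simulation study.
#' @param sampling_scheme `"two_stage"` (sample centres, then members,
#'   validation = remaining centres) or `"dirichlet"` (fresh training
#'   clusters with Dirichlet-multinomial sizes).
#' @param stage2 `"pooled"` draws the stage-2 members from the pooled
#'   records of the sampled centres; `"stratified"` draws an equal number
#'   per centre.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(icc = NULL, sigma_u2 = NULL,
                       n_source_clusters = 100L,
                       lambda_mean = 5.7, lambda_sd = 0.3,
                       normal_sds = c(1, 0.3, 0.2),
                       bernoulli_prevalences = c(0.2, 0.3, 0.4),
                       coefficients = rep(1, 6), intercept = 0,
                       n_sampled_clusters = 20L, training_size = 1000L,
                       n_replicates = 100L,
                       sampling_scheme = c("two_stage", "dirichlet"),
                       stage2 = c("pooled", "stratified")) {
  if (is.null(icc) == is.null(sigma_u2))
    stop("exactly one of 'icc' and 'sigma_u2' must be supplied")
  if (is.null(sigma_u2)) sigma_u2 <- sigma2_from_icc(icc)
  else icc <- icc_from_sigma2(sigma_u2)
  stopifnot(sigma_u2 >= 0, n_source_clusters >= 1, lambda_sd >= 0,
            all(normal_sds > 0),
            all(bernoulli_prevalences > 0 & bernoulli_prevalences < 1),
            n_sampled_clusters >= 1, training_size >= 1, n_replicates >= 0)
  p <- length(normal_sds) + length(bernoulli_prevalences)
  if (length(coefficients) != p)
    stop("need one coefficient per predictor (", p, ")")
  structure(list(icc = icc, sigma_u2 = sigma_u2,
                 n_source_clusters = as.integer(n_source_clusters),
                 lambda_mean = lambda_mean, lambda_sd = lambda_sd,
                 normal_sds = normal_sds,
                 bernoulli_prevalences = bernoulli_prevalences,
                 coefficients = coefficients, intercept = intercept,
                 n_sampled_clusters = as.integer(n_sampled_clusters),
                 training_size = as.integer(training_size),
                 n_replicates = as.integer(n_replicates),
                 sampling_scheme = match.arg(sampling_scheme),
                 stage2 = match.arg(stage2)),
            class = "sim_config")
}

## covariate block for n records under the config
.draw_covariates <- function(n, config) {
  Xc <- vapply(config$normal_sds, function(s) stats::rnorm(n, 0, s),
               numeric(n))
  Xb <- vapply(config$bernoulli_prevalences,
               function(pr) stats::rbinom(n, 1L, pr) + 0, numeric(n))
  X <- cbind(Xc, Xb)
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

.assemble_population <- function(cluster, u_by_cluster, X, config) {
  eta <- config$intercept + drop(X %*% config$coefficients) +
    u_by_cluster[cluster]
  prob <- plogis(eta)
  y <- stats::rbinom(length(eta), 1L, prob)
  data <- clustered_data(data.frame(cluster = cluster, y = y, X))
  structure(list(data = data, u = u_by_cluster, eta = eta, prob = prob,
                 config = config),
            class = "source_population")
}

#' Generate the synthetic source population
#'
#' Draws cluster sizes, covariates, random intercepts, true linear
#' predictors and outcomes for the full source population described in
#' [sim_config()].  Zero-size clusters are redrawn so the number of
#' clusters is exactly `n_source_clusters`.  Consumes the current RNG
#' state; call `set.seed()` first for reproducibility.
#'
#' @param config a [sim_config()].
#' @return an object of class `source_population`: a list with the
#'   clustered `data`, the per-cluster random intercepts `u`, the true
#'   per-record linear predictor `eta` and event probability `prob`.
#' @export
generate_source_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  K <- config$n_source_clusters
  sizes <- integer(K)
  for (i in seq_len(K)) {
    repeat {
      lam <- stats::rnorm(1L, config$lambda_mean, config$lambda_sd)
      n_i <- stats::rpois(1L, exp(lam))
      if (n_i > 0L) break
    }
    sizes[i] <- n_i
  }
  cluster <- rep(seq_len(K), sizes)
  u <- stats::rnorm(K, 0, sqrt(config$sigma_u2))
  X <- .draw_covariates(sum(sizes), config)
  .assemble_population(cluster, u, X, config)
}

#' Two-stage sampling of a training set, remainder as validation
#'
#' Stage 1 samples `n_sampled_clusters` centres without replacement from
#' the source population; stage 2 samples `training_size` members without
#' replacement from those centres (pooled across centres by default).  The
#' validation set is the whole source population after removing the
#' sampled centres, so training and validation cluster sets are disjoint.
#'
#' @param pop a `source_population`.
#' @param config the [sim_config()] (defaults to the one stored in `pop`).
#' @return list with elements `training` and `validation` (clustered data
#'   frames) and `sampled_clusters`.
#' @export
draw_training_validation <- function(pop, config = pop$config) {
  stopifnot(inherits(pop, "source_population"))
  data <- pop$data
  ids <- unique(data$cluster)
  if (config$n_sampled_clusters > length(ids))
    stop("cannot sample more clusters than the population contains")
  chosen <- sample(ids, config$n_sampled_clusters)
  in_chosen <- data$cluster %in% chosen
  pool_idx <- which(in_chosen)
  if (config$stage2 == "pooled") {
    if (length(pool_idx) < config$training_size)
      stop("sampled clusters hold fewer members than 'training_size'")
    take <- sample(pool_idx, config$training_size)
  } else {
    per <- config$training_size %/% config$n_sampled_clusters
    take <- unlist(lapply(chosen, function(cl) {
      members <- which(data$cluster == cl)
      if (length(members) < per)
        stop("cluster ", cl, " holds fewer than ", per, " members")
      sample(members, per)
    }))
  }
  list(training = clustered_data(data[sort(take), , drop = FALSE]),
       validation = clustered_data(data[!in_chosen, , drop = FALSE]),
       sampled_clusters = chosen)
}

#' Training set with Dirichlet-multinomial cluster sizes
#'
#' Sensitivity variant: generates a fresh training set of
#' `training_size` records in `n_sampled_clusters` new clusters whose
#' sizes follow a Multinomial with probabilities drawn from a flat
#' Dirichlet, with covariates, random intercepts and outcomes drawn from
#' the same distributions as the source population.
#'
#' @param config a [sim_config()].
#' @return a clustered data frame.
#' @export
draw_training_dirichlet <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  K <- config$n_sampled_clusters
  g <- stats::rgamma(K, 1, 1)            # Dirichlet(1, ..., 1)
  sizes <- drop(stats::rmultinom(1L, config$training_size, g / sum(g)))
  cluster <- rep(seq_len(K), sizes)
  u <- stats::rnorm(K, 0, sqrt(config$sigma_u2))
  X <- .draw_covariates(sum(sizes), config)
  pop <- .assemble_population(cluster, u, X, config)
  pop$data
}

#' @export
print.source_population <- function(x, ...) {
  sizes <- table(x$data$cluster)
  cat("Synthetic source population:", length(sizes), "clusters,",
      nrow(x$data), "records\n")
  cat(sprintf("  sigma_u^2 = %.4f (ICC %.3f), prevalence %.3f, ",
              x$config$sigma_u2, x$config$icc, mean(x$data$y)),
      sprintf("median cluster size %d\n", as.integer(stats::median(sizes))))
  invisible(x)
}
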