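## S3 methods for the fitted-model classes.

#' @export
print.marginal_fit <- function(x, digits = 4, ...) {
  lab <- if (x$method == "gee")
    paste0("Logistic GEE (", x$working_correlation, " working correlation)")
  else "Logistic regression (standard MLE, clustering ignored)"
  cat(lab, "\n")
  print(round(x$coef, digits))
  if (x$method == "gee" && x$working_correlation == "exchangeable")
    cat("Estimated exchangeable correlation:", round(x$rho, digits), "\n")
  cat(x$n_obs, "records in", x$n_clusters, "clusters;",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' @export
coef.marginal_fit <- function(object, ...) object$coef

#' @export
vcov.marginal_fit <- function(object, ...) object$vcov

#' @export
logLik.marginal_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coef), class = "logLik")
}

#' @export
summary.marginal_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coef / se
  tab <- cbind(Estimate = object$coef, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab),
            class = "summary.marginal_fit")
}

#' @export
print.summary.marginal_fit <- function(x, ...) {
  print(x$fit)
  cat("\n")
  stats::printCoefmat(x$coefficients)
  if (x$fit$method == "gee")
    cat("Standard errors are robust (sandwich).\n")
  invisible(x)
}

#' @export
print.ri_fit <- function(x, digits = 4, ...) {
  cat("Logistic random-intercepts model",
      sprintf("(Gauss-Hermite, order %d%s)\n", x$quadrature_order,
              if (x$adaptive) ", adaptive" else ""))
  print(round(x$coef, digits))
  cat(sprintf("sigma_u^2 = %.*f  (latent-scale ICC %.*f%s)\n", digits,
              x$sigma_u2, digits, icc_from_sigma2(x$sigma_u2),
              if (x$fixed_sigma) ", fixed" else ""))
  cat(sprintf("log-likelihood %.*f over %d records in %d clusters; %s\n",
              digits, x$loglik, x$n_obs, x$n_clusters,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.ri_fit <- function(object, ...) object$coef

#' @export
logLik.ri_fit <- function(object, ...) {
  df <- length(object$coef) + !object$fixed_sigma
  structure(object$loglik, df = df, class = "logLik")
}

#' @export
summary.ri_fit <- function(object, ...) {
  se <- rep(NA_real_, length(object$coef))
  if (!object$fixed_sigma || object$sigma_u2 > 0) {
    ## observed information on (alpha, beta, log sigma) by differencing the
    ## analytic score
    des <- list(y = object$data$y,
                X = .covariate_matrix(object$data, object$covariates),
                cluster = factor(object$data$cluster))
    gh <- gauss_hermite_normal(object$quadrature_order)
    fix <- if (object$fixed_sigma) object$sigma_u2 else NULL
    theta <- c(unname(object$coef),
               if (!object$fixed_sigma) log(sqrt(max(object$sigma_u2,
                                                     1e-10))))
    H <- .fd_jacobian(function(th)
      .ri_objective(th, des$y, des$X, des$cluster, gh, fix)$gradient, theta)
    V <- tryCatch(solve(-(H + t(H)) / 2), error = function(e) NULL)
    if (!is.null(V))
      se <- sqrt(pmax(diag(V)[seq_along(object$coef)], 0))
  } else {
    mle <- logistic_mle(object$data)
    se <- sqrt(diag(mle$vcov))
  }
  z <- object$coef / se
  tab <- cbind(Estimate = object$coef, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab),
            class = "summary.ri_fit")
}

#' @export
print.summary.ri_fit <- function(x, ...) {
  print(x$fit)
  cat("\nConditional (cluster-specific) fixed effects:\n")
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' Simulate outcomes from a fitted random-intercepts model
#'
#' Draws fresh random intercepts for each cluster of `newdata` (or the
#' training data) and Bernoulli outcomes from the conditional
#' probabilities.
#'
#' @param object an `ri_fit`.
#' @param nsim number of simulated outcome vectors.
#' @param seed optional seed.
#' @param newdata optional clustered data frame.
#' @param ... unused.
#' @return data frame of `nsim` simulated 0/1 outcome columns.
#' @export
simulate.ri_fit <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                            ...) {
  if (!is.null(seed)) set.seed(seed)
  data <- if (is.null(newdata)) object$data else clustered_data(newdata)
  X <- .covariate_matrix(data, object$covariates)
  eta_fixed <- drop(cbind(1, X) %*% object$coef)
  cl <- factor(data$cluster)
  out <- as.data.frame(replicate(nsim, {
    u <- stats::rnorm(nlevels(cl), 0, sqrt(object$sigma_u2))
    stats::rbinom(nrow(data), 1L, plogis(eta_fixed + u[as.integer(cl)]))
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Residuals of a random-intercepts fit
#'
#' Response or Pearson residuals against the marginal (integrated) fitted
#' probabilities.
#'
#' @param object an `ri_fit`.
#' @param type `"response"` or `"pearson"`.
#' @param ... unused.
#' @export
residuals.ri_fit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  p <- predict(object, object$data, type = "re_integ")$risk
  r <- object$data$y - p
  if (type == "pearson") r <- r / sqrt(p * (1 - p))
  r
}

#' Serialise a fitted model to JSON
#'
#' Writes parameter names and values, the random-intercept variance and
#' log-likelihood where applicable, and convergence metadata.
#'
#' @param object an `ri_fit` or `marginal_fit`.
#' @param path output file; with `NULL` the JSON string is returned.
#' @export
fit_to_json <- function(object, path = NULL) {
  stopifnot(inherits(object, c("ri_fit", "marginal_fit")))
  x <- list(class = class(object)[1L],
            coefficients = as.list(object$coef),
            converged = object$converged,
            n_obs = object$n_obs, n_clusters = object$n_clusters)
  if (inherits(object, "ri_fit")) {
    x$sigma_u2 <- object$sigma_u2
    x$loglik <- object$loglik
    x$quadrature_order <- object$quadrature_order
  } else {
    x$method <- object$method
    x$working_correlation <- object$working_correlation
    if (object$method == "gee") x$rho <- object$rho
    if (is.finite(object$loglik %||% NA)) x$loglik <- object$loglik
  }
  if (is.null(path))
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
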