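## Marginal and conditional risk calculation from a fitted
## random-intercepts model.

.PROB_EPS <- 1e-12

.prediction_set <- function(risk, lp, method, cluster = NULL) {
  risk <- pmin(pmax(risk, .PROB_EPS), 1 - .PROB_EPS)
  out <- data.frame(linear_predictor = lp, risk = risk)
  if (!is.null(cluster)) out <- cbind(cluster = cluster, out)
  attr(out, "method") <- method
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' Zeger attenuation factor
#'
#' The closed-form factor `1 / sqrt(c^2 sigma_u^2 + 1)`, with
#' `c = 16 sqrt(3) / (15 pi)`, by which the conditional coefficients of a
#' logistic random-intercepts model are (approximately) attenuated to give
#' the marginal coefficients.  Equals 1 at `sigma_u2 = 0` and decreases as
#' the random-effect variance grows.
#'
#' @param sigma_u2 random-intercept variance (>= 0), possibly a vector.
#' @return the attenuation factor(s) in (0, 1].
#' @examples
#' zeger_attenuation(1.41)  # about 0.82
#' @export
zeger_attenuation <- function(sigma_u2) {
  if (any(!is.finite(sigma_u2)) || any(sigma_u2 < 0))
    stop("'sigma_u2' must be non-negative and finite")
  cc <- 16 * sqrt(3) / (15 * pi)
  1 / sqrt(cc^2 * sigma_u2 + 1)
}

## E[ plogis(eta + u) ], u ~ N(0, sigma2), vectorised over eta
.integrated_risk <- function(eta, sigma2, order = 41L) {
  if (sigma2 == 0) return(plogis(eta))
  gh <- gauss_hermite_normal(order)
  u <- sqrt(sigma2) * gh$nodes
  drop(plogis(outer(eta, u, "+")) %*% gh$weights)
}

.newdata_design <- function(object, newdata) {
  covs <- object$covariates
  miss <- setdiff(covs, colnames(newdata))
  if (length(miss))
    stop("newdata lacks covariate column(s): ", paste(miss, collapse = ", "))
  as.matrix(as.data.frame(newdata)[, covs, drop = FALSE])
}

#' Predicted risks from a marginal logistic fit
#'
#' @param object a `marginal_fit` from [logistic_mle()] or
#'   [gee_logistic()].
#' @param newdata data frame containing the model's covariate columns;
#'   defaults would require the training data, so it is mandatory.
#' @param ... unused.
#' @return a `prediction_set` data frame with columns `linear_predictor`
#'   and `risk`.
#' @export
predict.marginal_fit <- function(object, newdata, ...) {
  X <- .newdata_design(object, newdata)
  cf <- object$coef
  lp <- if (object$include_intercept %||% TRUE)
    drop(cbind(1, X) %*% cf) else drop(X %*% cf)
  .prediction_set(plogis(lp), lp,
                  if (object$method == "gee") "gee" else "no_clustering",
                  newdata$cluster)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Marginal and conditional predicted risks from a random-intercepts fit
#'
#' Computes predicted event probabilities from a fitted logistic
#' random-intercepts model by the methods compared in the package:
#'
#' * `"re_zero"` — naive marginal prediction with the random effect set to
#'   its mean, zero: `plogis(alpha + x beta)`.  Mis-calibrated as a
#'   population-average risk whenever `sigma_u^2 > 0`.
#' * `"re_integ"` — proper marginal prediction, integrating
#'   `plogis(alpha + u + x beta)` over `u ~ N(0, sigma_u^2)` by
#'   Gauss-Hermite quadrature.
#' * `"re_approx"` — marginal prediction from conditional coefficients
#'   rescaled by the Zeger attenuation factor (see [zeger_attenuation()]).
#' * `"conditional"` — cluster-specific prediction for members of clusters
#'   seen in training, using the posterior distribution of the cluster's
#'   random effect given its observed outcomes; either the posterior-mean
#'   plug-in (`conditional_mode = "plugin"`) or full integration over the
#'   posterior (`"integrated"`, the default).
#'
#' @param object an `ri_fit` from [ri_logistic()].
#' @param newdata data frame with the covariate columns; for conditional
#'   prediction it must also carry a `cluster` column whose values occur in
#'   the training data.
#' @param type prediction method, see Details.
#' @param conditional_mode `"integrated"` or `"plugin"` (posterior mean).
#' @param order quadrature order for the integrated methods.
#' @param ... unused.
#' @return a `prediction_set` data frame with columns `linear_predictor`
#'   and `risk` (and `cluster` when supplied).  For integrated methods the
#'   linear predictor is defined as `qlogis(risk)`.
#' @export
predict.ri_fit <- function(object, newdata,
                           type = c("re_integ", "re_zero", "re_approx",
                                    "conditional"),
                           conditional_mode = c("integrated", "plugin"),
                           order = 41L, ...) {
  type <- match.arg(type)
  conditional_mode <- match.arg(conditional_mode)
  X <- .newdata_design(object, newdata)
  cf <- object$coef
  eta_fixed <- drop(cbind(1, X) %*% cf)
  cl <- if ("cluster" %in% colnames(newdata)) newdata$cluster else NULL
  switch(type,
    re_zero = .prediction_set(plogis(eta_fixed), eta_fixed, "re_zero", cl),
    re_approx = {
      lp <- zeger_attenuation(object$sigma_u2) * eta_fixed
      .prediction_set(plogis(lp), lp, "re_approx", cl)
    },
    re_integ = {
      risk <- .integrated_risk(eta_fixed, object$sigma_u2, order)
      risk <- pmin(pmax(risk, .PROB_EPS), 1 - .PROB_EPS)
      .prediction_set(risk, qlogis(risk), "re_integ", cl)
    },
    conditional = {
      if (is.null(cl))
        stop("conditional prediction needs a 'cluster' column in newdata")
      post <- ranef_posterior(object, grid_size = order)
      unknown <- setdiff(unique(as.character(cl)), names(post))
      if (length(unknown))
        stop("cluster(s) not in the training data: ",
             paste(unknown, collapse = ", "),
             "; use a marginal prediction type for new clusters")
      risk <- numeric(length(eta_fixed))
      for (cid in unique(as.character(cl))) {
        idx <- as.character(cl) == cid
        pz <- post[[cid]]
        risk[idx] <- if (conditional_mode == "plugin")
          plogis(eta_fixed[idx] + pz$mean)
        else drop(plogis(outer(eta_fixed[idx], pz$nodes, "+")) %*% pz$weights)
      }
      risk <- pmin(pmax(risk, .PROB_EPS), 1 - .PROB_EPS)
      method <- paste0("cond_",
                       if (conditional_mode == "plugin") "plugin" else "integ")
      lp <- if (conditional_mode == "plugin")
        eta_fixed + vapply(as.character(cl), function(i) post[[i]]$mean,
                           numeric(1))
      else qlogis(risk)
      .prediction_set(risk, lp, method, cl)
    })
}

#' Posterior distribution of cluster random effects
#'
#' For each training cluster, returns a discrete approximation to the
#' posterior of its random intercept given the cluster's observed outcomes:
#' quadrature nodes `u_k` with normalised weights proportional to
#' `dnorm(u_k; 0, sigma_u) * prod_j Bernoulli(y_j | plogis(alpha + u_k +
#' x_j beta))`, plus the posterior mean (the empirical-Bayes estimate) and
#' posterior mode.
#'
#' @param object an `ri_fit`.
#' @param newdata optional clustered data frame to use as the cluster
#'   history instead of the training data.
#' @param grid_size number of quadrature nodes.
#' @return a named list (one element per cluster) of lists with `nodes`,
#'   `weights`, `mean`, `mode`.
#' @export
ranef_posterior <- function(object, newdata = NULL, grid_size = 41L) {
  data <- if (is.null(newdata)) object$data else clustered_data(newdata)
  if (nrow(data) < 1L) stop("empty cluster history")
  X <- .covariate_matrix(data, object$covariates)
  cf <- object$coef
  eta_fixed <- drop(cbind(1, X) %*% cf)
  y <- data$y
  s2 <- object$sigma_u2
  out <- list()
  for (cid in unique(as.character(data$cluster))) {
    idx <- as.character(data$cluster) == cid
    if (s2 == 0) {
      out[[cid]] <- list(nodes = 0, weights = 1, mean = 0, mode = 0)
      next
    }
    gh <- gauss_hermite_normal(grid_size)
    u <- sqrt(s2) * gh$nodes
    ETA <- outer(eta_fixed[idx], u, "+")
    lw <- log(gh$weights) +
      colSums(y[idx] * ETA -
                ifelse(ETA > 0, ETA + log1p(exp(-ETA)), log1p(exp(ETA))))
    w <- exp(lw - max(lw))
    w <- w / sum(w)
    out[[cid]] <- list(nodes = u, weights = w, mean = sum(w * u),
                       mode = u[which.max(w)])
  }
  out
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("Predicted risks (", attr(x, "method"), "), ", nrow(x),
      " records\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Write a prediction set to CSV
#'
#' @param x a `prediction_set`.
#' @param path output file.
#' @export
write_predictions_csv <- function(x, path) {
  df <- as.data.frame(x)
  df$method <- attr(x, "method")
  df$record <- seq_len(nrow(df))
  utils::write.csv(
    df[, c("record", intersect("cluster", names(df)), "method",
           "linear_predictor", "risk")],
    path, row.names = FALSE)
  invisible(path)
}
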