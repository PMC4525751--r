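## Model fitting: standard logistic MLE, random-intercepts logistic MLE by
## Gauss-Hermite quadrature, and GEE with independence or exchangeable
## working correlation.

.resolve_design <- function(formula, data, covariates = NULL) {
  data <- clustered_data(data, covariates)
  covs <- attr(data, "covariates")
  if (!is.null(formula)) {
    covs <- attr(stats::terms(formula, data = data[setdiff(names(data),
                                                           "cluster")]),
                 "term.labels")
  }
  list(data = data, covariates = covs,
       X = .covariate_matrix(data, covs), y = data$y,
       cluster = data$cluster)
}

#' Standard logistic regression ignoring clustering
#'
#' Fits the marginal logistic model by ordinary maximum likelihood, treating
#' all records as independent.  With clustered data the point estimates are
#' consistent for the marginal (population-average) coefficients even though
#' the naive standard errors are not trustworthy.
#'
#' @param data data frame with columns `cluster`, `y` and covariates
#'   (see [clustered_data()]).
#' @param formula optional one-sided selection of covariates, e.g.
#'   `~ x1 + x2`; default uses every covariate column.
#' @param include_intercept logical; drop the intercept with `FALSE`.
#' @param tol,maxit IRLS convergence tolerance (score max-norm) and
#'   iteration cap.
#' @return an object of class `marginal_fit`.
#' @examples
#' d <- data.frame(cluster = 1, y = rep(c(0, 1), c(7, 3)))
#' coef(logistic_mle(d))  # logit(0.3)
#' @export
logistic_mle <- function(data, formula = NULL, include_intercept = TRUE,
                         tol = 1e-8, maxit = 200L) {
  des <- .resolve_design(formula, data)
  X <- if (include_intercept) cbind("(Intercept)" = 1, des$X) else des$X
  if (ncol(X) == 0L) stop("empty model: no intercept and no covariates")
  fit <- logistic_irls(X, des$y, tol = tol, maxit = maxit)
  names(fit$coef) <- colnames(X)
  structure(list(coef = fit$coef, vcov = fit$vcov, loglik = fit$loglik,
                 method = "standard_mle", working_correlation = "independence",
                 converged = fit$converged, iter = fit$iter,
                 include_intercept = include_intercept,
                 covariates = des$covariates, n_obs = nrow(X),
                 n_clusters = length(unique(des$cluster)),
                 call = match.call()),
            class = "marginal_fit")
}

## ------------------------------------------------------------------------
## Random-intercepts model

## joint log-likelihood and score over all clusters, non-adaptive GH.
## theta = c(alpha, beta, log sigma_u); if sigma_fixed is non-NULL the last
## element is absent and sigma is held at sqrt(sigma_fixed).
.ri_objective <- function(theta, y, X, cluster, gh, sigma_fixed = NULL,
                          gradient = TRUE) {
  p <- ncol(X)
  alpha <- theta[1L]
  beta <- if (p > 0) theta[2:(p + 1L)] else numeric(0)
  sigma <- if (is.null(sigma_fixed)) exp(theta[p + 2L]) else sqrt(sigma_fixed)
  eta0 <- alpha + if (p > 0) drop(X %*% beta) else 0
  u <- sigma * gh$nodes
  q <- length(u)
  ETA <- outer(eta0, rep(1, q)) + outer(rep(1, length(eta0)), u)
  LL <- y * ETA - ifelse(ETA > 0, ETA + log1p(exp(-ETA)), log1p(exp(ETA)))
  H <- rowsum(LL, cluster, reorder = FALSE)            # K x q
  A <- sweep(H, 2L, log(gh$weights), "+")
  li <- .logsumexp_rows(A)
  out <- list(loglik = sum(li))
  if (gradient) {
    W <- exp(A - li)                                   # posterior node weights
    R <- y - plogis(ETA)
    S0 <- rowsum(R, cluster, reorder = FALSE)          # K x q, d h / d alpha
    g <- numeric(length(theta))
    g[1L] <- sum(W * S0)
    for (m in seq_len(p))
      g[m + 1L] <- sum(W * rowsum(R * X[, m], cluster, reorder = FALSE))
    if (is.null(sigma_fixed))
      g[p + 2L] <- sum(W * sweep(S0, 2L, u, "*"))      # d u / d log sigma = u
    out$gradient <- g
  }
  out
}

#' Marginal log-likelihood contribution of one cluster
#'
#' Evaluates `log integral prod_j Bernoulli(y_j | plogis(alpha + u + x_j
#' beta)) dN(u; 0, sigma_u2)` by Gauss-Hermite quadrature.  With
#' `sigma_u2 = 0` this is the plug-in log-likelihood at `u = 0`.
#'
#' @param alpha intercept.
#' @param beta covariate coefficient vector (length `ncol(X)`).
#' @param sigma_u2 random-intercept variance (>= 0).
#' @param y 0/1 outcomes of the cluster's records.
#' @param X covariate matrix of the cluster's records (no intercept column).
#' @param order quadrature order (>= 1).
#' @param adaptive logical; centre and scale the nodes at the mode and
#'   curvature of the integrand (adaptive Gauss-Hermite).
#' @return the log marginal likelihood of the cluster, a single number.
#' @export
ri_cluster_loglik <- function(alpha, beta, sigma_u2, y, X, order = 21L,
                              adaptive = FALSE) {
  X <- as.matrix(X)
  if (!all(is.finite(c(alpha, beta, sigma_u2))) || !all(is.finite(X)))
    stop("non-finite parameters or covariates")
  if (sigma_u2 < 0) stop("'sigma_u2' must be non-negative")
  if (order < 1) stop("'order' must be >= 1")
  eta0 <- alpha + if (ncol(X) > 0) drop(X %*% beta) else rep(0, length(y))
  hfun <- function(u) {           # vectorised over u: sum_j log Bernoulli
    vapply(u, function(ui) {
      eta <- eta0 + ui
      sum(y * eta - ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))))
    }, numeric(1))
  }
  if (sigma_u2 == 0) return(hfun(0))
  sigma <- sqrt(sigma_u2)
  if (!adaptive) {
    gh <- gauss_hermite_normal(order)
    h <- hfun(sigma * gh$nodes)
    mx <- max(h)
    return(mx + log(sum(gh$weights * exp(h - mx))))
  }
  ## adaptive: centre at the mode of g(u) = h(u) - u^2/(2 sigma^2)
  g1 <- function(u) sum(y - plogis(eta0 + u)) - u / sigma_u2
  g2 <- function(u) { p <- plogis(eta0 + u); -sum(p * (1 - p)) - 1 / sigma_u2 }
  mode <- 0
  for (it in 1:50) {
    step <- -g1(mode) / g2(mode)
    mode <- mode + step
    if (abs(step) < 1e-12) break
  }
  tau <- 1 / sqrt(-g2(mode))
  raw <- pracma::gaussHermite(max(order, 2L))
  uu <- mode + sqrt(2) * tau * raw$x
  lg <- hfun(uu) + stats::dnorm(uu, 0, sigma, log = TRUE)
  lterms <- log(raw$w) + raw$x^2 + lg
  mx <- max(lterms)
  log(sqrt(2) * tau) + mx + log(sum(exp(lterms - mx)))
}

#' Random-intercepts logistic regression via Gauss-Hermite quadrature
#'
#' Maximises the marginal likelihood of the logistic random-intercepts
#' model, integrating the cluster random effect `u_i ~ N(0, sigma_u^2)`
#' out of each cluster's likelihood by Gauss-Hermite quadrature.  The
#' variance is optimised on the log-sd scale so the boundary
#' `sigma_u^2 = 0` is approached smoothly; estimates below 1e-10 are
#' reported as exactly zero.  Optimisation is BFGS with analytic score,
#' followed by Newton polishing to score max-norm `tol`.
#'
#' @inheritParams logistic_mle
#' @param order quadrature order used during fitting (>= 5 recommended).
#' @param fix_sigma_u2 optional fixed value of the random-intercept
#'   variance; only `alpha` and `beta` are then estimated.  Required if the
#'   data contain a single cluster, where the variance is not identifiable.
#' @param adaptive logical; use adaptively centred quadrature (slower;
#'   finite-difference score).
#' @param start optional starting values `c(alpha, beta, log_sigma_u)`.
#' @return an object of class `ri_fit` with components `coef` (intercept
#'   and conditional coefficients), `sigma_u2`, `loglik`, `converged`,
#'   `quadrature_order`, `n_obs`, `n_clusters` and the training data
#'   (needed for conditional prediction).
#' @seealso [predict.ri_fit()] for the marginal and conditional risk
#'   calculations, [ranef_posterior()] for cluster-level posteriors.
#' @export
ri_logistic <- function(data, formula = NULL, order = 51L,
                        fix_sigma_u2 = NULL, adaptive = FALSE,
                        tol = 1e-8, maxit = 200L, start = NULL) {
  des <- .resolve_design(formula, data)
  y <- des$y; X <- des$X
  cluster <- factor(des$cluster)
  K <- nlevels(cluster)
  if (K < 2L && is.null(fix_sigma_u2))
    stop("sigma_u^2 is not identifiable from a single cluster; ",
         "supply 'fix_sigma_u2'")
  if (order < 5L && is.null(fix_sigma_u2))
    warning("quadrature order below 5 is unreliable for fitting")
  p <- ncol(X)

  if (!is.null(fix_sigma_u2) && fix_sigma_u2 == 0) {
    mle <- logistic_mle(data, formula)
    fit <- list(coef = mle$coef, sigma_u2 = 0, loglik = mle$loglik,
                converged = mle$converged, score_norm = NA_real_)
  } else {
    gh <- gauss_hermite_normal(order)
    mle <- tryCatch(logistic_mle(data, formula),
                    error = function(e) NULL)
    theta <- if (!is.null(start)) start else {
      st <- if (!is.null(mle)) unname(mle$coef) else numeric(p + 1L)
      c(st, if (is.null(fix_sigma_u2)) log(0.7) else NULL)
    }
    if (!is.null(fix_sigma_u2)) theta <- theta[seq_len(p + 1L)]

    if (adaptive) {
      negll <- function(th) {
        a <- th[1L]; b <- th[seq_len(p) + 1L]
        s2 <- if (is.null(fix_sigma_u2)) exp(2 * th[p + 2L]) else fix_sigma_u2
        -sum(vapply(levels(cluster), function(cl) {
          idx <- cluster == cl
          ri_cluster_loglik(a, b, s2, y[idx], X[idx, , drop = FALSE],
                            order, adaptive = TRUE)
        }, numeric(1)))
      }
      opt <- stats::optim(theta, negll, method = "BFGS",
                          control = list(maxit = maxit, reltol = 1e-12))
      theta <- opt$par
      grad_norm <- NA_real_
      conv <- opt$convergence == 0L
      ll <- -opt$value
    } else {
      fn <- function(th) -.ri_objective(th, y, X, cluster, gh,
                                        fix_sigma_u2, gradient = FALSE)$loglik
      gr <- function(th) -.ri_objective(th, y, X, cluster, gh,
                                        fix_sigma_u2)$gradient
      opt <- stats::optim(theta, fn, gr, method = "BFGS",
                          control = list(maxit = maxit, reltol = 1e-14))
      theta <- opt$par
      ## Newton polish on the analytic score
      for (it in 1:40) {
        ob <- .ri_objective(theta, y, X, cluster, gh, fix_sigma_u2)
        if (max(abs(ob$gradient)) < tol) break
        Hm <- .fd_jacobian(function(th)
          .ri_objective(th, y, X, cluster, gh, fix_sigma_u2)$gradient, theta)
        step <- tryCatch(solve((Hm + t(Hm)) / 2, ob$gradient),
                         error = function(e) NULL)
        if (is.null(step)) break
        h <- 1
        repeat {
          cand <- theta - h * step
          if (-fn(cand) >= ob$loglik - 1e-10 || h < 1e-6) break
          h <- h / 2
        }
        theta <- cand
      }
      ob <- .ri_objective(theta, y, X, cluster, gh, fix_sigma_u2)
      grad_norm <- max(abs(ob$gradient))
      ll <- ob$loglik
      conv <- opt$convergence == 0L &&
        (grad_norm < 1e-4 * max(1, abs(ll)) || grad_norm < 1e-6)
    }
    if (max(abs(theta[seq_len(p + 1L)])) > 30)
      stop("perfect or quasi-complete separation detected in ",
           "random-intercepts fit", call. = FALSE)
    s2 <- if (is.null(fix_sigma_u2)) exp(2 * theta[p + 2L]) else fix_sigma_u2
    if (s2 < 1e-10) s2 <- 0
    coefs <- theta[seq_len(p + 1L)]
    names(coefs) <- c("(Intercept)", des$covariates)
    fit <- list(coef = coefs, sigma_u2 = s2, loglik = ll, converged = conv,
                score_norm = grad_norm)
  }
  if (!fit$converged)
    warning("random-intercepts fit did not converge (score max-norm ",
            signif(fit$score_norm, 3), ")")
  structure(list(coef = fit$coef, sigma_u2 = fit$sigma_u2,
                 loglik = fit$loglik, converged = fit$converged,
                 score_norm = fit$score_norm, quadrature_order = order,
                 adaptive = adaptive, fixed_sigma = !is.null(fix_sigma_u2),
                 n_obs = length(y), n_clusters = K,
                 covariates = des$covariates, data = des$data,
                 call = match.call()),
            class = "ri_fit")
}

## central finite-difference Jacobian of a vector-valued function
.fd_jacobian <- function(f, x, h = 1e-5) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- numeric(n); e[i] <- h * max(1, abs(x[i]))
    J[, i] <- (f(x + e) - f(x - e)) / (2 * e[i])
  }
  J
}

## ------------------------------------------------------------------------
## GEE

#' Logistic GEE with independence or exchangeable working correlation
#'
#' Solves the generalised estimating equations for the marginal logistic
#' model by Fisher scoring, alternating with a moment estimate of the
#' exchangeable correlation parameter from standardised Pearson residuals.
#' Dispersion is fixed at 1 (binary outcome).  Robust (sandwich) standard
#' errors are returned in `vcov`.
#'
#' @inheritParams logistic_mle
#' @param working_correlation `"exchangeable"` or `"independence"`.
#' @return an object of class `marginal_fit`; for the exchangeable
#'   structure the estimated correlation is in `$rho`.
#' @export
gee_logistic <- function(data, formula = NULL,
                         working_correlation = c("exchangeable",
                                                 "independence"),
                         tol = 1e-8, maxit = 200L) {
  working_correlation <- match.arg(working_correlation)
  des <- .resolve_design(formula, data)
  y <- des$y
  X <- cbind("(Intercept)" = 1, des$X)
  cluster <- factor(des$cluster)
  K <- nlevels(cluster)
  p <- ncol(X)
  if (working_correlation == "exchangeable" && K < 2L)
    stop("exchangeable working correlation needs at least 2 clusters")

  init <- logistic_irls(X, y, tol = tol, maxit = maxit)
  beta <- init$coef
  rho <- 0
  sizes <- as.vector(table(cluster))
  npairs <- sum(sizes * (sizes - 1))          # ordered pairs
  converged <- working_correlation == "independence"

  if (working_correlation == "exchangeable" && npairs > 0) {
    for (it in seq_len(maxit)) {
      eta <- drop(X %*% beta)
      mu <- plogis(eta)
      v <- mu * (1 - mu)
      if (!all(is.finite(1 / v)))
        stop("GEE diverged: degenerate fitted probabilities", call. = FALSE)
      z <- (y - mu) / sqrt(v)
      ## moment estimator of rho from within-cluster residual products
      zsum <- rowsum(z, cluster, reorder = FALSE)
      z2sum <- rowsum(z^2, cluster, reorder = FALSE)
      rho_new <- (sum(zsum^2 - z2sum) / 2) / (npairs / 2 - p)
      rho_new <- max(min(rho_new, 0.99), -0.99)
      ## Fisher-scoring step at the current rho
      Xt <- X * sqrt(v)
      cs <- rowsum(Xt, cluster, reorder = FALSE)          # K x p colsums
      zs <- drop(zsum)
      a1 <- 1 / (1 - rho_new)
      a2 <- rho_new / ((1 - rho_new) * (1 + (sizes - 1) * rho_new))
      LHS <- a1 * crossprod(Xt) - crossprod(cs, cs * a2)
      RHS <- a1 * drop(crossprod(Xt, z)) - drop(crossprod(cs * a2, zs))
      step <- tryCatch(solve(LHS, RHS), error = function(e)
        stop("singular working covariance in GEE", call. = FALSE))
      ## damp oversized scoring steps to keep the iteration stable
      if (max(abs(step)) > 2) step <- step * 2 / max(abs(step))
      beta <- beta + step
      if (max(abs(step)) < tol && abs(rho_new - rho) < tol) {
        rho <- rho_new; converged <- TRUE; break
      }
      rho <- rho_new
    }
    if (!converged)
      stop("GEE failed to converge in ", maxit, " iterations", call. = FALSE)
  }

  ## sandwich variance at the solution
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  v <- mu * (1 - mu)
  Xt <- X * sqrt(v)
  z <- (y - mu) / sqrt(v)
  a1 <- 1 / (1 - rho)
  a2 <- if (rho != 0) rho / ((1 - rho) * (1 + (sizes - 1) * rho)) else
    rep(0, K)
  cs <- rowsum(Xt, cluster, reorder = FALSE)
  zs <- drop(rowsum(z, cluster, reorder = FALSE))
  Bread <- a1 * crossprod(Xt) - crossprod(cs, cs * a2)
  ## per-cluster estimating-function contributions
  Ui <- a1 * rowsum(Xt * z, cluster, reorder = FALSE) - cs * (a2 * zs)
  Meat <- crossprod(Ui)
  Binv <- solve(Bread)
  vc <- Binv %*% Meat %*% Binv
  names(beta) <- colnames(X)

  structure(list(coef = beta, vcov = vc, rho = rho,
                 loglik = NA_real_, method = "gee",
                 working_correlation = working_correlation,
                 converged = converged, covariates = des$covariates,
                 n_obs = length(y), n_clusters = K, call = match.call()),
            class = "marginal_fit")
}
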