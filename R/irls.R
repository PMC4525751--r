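## Newton/IRLS core for logistic regression, shared by the standard MLE,
## the GEE initialiser and both calibration models.

#' @keywords internal
.bernoulli_loglik <- function(y, eta) {
  ## y*eta - log(1 + exp(eta)), computed stably
  sum(y * eta - ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))))
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximises the independent-Bernoulli log-likelihood by Newton steps with
#' step-halving.  Detects complete/quasi-complete separation (diverging
#' coefficients) and signals an error rather than returning a spurious fit.
#'
#' @param X numeric design matrix (including an intercept column if wanted).
#' @param y 0/1 response vector.
#' @param offset optional offset added to the linear predictor.
#' @param tol convergence tolerance on the score max-norm.
#' @param maxit maximum Newton iterations.
#' @param coef_limit coefficient magnitude beyond which separation is
#'   declared.
#' @return list with `coef`, `vcov` (inverse observed information),
#'   `loglik`, `fitted`, `converged`, `iter`.
#' @keywords internal
logistic_irls <- function(X, y, offset = NULL, tol = 1e-8, maxit = 200L,
                          coef_limit = 30) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length of 'y' does not match nrow(X)")
  if (!all(y %in% c(0, 1))) stop("'y' must contain only 0 and 1")
  if (is.null(offset)) offset <- numeric(n)
  if (!all(is.finite(X)) || !all(is.finite(offset)))
    stop("non-finite values in design matrix or offset")

  beta <- numeric(p)
  eta <- drop(X %*% beta) + offset
  ll <- .bernoulli_loglik(y, eta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e)
      stop("singular information matrix in logistic IRLS", call. = FALSE))
    ## step-halving to guarantee monotone likelihood ascent
    h <- 1
    repeat {
      beta_new <- beta + h * step
      ll_new <- .bernoulli_loglik(y, drop(X %*% beta_new) + offset)
      if (ll_new >= ll - 1e-12 || h < 1e-8) break
      h <- h / 2
    }
    beta <- beta_new
    eta <- drop(X %*% beta) + offset
    ll <- ll_new
    if (max(abs(beta)) > coef_limit)
      stop("perfect or quasi-complete separation detected: ",
           "coefficient magnitude exceeded ", coef_limit, call. = FALSE)
  }
  if (!converged && iter >= maxit)
    stop("logistic IRLS failed to converge in ", maxit,
         " iterations (score max-norm ", signif(max(abs(score)), 3), ")",
         call. = FALSE)
  ## an essentially perfect fit of a binary outcome means the data are
  ## (quasi-)completely separated: the MLE is at infinity
  if (ll > -1e-6)
    stop("perfect or quasi-complete separation detected: ",
         "the fitted probabilities are degenerate", call. = FALSE)
  mu <- plogis(eta)
  info <- crossprod(X * (mu * (1 - mu)), X)
  list(coef = beta, vcov = solve(info), loglik = ll, fitted = mu,
       converged = converged, iter = iter)
}
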