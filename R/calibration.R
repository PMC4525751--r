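## Calibration assessment of predicted risks on validation data, and the
## latent-scale ICC / random-intercept variance conversions.

#' Calibration slope and calibration-in-the-large
#'
#' Assesses the calibration of predicted log-odds against observed binary
#' outcomes with the two standard validation regressions:
#'
#' * calibration slope: the slope `b1` of the logistic regression
#'   `logit P(Y = 1) = b0 + b1 * lp`.  A well-calibrated model has slope 1;
#'   a slope below 1 means the predictions are too widely dispersed.
#' * calibration-in-the-large (CITL): the intercept `a` of the
#'   intercept-only logistic model `logit P(Y = 1) = a + offset(lp)`.
#'   Zero means the average predicted risk matches the outcome prevalence;
#'   a positive value means the predictions are too low on average.
#'
#' Both models are fitted by the package's IRLS core; standard errors come
#' from the observed information.
#'
#' @param outcome 0/1 outcome vector.
#' @param linear_predictor predicted log-odds (`qlogis` of the predicted
#'   risk).
#' @param tol IRLS convergence tolerance.
#' @return `calibration()` returns an object of class `"calibration"` with
#'   `citl`, `citl_se`, `slope`, `slope_se` and `n`;
#'   `calibration_slope()` and `calibration_in_the_large()` return the
#'   corresponding single estimate with its SE as an attribute.
#' @examples
#' set.seed(1)
#' eta <- rnorm(5000)
#' y <- rbinom(5000, 1, plogis(eta))
#' calibration(y, eta)  # slope ~ 1, CITL ~ 0
#' @export
calibration <- function(outcome, linear_predictor, tol = 1e-10) {
  n <- length(outcome)
  if (length(linear_predictor) != n)
    stop("outcome and linear predictor lengths differ")
  if (!all(outcome %in% c(0, 1))) stop("outcome must be 0/1")
  if (!all(is.finite(linear_predictor)))
    stop("non-finite linear predictor")
  if (all(outcome == outcome[1L]))
    stop("outcome is constant; calibration is undefined")
  if (stats::var(linear_predictor) == 0)
    stop("constant linear predictor; calibration slope is undefined")
  sl <- logistic_irls(cbind(1, linear_predictor), outcome, tol = tol)
  cl <- logistic_irls(matrix(1, n, 1), outcome,
                      offset = linear_predictor, tol = tol)
  structure(list(citl = unname(cl$coef[1L]),
                 citl_se = sqrt(cl$vcov[1L, 1L]),
                 slope = unname(sl$coef[2L]),
                 slope_se = sqrt(sl$vcov[2L, 2L]),
                 slope_intercept = unname(sl$coef[1L]),
                 n = n),
            class = "calibration")
}

#' @rdname calibration
#' @export
calibration_slope <- function(outcome, linear_predictor, tol = 1e-10) {
  r <- calibration(outcome, linear_predictor, tol)
  structure(r$slope, se = r$slope_se)
}

#' @rdname calibration
#' @export
calibration_in_the_large <- function(outcome, linear_predictor,
                                     tol = 1e-10) {
  n <- length(outcome)
  if (!all(outcome %in% c(0, 1))) stop("outcome must be 0/1")
  if (all(outcome == outcome[1L]))
    stop("outcome is constant; CITL is undefined")
  cl <- logistic_irls(matrix(1, n, 1), outcome,
                      offset = linear_predictor, tol = tol)
  structure(unname(cl$coef[1L]), se = sqrt(cl$vcov[1L, 1L]))
}

#' @export
print.calibration <- function(x, ...) {
  cat("Calibration on", x$n, "records\n")
  cat(sprintf("  in-the-large: %8.4f (se %.4f)\n", x$citl, x$citl_se))
  cat(sprintf("  slope:        %8.4f (se %.4f)\n", x$slope, x$slope_se))
  invisible(x)
}

#' Latent-scale intra-cluster correlation conversions
#'
#' On the latent logistic scale the ICC of a random-intercepts model is
#' `sigma_u^2 / (pi^2 / 3 + sigma_u^2)`; these two functions convert in
#' both directions and are exact inverses.
#'
#' @param sigma_u2 random-intercept variance (>= 0).
#' @param icc intra-cluster correlation in `[0, 1)`.
#' @return the corresponding ICC or variance.
#' @examples
#' icc_from_sigma2(0.17)   # ~0.05
#' sigma2_from_icc(0.30)   # ~1.41
#' @export
icc_from_sigma2 <- function(sigma_u2) {
  if (any(sigma_u2 < 0)) stop("'sigma_u2' must be non-negative")
  sigma_u2 / (pi^2 / 3 + sigma_u2)
}

#' @rdname icc_from_sigma2
#' @export
sigma2_from_icc <- function(icc) {
  if (any(icc < 0) || any(icc >= 1)) stop("'icc' must be in [0, 1)")
  (pi^2 / 3) * icc / (1 - icc)
}
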