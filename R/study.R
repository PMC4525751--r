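## Orchestration of the simulation experiment: per-replicate fit/predict/
## calibrate, aggregation across replicates, and prediction curves.

.ALL_METHODS <- c("no_clustering", "re_zero", "re_integ", "re_approx", "gee")

#' One simulation replicate: sample, fit, predict, calibrate
#'
#' Draws a training/validation split from the source population (or a
#' Dirichlet-multinomial training set, per the config), fits the standard
#' MLE, random-intercepts and GEE models on the training data as needed,
#' computes each requested marginal prediction on the validation records
#' and returns the calibration of each method.  A failed fit marks only
#' the methods that depend on it as failed.
#'
#' @param pop a `source_population`.
#' @param config a [sim_config()].
#' @param methods subset of `no_clustering`, `re_zero`, `re_integ`,
#'   `re_approx`, `gee`.
#' @param order_fit,order_pred quadrature orders for fitting and for the
#'   integrated prediction.
#' @return data frame with one row per method: calibration estimates and
#'   SEs, the fitted `sigma_u2` where relevant, and a `failed` flag.
#' @export
run_replicate <- function(pop, config = pop$config, methods = .ALL_METHODS,
                          order_fit = 51L, order_pred = 41L) {
  methods <- match.arg(methods, .ALL_METHODS, several.ok = TRUE)
  if (config$sampling_scheme == "dirichlet") {
    training <- draw_training_dirichlet(config)
    validation <- pop$data
  } else {
    split <- draw_training_validation(pop, config)
    training <- split$training
    validation <- split$validation
  }
  y_val <- validation$y

  fits <- list()
  errs <- list()
  ## a fit that errors, or comes back non-converged, fails its methods only
  try_fit <- function(expr) {
    fit <- tryCatch(withCallingHandlers(expr, warning = function(w)
      tryInvokeRestart("muffleWarning")),
      error = function(e) conditionMessage(e))
    if (is.character(fit)) return(fit)
    if (!isTRUE(fit$converged)) return("fit did not converge")
    fit
  }
  as_fit <- function(x) if (is.character(x)) NULL else x
  as_err <- function(x) if (is.character(x)) x else NULL
  if ("no_clustering" %in% methods) {
    f <- try_fit(logistic_mle(training))
    fits$mle <- as_fit(f); errs$mle <- as_err(f)
  }
  if (any(c("re_zero", "re_integ", "re_approx") %in% methods)) {
    f <- try_fit(ri_logistic(training, order = order_fit))
    fits$ri <- as_fit(f); errs$ri <- as_err(f)
  }
  if ("gee" %in% methods) {
    f <- try_fit(gee_logistic(training, working_correlation = "exchangeable"))
    fits$gee <- as_fit(f); errs$gee <- as_err(f)
  }

  one <- function(method) {
    fit <- switch(method, no_clustering = fits$mle, gee = fits$gee, fits$ri)
    if (is.null(fit))
      return(data.frame(method = method, citl = NA_real_, citl_se = NA_real_,
                        slope = NA_real_, slope_se = NA_real_,
                        sigma_u2 = NA_real_, n = length(y_val),
                        failed = TRUE,
                        error = errs[[switch(method, no_clustering = "mle",
                                             gee = "gee", "ri")]] %||% ""))
    pred <- switch(method,
      no_clustering = ,
      gee = predict(fit, validation),
      predict(fit, validation, type = method, order = order_pred))
    cal <- tryCatch(calibration(y_val, pred$linear_predictor),
                    error = function(e) NULL)
    if (is.null(cal))
      return(data.frame(method = method, citl = NA_real_, citl_se = NA_real_,
                        slope = NA_real_, slope_se = NA_real_,
                        sigma_u2 = fit$sigma_u2 %||% NA_real_,
                        n = length(y_val), failed = TRUE,
                        error = "calibration failure"))
    data.frame(method = method, citl = cal$citl, citl_se = cal$citl_se,
               slope = cal$slope, slope_se = cal$slope_se,
               sigma_u2 = fit$sigma_u2 %||% NA_real_,
               n = length(y_val), failed = FALSE, error = "")
  }
  do.call(rbind, lapply(methods, one))
}

#' Run the full simulation study
#'
#' For each requested ICC: generates an independent source population,
#' repeats the two-stage sampling `n_replicates` times, fits the models
#' and calibrates each marginal prediction method on the held-out
#' clusters, then aggregates medians and empirical (across-replicate)
#' standard deviations.  All randomness derives from `seed`.
#'
#' @param config a [sim_config()]; its `icc` slot is overridden per
#'   scenario.
#' @param iccs ICC scenarios to run.
#' @param seed integer seed governing every draw.
#' @param methods prediction methods to evaluate (see [run_replicate()]).
#' @param order_fit,order_pred quadrature orders.
#' @param fresh_population with `TRUE` (default) every replicate generates
#'   its own source population before sampling, so the aggregated
#'   calibration estimates the design-averaged quantity; with `FALSE` one
#'   population per ICC scenario is shared by all replicates, and the
#'   results are conditional on that population's realised random
#'   intercepts.
#' @param verbose print progress.
#' @return an object of class `study_result`: `table` (per method and ICC:
#'   median and empirical SE of CITL and slope, mean, failures) and
#'   `replicates` (every replicate row).
#' @export
run_study <- function(config = sim_config(icc = 0.05),
                      iccs = c(0.05, 0.10, 0.15, 0.30), seed = 1L,
                      methods = .ALL_METHODS,
                      order_fit = 51L, order_pred = 41L,
                      fresh_population = TRUE, verbose = FALSE) {
  if (config$n_replicates < 1L) stop("n_replicates must be >= 1")
  set.seed(seed)
  scen_seeds <- sample.int(2147483646L, length(iccs))
  reps <- list()
  for (s in seq_along(iccs)) {
    cfg <- config
    cfg$icc <- iccs[s]
    cfg$sigma_u2 <- sigma2_from_icc(iccs[s])
    set.seed(scen_seeds[s])
    pop <- if (fresh_population) NULL else generate_source_population(cfg)
    rep_seeds <- sample.int(2147483646L, cfg$n_replicates)
    for (r in seq_len(cfg$n_replicates)) {
      set.seed(rep_seeds[r])
      if (fresh_population) pop <- generate_source_population(cfg)
      out <- run_replicate(pop, cfg, methods, order_fit, order_pred)
      out$icc <- iccs[s]
      out$replicate <- r
      reps[[length(reps) + 1L]] <- out
      if (verbose && r %% 10L == 0L)
        message("ICC ", iccs[s], ": replicate ", r, "/", cfg$n_replicates)
    }
  }
  replicates <- do.call(rbind, reps)
  agg <- do.call(rbind, lapply(split(
    replicates, list(replicates$method, replicates$icc), drop = TRUE),
    function(d) {
      ok <- !d$failed
      data.frame(method = d$method[1L], icc = d$icc[1L],
                 n_replicates = nrow(d), failures = sum(!ok),
                 citl = stats::median(d$citl[ok]),
                 citl_se = stats::sd(d$citl[ok]),
                 citl_mean = mean(d$citl[ok]),
                 slope = stats::median(d$slope[ok]),
                 slope_se = stats::sd(d$slope[ok]),
                 slope_mean = mean(d$slope[ok]))
    }))
  agg <- agg[order(agg$icc, match(agg$method, .ALL_METHODS)), ]
  rownames(agg) <- NULL
  flagged <- agg$failures > 0.2 * agg$n_replicates
  if (any(flagged))
    warning("more than 20% replicate failures for: ",
            paste(unique(agg$method[flagged]), collapse = ", "))
  structure(list(table = agg, replicates = replicates, seed = seed,
                 config = config, iccs = iccs),
            class = "study_result")
}

#' @export
print.study_result <- function(x, digits = 3, ...) {
  cat("Simulation study:", max(x$table$n_replicates), "replicates per ICC,",
      "seed", x$seed, "\n")
  tab <- x$table
  tab$citl <- sprintf("%.3f (%.3f)", tab$citl, tab$citl_se)
  tab$slope <- sprintf("%.3f (%.3f)", tab$slope, tab$slope_se)
  print.data.frame(tab[, c("method", "icc", "citl", "slope", "failures")],
                   row.names = FALSE)
  cat("entries: median (empirical SE) across replicates\n")
  invisible(x)
}

#' Write study outputs as CSV
#'
#' Writes `table1.csv` (the aggregated calibration table),
#' `replicates.csv` (per-replicate results) and `run.json` (seed and
#' configuration) into `dir`.
#'
#' @param x a `study_result`.
#' @param dir output directory (created if absent).
#' @export
write_study_csv <- function(x, dir) {
  stopifnot(inherits(x, "study_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$table, file.path(dir, "table1.csv"), row.names = FALSE)
  utils::write.csv(x$replicates, file.path(dir, "replicates.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(seed = x$seed, iccs = x$iccs,
                            config = unclass(x$config)),
                       file.path(dir, "run.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Predicted-risk curves along one predictor
#'
#' Evaluates each fitted model's predicted risk over a grid of the first
#' continuous predictor with every other predictor fixed at zero, the
#' standard display of how the naive RE-zero predictions are more extreme
#' than the properly marginalised ones.
#'
#' @param fits named list of fitted models; an `ri_fit` contributes the
#'   `re_zero`, `re_integ` and `re_approx` curves, a `marginal_fit` its
#'   own method.
#' @param x1 grid of values for the varied predictor.
#' @param covariates covariate names expected by the fits; defaults to the
#'   first fit's.
#' @param vary which covariate to vary (default the first).
#' @return a data frame of class `prediction_curves` with columns
#'   `method`, `x1`, `risk`.
#' @export
prediction_curves <- function(fits, x1 = seq(-4, 4, by = 0.1),
                              covariates = NULL, vary = NULL) {
  if (!length(fits)) stop("no fitted models supplied")
  covariates <- covariates %||% fits[[1L]]$covariates
  vary <- vary %||% covariates[1L]
  nd <- as.data.frame(matrix(0, length(x1), length(covariates),
                             dimnames = list(NULL, covariates)))
  nd[[vary]] <- x1
  rows <- list()
  for (f in fits) {
    if (inherits(f, "ri_fit")) {
      for (tp in c("re_zero", "re_integ", "re_approx")) {
        p <- predict(f, nd, type = tp)
        rows[[length(rows) + 1L]] <-
          data.frame(method = tp, x1 = x1, risk = p$risk)
      }
    } else if (inherits(f, "marginal_fit")) {
      p <- predict(f, nd)
      rows[[length(rows) + 1L]] <-
        data.frame(method = attr(p, "method"), x1 = x1, risk = p$risk)
    } else stop("unsupported fit object of class ", class(f)[1L])
  }
  out <- do.call(rbind, rows)
  class(out) <- c("prediction_curves", "data.frame")
  out
}

#' @export
plot.prediction_curves <- function(x, ...) {
  methods <- unique(x$method)
  cols <- seq_along(methods)
  grid_x <- sort(unique(x$x1))
  plot(range(grid_x), c(0, 1), type = "n", xlab = "x1",
       ylab = "predicted risk", ...)
  for (i in seq_along(methods)) {
    d <- x[x$method == methods[i], ]
    graphics::lines(d$x1, d$risk, col = cols[i], lwd = 2,
                    lty = if (methods[i] == "re_zero") 2 else 1)
  }
  graphics::legend("topleft", legend = methods, col = cols, lwd = 2, bty = "n")
  invisible(x)
}
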