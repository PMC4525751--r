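#' Validate a clustered binary-outcome dataset
#'
#' A clustered dataset is a plain data frame with a cluster identifier
#' column (`cluster`), a 0/1 outcome column (`y`) and numeric covariate
#' columns (by convention `x1`, ..., `xp`).  This function checks the
#' invariants and returns the data frame with covariate names recorded in
#' an attribute.
#'
#' @param data data frame with columns `cluster`, `y` and covariates.
#' @param covariates character vector of covariate column names; defaults
#'   to every column other than `cluster` and `y`.
#' @return the validated data frame, with attribute `"covariates"`.
#' @examples
#' d <- data.frame(cluster = c(1, 1, 2), y = c(0, 1, 1), x1 = rnorm(3))
#' d <- clustered_data(d)
#' attr(d, "covariates")
#' @export
clustered_data <- function(data, covariates = NULL) {
  data <- as.data.frame(data)
  if (!all(c("cluster", "y") %in% names(data)))
    stop("data must have 'cluster' and 'y' columns")
  if (nrow(data) < 1L) stop("data must contain at least one record")
  if (!all(data$y %in% c(0, 1))) stop("outcome 'y' must be 0 or 1")
  if (anyNA(data$cluster)) stop("missing cluster identifiers")
  if (is.null(covariates))
    covariates <- setdiff(names(data), c("cluster", "y"))
  for (v in covariates) {
    if (!v %in% names(data)) stop("missing covariate column: ", v)
    if (!is.numeric(data[[v]]) || !all(is.finite(data[[v]])))
      stop("covariate '", v, "' must be finite numeric")
  }
  attr(data, "covariates") <- covariates
  data
}

#' Read / write clustered datasets as delimited text
#'
#' The on-disk format is a CSV with a header row and columns `cluster`,
#' `y`, `x1`, ..., `xp`.
#'
#' @param path file path.
#' @return `read_clustered_csv` returns a validated data frame (see
#'   [clustered_data()]).
#' @export
read_clustered_csv <- function(path) {
  clustered_data(utils::read.csv(path))
}

#' @rdname read_clustered_csv
#' @param data clustered data frame.
#' @export
write_clustered_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

## design matrix of the covariate columns
.covariate_matrix <- function(data, covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- attr(data, "covariates")
    if (is.null(covariates))
      covariates <- setdiff(names(data), c("cluster", "y"))
  }
  as.matrix(data[, covariates, drop = FALSE])
}
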