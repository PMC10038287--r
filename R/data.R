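#' Bundle a feature matrix, response and row roles
#'
#' Rows are labelled `train`, `valid` or `test`.  Sub-SAGE estimates are
#' only meaningful on rows the model never saw during fitting; the
#' `test_independent` flag is the caller's assertion that the test rows are
#' such rows, and [subsage_estimate()] refuses to run without it (estimates
#' on training data systematically overstate importance and understate
#' uncertainty).
#'
#' @param x numeric feature matrix (rows = samples); genotype minor-allele
#'   counts 0/1/2 are simply numeric values
#' @param y response vector: real for regression, 0/1 for classification
#' @param role character/factor of row roles (`train`/`valid`/`test`), or
#'   `NULL` to label every row `test`
#' @param feature_names optional column names (defaults to `colnames(x)`)
#' @param test_independent logical; assert that the test rows were never
#'   used for model fitting
#' @return an object of class `subsage_data`
#' @export
subsage_data <- function(x, y, role = NULL, feature_names = colnames(x),
                         test_independent = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x and y disagree on the number of rows")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported; clean the data first")
  if (is.null(role)) role <- rep("test", nrow(x))
  role <- as.character(role)
  if (length(role) != nrow(x)) stop("role must label every row")
  bad <- setdiff(unique(role), c("train", "valid", "test"))
  if (length(bad)) stop("unknown role label(s): ", paste(bad, collapse = ", "))
  if (!is.null(feature_names)) colnames(x) <- feature_names
  structure(list(x = x, y = y, role = role, feature_names = colnames(x)),
            class = "subsage_data",
            test_independent = isTRUE(test_independent))
}

#' @export
print.subsage_data <- function(x, ...) {
  tab <- table(factor(x$role, levels = c("train", "valid", "test")))
  cat(sprintf("subsage_data: %d rows x %d features (train %d / valid %d / test %d)\n",
              nrow(x$x), ncol(x$x), tab[["train"]], tab[["valid"]], tab[["test"]]))
  cat(sprintf("test rows independent of model fitting: %s\n",
              isTRUE(attr(x, "test_independent"))))
  invisible(x)
}

#' @rdname subsage_data
#' @param data a `subsage_data` object
#' @param independent logical flag value to set
#' @export
mark_test_independent <- function(data, independent = TRUE) {
  stopifnot(inherits(data, "subsage_data"))
  attr(data, "test_independent") <- isTRUE(independent)
  data
}

#' @rdname subsage_data
#' @param role role(s) to select, or `NULL` for all rows
#' @export
data_matrix <- function(data, role = NULL) {
  stopifnot(inherits(data, "subsage_data"))
  if (is.null(role)) data$x else data$x[data$role %in% role, , drop = FALSE]
}

#' @rdname subsage_data
#' @export
data_response <- function(data, role = NULL) {
  stopifnot(inherits(data, "subsage_data"))
  if (is.null(role)) data$y else data$y[data$role %in% role]
}

.check_test_independent <- function(data) {
  if (!isTRUE(attr(data, "test_independent")))
    stop(paste("the test rows are not flagged as independent of model fitting;",
               "Sub-SAGE estimates computed on training data are invalid.",
               "Use mark_test_independent() if the rows truly were held out."))
  invisible(TRUE)
}
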