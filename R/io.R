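#' Write / read a dataset as delimited text
#'
#' The on-disk format is a plain CSV with a header: the feature columns,
#' the response column and a role column.
#'
#' @param data a [subsage_data()]
#' @param path output file
#' @param response name for the response column
#' @param role name for the role column
#' @export
write_dataset <- function(data, path, response = "y", role = "role") {
  stopifnot(inherits(data, "subsage_data"))
  df <- as.data.frame(data$x)
  df[[response]] <- data$y
  df[[role]] <- data$role
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @param test_independent flag asserting the test rows were held out of
#'   model fitting (see [mark_test_independent()])
#' @export
read_dataset <- function(path, response = "y", role = "role",
                         test_independent = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!response %in% names(df)) stop("response column '", response, "' not found")
  rl <- if (role %in% names(df)) df[[role]] else NULL
  x <- as.matrix(df[, setdiff(names(df), c(response, role)), drop = FALSE])
  subsage_data(x, df[[response]], rl, test_independent = test_independent)
}

#' Serialize Sub-SAGE estimates
#'
#' JSON records carry the full per-coalition delta table; the TSV is a
#' flat two-column (feature, psi_hat) ranking for downstream tools.
#'
#' @param estimates a `subsage_estimate` or list of them
#' @param path output file
#' @export
write_subsage_json <- function(estimates, path) {
  if (inherits(estimates, "subsage_estimate")) estimates <- list(estimates)
  recs <- lapply(estimates, function(e)
    list(feature = e$feature, name = e$feature_name, estimate = e$estimate,
         loss = e$loss, n_test = e$n_test, deltas = e$deltas))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_subsage_json
#' @export
write_subsage_tsv <- function(estimates, path) {
  if (inherits(estimates, "subsage_estimate")) estimates <- list(estimates)
  df <- data.frame(feature = vapply(estimates, `[[`, "", "feature_name"),
                   psi_hat = vapply(estimates, `[[`, 0.0, "estimate"))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize bootstrap results
#'
#' One JSON record per feature with the point estimate, interval
#' endpoints, BCa constants when present, and the seed.  Replicate vectors
#' can be dumped alongside as single-column text for external plotting.
#'
#' @param results a `bootstrap_result` or list of them
#' @param path output file
#' @param replicates_dir optional directory for per-feature replicate dumps
#' @export
write_bootstrap_json <- function(results, path, replicates_dir = NULL) {
  if (inherits(results, "bootstrap_result")) results <- list(results)
  recs <- lapply(results, function(r) {
    rec <- list(feature = r$feature, psi_hat = r$estimate, B = r$B,
                alpha = r$alpha,
                percentile = as.numeric(r$percentile),
                bca = if (is.null(r$bca)) NULL else c(r$bca$lower, r$bca$upper),
                z0 = if (is.null(r$bca)) NULL else r$bca$z0,
                a = if (is.null(r$bca)) NULL else r$bca$a,
                seed = r$seed)
    if (!is.null(replicates_dir)) {
      dir.create(replicates_dir, showWarnings = FALSE, recursive = TRUE)
      fp <- file.path(replicates_dir, sprintf("replicates_feature%d.txt", r$feature))
      utils::write.table(r$replicates, fp, row.names = FALSE, col.names = FALSE)
    }
    rec
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records every effective parameter and seed of a run so that any two
#' runs with identical manifests produce identical outputs.
#'
#' @param params named list of effective parameters
#' @param path output file
#' @export
write_manifest <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
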