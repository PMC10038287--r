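#' Read a tree ensemble from an XGBoost-style JSON dump
#'
#' Parses the per-tree JSON produced by `xgboost::xgb.dump(model,
#' dump_format = "json")`: nested node records with `nodeid`, `split`,
#' `split_condition`, `yes`/`no`/`missing` child ids and `leaf` values.
#' Split features named `f0`, `f1`, ... are mapped to 1-based column
#' indices; any other naming requires `feature_names` so that split names
#' can be matched to data columns.
#'
#' The dump stores thresholds and leaf values as exact decimal renderings
#' of the model's single-precision parameters, so the parsed ensemble
#' reproduces the source booster's margins up to float32 accumulation
#' error.  Traversal probabilities are unset after reading; call
#' [estimate_node_probabilities()] before any conditional expectation.
#'
#' Models that route missing values asymmetrically (a node whose `missing`
#' child differs from its `yes` child) are loaded and flagged via the
#' `missing_asymmetric` attribute; evaluation rejects missing values
#' regardless.
#'
#' @param text JSON text (single string or character vector of lines), or a
#'   path to a file containing it
#' @param n_features feature count `M`; defaults to the largest split index
#'   seen (or `length(feature_names)`)
#' @param offset additive margin offset (XGBoost `base_score`, already on
#'   the margin scale; use `qlogis(base_score)` for logistic models)
#' @param loss `"squared"` or `"xent"`
#' @param feature_names optional feature names used to resolve split names
#' @return a `tree_ensemble`
#' @export
read_xgboost_dump <- function(text, n_features = NULL, offset = 0,
                              loss = c("squared", "xent"), feature_names = NULL) {
  loss <- match.arg(loss)
  if (length(text) == 1L && !grepl("[\\[{]", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  txt <- paste(text, collapse = "\n")
  js <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                 error = function(e) stop("malformed JSON model dump: ",
                                          conditionMessage(e), call. = FALSE))
  if (!is.list(js)) stop("model dump must be a JSON array of trees")
  if (length(js) && !is.null(js[[1L]]$nodeid) == FALSE && is.null(js[[1L]]$leaf) &&
      is.null(js[[1L]]$split))
    stop("model dump must be a JSON array of tree node records")

  # dump numbers denote float32 model parameters printed in decimal; snap
  # them to the nearest single so threshold comparisons reproduce the
  # booster's own routing exactly
  f32 <- function(v) readBin(writeBin(as.numeric(v), raw(), size = 4L),
                             "numeric", size = 4L, n = length(v))

  resolve_feature <- function(split) {
    if (!is.null(feature_names)) {
      i <- match(split, feature_names)
      if (!is.na(i)) return(i)
    }
    if (grepl("^f[0-9]+$", split)) return(as.integer(sub("^f", "", split)) + 1L)
    stop(sprintf("cannot resolve split feature '%s'; supply feature_names", split))
  }

  asym <- FALSE
  parse_tree <- function(node) {
    rows <- list()
    rec <- function(nd) {
      if (!is.null(nd$leaf) && is.null(nd$children)) {
        rows[[length(rows) + 1L]] <<- data.frame(
          id = nd$nodeid, feature = NA_integer_, threshold = NA_real_,
          yes = NA_integer_, no = NA_integer_, value = f32(nd$leaf),
          default_left = NA)
        return(invisible())
      }
      if (is.null(nd$split) || is.null(nd$split_condition) ||
          is.null(nd$yes) || is.null(nd$no))
        stop("internal node record lacks split/split_condition/yes/no")
      ch <- nd$children
      if (is.null(ch) || length(ch) != 2L)
        stop(sprintf("node %s is not binary (has %d children)",
                     nd$nodeid, length(ch)))
      ids <- vapply(ch, function(c) as.integer(c$nodeid), 1L)
      if (!setequal(ids, c(nd$yes, nd$no)))
        stop(sprintf("node %s references child ids {%s} but contains {%s}",
                     nd$nodeid, paste(c(nd$yes, nd$no), collapse = ","),
                     paste(ids, collapse = ",")))
      miss <- if (is.null(nd$missing)) nd$yes else nd$missing
      if (miss != nd$yes) asym <<- TRUE
      rows[[length(rows) + 1L]] <<- data.frame(
        id = nd$nodeid, feature = resolve_feature(nd$split),
        threshold = f32(nd$split_condition),
        yes = as.integer(nd$yes), no = as.integer(nd$no), value = 0,
        default_left = miss == nd$yes)
      for (c in ch) rec(c)
    }
    rec(node)
    regression_tree(do.call(rbind, rows))
  }

  trees <- lapply(js, parse_tree)
  if (is.null(n_features)) {
    used <- unlist(lapply(trees, function(t) t$nodes$feature))
    n_features <- if (!is.null(feature_names)) length(feature_names)
                  else max(c(used, 1L), na.rm = TRUE)
  }
  ens <- tree_ensemble(trees, n_features = n_features, offset = offset,
                       loss = loss, feature_names = feature_names)
  attr(ens, "missing_asymmetric") <- asym
  ens
}

#' Convert a fitted model object to a `tree_ensemble`
#'
#' @param x a fitted model (currently an `xgb.Booster`)
#' @param ... passed to methods
#' @return a `tree_ensemble`
#' @export
as_tree_ensemble <- function(x, ...) UseMethod("as_tree_ensemble")

#' @describeIn as_tree_ensemble Extracts the JSON dump, the stored
#'   `base_score` and the feature names from a fitted XGBoost booster.
#'   When the booster was fitted with early stopping only the trees up to
#'   `best_iteration` are kept, matching what `predict()` uses.  For
#'   squared-error objectives the margin offset is `base_score` itself; for
#'   `binary:logistic` it is `qlogis(base_score)`.
#' @param loss `"squared"` or `"xent"`; defaults to the booster's objective
#' @param feature_names feature names; defaults to the booster's
#' @export
as_tree_ensemble.xgb.Booster <- function(x, loss = NULL, feature_names = NULL, ...) {
  if (!requireNamespace("xgboost", quietly = TRUE))
    stop("the 'xgboost' package is required to convert a fitted booster")
  cfg <- xgboost::xgb.config(x)
  if (is.character(cfg)) cfg <- jsonlite::fromJSON(cfg)
  objective <- tryCatch(cfg$learner$learner_train_param$objective,
                        error = function(e) NULL)
  if (is.null(loss))
    loss <- if (!is.null(objective) && grepl("binary", objective)) "xent" else "squared"
  base_score <- as.numeric(cfg$learner$learner_model_param$base_score)
  offset <- if (loss == "xent") stats::qlogis(base_score) else base_score
  n_features <- as.integer(cfg$learner$learner_model_param$num_feature)
  if (is.null(feature_names))
    feature_names <- tryCatch(xgboost::getinfo(x, "feature_name"),
                              error = function(e) NULL)
  if (!length(feature_names)) feature_names <- NULL
  dump <- xgboost::xgb.dump(x, dump_format = "json")
  ens <- read_xgboost_dump(dump, n_features = n_features, offset = offset,
                           loss = loss, feature_names = feature_names)
  best <- suppressWarnings(as.integer(xgboost::xgb.attr(x, "best_iteration")))
  if (length(best) == 1L && !is.na(best) && best + 1L < length(ens$trees))
    ens$trees <- ens$trees[seq_len(best + 1L)]
  attr(ens, "base_score") <- base_score
  ens
}
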