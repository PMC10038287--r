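#' Build a regression tree from a node table
#'
#' A regression tree is stored as a node table with one row per node.
#' Internal nodes carry a split feature (1-based column index into the
#' feature matrix), a numeric threshold and the ids of their two children;
#' leaves carry a value on the response (or margin) scale.  Routing is
#' "left iff x < threshold", the convention used by XGBoost JSON dumps.
#' Ties at the threshold are only reachable when a threshold coincides
#' exactly with a data value; XGBoost places thresholds strictly between
#' observed values (e.g. between integer genotype counts), so the choice
#' of strict versus non-strict comparison does not affect the intended use.
#'
#' @param nodes data.frame with columns `id` (integer node id, root first),
#'   `feature` (split feature index, `NA` for leaves), `threshold`, `yes`,
#'   `no` (ids of the left/right child, `NA` for leaves), `value` (leaf
#'   value, `NA` or 0 for internal nodes), and optionally `p_left`,
#'   `p_right` (traversal probabilities, `NA` until estimated) and
#'   `default_left` (missing-value routing kept from a dump).
#' @return an object of class `regression_tree`
#' @export
regression_tree <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  need <- c("id", "feature", "threshold", "yes", "no", "value")
  miss <- setdiff(need, names(nodes))
  if (length(miss))
    stop("node table is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(nodes$p_left)) nodes$p_left <- NA_real_
  if (is.null(nodes$p_right)) nodes$p_right <- NA_real_
  nodes$value[is.na(nodes$value)] <- 0
  tree <- structure(list(nodes = nodes), class = "regression_tree")
  validate_regression_tree(tree)
  tree
}

#' @rdname regression_tree
#' @param tree a `regression_tree`
#' @export
validate_regression_tree <- function(tree) {
  nd <- tree$nodes
  if (anyDuplicated(nd$id)) stop("duplicate node ids")
  internal <- !is.na(nd$feature)
  kids <- c(nd$yes[internal], nd$no[internal])
  if (anyNA(kids)) stop("internal node with a missing child reference")
  if (!all(kids %in% nd$id)) stop("unresolvable child reference in tree")
  if (anyDuplicated(kids)) stop("node referenced as child more than once; not a tree")
  roots <- setdiff(nd$id, kids)
  if (length(roots) != 1L) stop("tree must have exactly one root")
  if (nd$id[1L] != roots) stop("root node must be the first row of the node table")
  if (sum(!internal) != sum(internal) + 1L)
    stop("leaf count must equal internal-node count + 1")
  # reachability by walking from the root
  seen <- character(0)
  walk <- function(id) {
    seen <<- c(seen, as.character(id))
    i <- match(id, nd$id)
    if (internal[i]) {
      walk(nd$yes[i])
      walk(nd$no[i])
    }
  }
  walk(roots)
  if (length(seen) != nrow(nd)) stop("unreachable nodes in tree")
  p <- c(nd$p_left[internal], nd$p_right[internal])
  p <- p[!is.na(p)]
  if (length(p) && (any(p < 0) || any(p > 1)))
    stop("traversal probabilities must lie in [0, 1]")
  est <- internal & !is.na(nd$p_left) & !is.na(nd$p_right)
  if (any(est) && any(abs(nd$p_left[est] + nd$p_right[est] - 1) > 1e-12))
    stop("sibling traversal probabilities must sum to 1")
  invisible(tree)
}

#' Build a tree ensemble
#'
#' An ensemble is an ordered collection of [regression_tree()] objects plus
#' an additive margin offset (the XGBoost base score, in the same units as
#' the leaf values).  The ensemble's margin prediction for a complete
#' instance is `offset + sum of the leaf values reached`.
#'
#' @param trees list of `regression_tree` objects (may be empty)
#' @param n_features number of features `M` the model is defined over
#' @param offset additive margin offset
#' @param loss `"squared"` (regression, squared-error loss) or `"xent"`
#'   (binary classification, cross-entropy on the margin/logit scale)
#' @param feature_names optional character vector of length `n_features`
#' @return an object of class `tree_ensemble`
#' @export
tree_ensemble <- function(trees, n_features, offset = 0,
                          loss = c("squared", "xent"), feature_names = NULL) {
  loss <- match.arg(loss)
  stopifnot(is.list(trees), is.numeric(n_features), n_features >= 1)
  n_features <- as.integer(n_features)
  for (tr in trees) {
    if (!inherits(tr, "regression_tree")) stop("trees must be regression_tree objects")
    f <- tr$nodes$feature
    f <- f[!is.na(f)]
    if (length(f) && (any(f < 1) || any(f > n_features)))
      stop("split feature index outside [1, n_features]")
  }
  if (!is.null(feature_names) && length(feature_names) != n_features)
    stop("feature_names must have length n_features")
  structure(list(trees = trees, n_features = n_features, offset = offset,
                 loss = loss, feature_names = feature_names),
            class = "tree_ensemble")
}

#' @export
print.tree_ensemble <- function(x, ...) {
  nf <- length(trees_using_any_feature(x))
  cat(sprintf("tree_ensemble: %d trees, M = %d features (%d used), offset = %g, loss = %s\n",
              length(x$trees), x$n_features, nf, x$offset, x$loss))
  cat(sprintf("traversal probabilities: %s\n",
              if (has_node_probabilities(x)) "estimated" else "unset"))
  invisible(x)
}

#' Convenience constructor for a decision stump
#'
#' @param feature split feature index (1-based)
#' @param threshold split point; rows with `x < threshold` go left
#' @param left,right leaf values
#' @return a `regression_tree` with one split
#' @export
stump <- function(feature, threshold, left, right) {
  regression_tree(data.frame(
    id = 0:2, feature = c(feature, NA, NA), threshold = c(threshold, NA, NA),
    yes = c(1L, NA, NA), no = c(2L, NA, NA), value = c(0, left, right)))
}

# Flat arrays for the compiled core: global node indices, root first per
# tree, 0-based features, -1 for leaf links.
.flatten_ensemble <- function(ensemble) {
  trees <- ensemble$trees
  sizes <- vapply(trees, function(t) nrow(t$nodes), 1L)
  ptr <- c(0L, cumsum(sizes))
  feature <- integer(0); threshold <- numeric(0); yes <- integer(0)
  no <- integer(0); value <- numeric(0); p_left <- numeric(0); p_right <- numeric(0)
  for (ti in seq_along(trees)) {
    nd <- trees[[ti]]$nodes
    loc <- function(ids) ptr[ti] + match(ids, nd$id) - 1L
    internal <- !is.na(nd$feature)
    feature <- c(feature, ifelse(internal, nd$feature - 1L, -1L))
    threshold <- c(threshold, ifelse(internal, nd$threshold, 0))
    yes <- c(yes, ifelse(internal, loc(nd$yes), -1L))
    no <- c(no, ifelse(internal, loc(nd$no), -1L))
    value <- c(value, nd$value)
    p_left <- c(p_left, nd$p_left)
    p_right <- c(p_right, nd$p_right)
  }
  list(ptr = ptr, feature = as.integer(feature), threshold = as.numeric(threshold),
       yes = as.integer(yes), no = as.integer(no), value = as.numeric(value),
       p_left = as.numeric(p_left), p_right = as.numeric(p_right))
}

#' @export
predict.tree_ensemble <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (anyNA(x)) stop("missing feature values are not supported at evaluation")
  if (ncol(x) < object$n_features)
    stop("newdata has fewer columns than the model's feature count")
  cpp_margin(.flatten_ensemble(object), x, object$offset)
}

#' Which trees split on a feature
#'
#' Returns the indices of the trees that use feature `k` for splitting at
#' least once (the tree group often written tau_k).  Trees outside this set
#' produce identical conditional expectations whether or not `k` is in the
#' coalition, which is what makes the decomposed loss deltas cheap.
#'
#' @param ensemble a `tree_ensemble`
#' @param k feature index (1-based)
#' @return integer vector of tree indices (possibly empty)
#' @export
trees_using_feature <- function(ensemble, k) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  if (length(k) != 1L || is.na(k) || k < 1 || k > ensemble$n_features)
    stop("feature index k out of range")
  which(vapply(ensemble$trees, function(t) any(t$nodes$feature == k, na.rm = TRUE), TRUE))
}

trees_using_any_feature <- function(ensemble) {
  sort(unique(unlist(lapply(ensemble$trees,
                            function(t) t$nodes$feature[!is.na(t$nodes$feature)]))))
}

has_node_probabilities <- function(ensemble) {
  length(ensemble$trees) == 0L ||
    all(vapply(ensemble$trees, function(t) {
      internal <- !is.na(t$nodes$feature)
      !anyNA(t$nodes$p_left[internal])
    }, TRUE))
}

#' Estimate per-node traversal probabilities from data
#'
#' For every internal node splitting feature `f` at threshold `t`, the
#' left-child probability is the empirical fraction of the supplied rows
#' whose `f` value falls in the half-open interval implied by ancestor
#' splits on the *same* feature (under feature independence, splits on
#' other features carry no information about `f`).  All supplied rows are
#' counted at every node, regardless of which leaf they would reach.
#'
#' A node whose ancestor-restricted interval contains no data rows falls
#' back to the unconditional marginal fraction for its threshold (and to
#' 0.5 per child if there are no rows at all); fallbacks trigger a warning.
#'
#' @param ensemble a `tree_ensemble`
#' @param data a numeric feature matrix, or a [subsage_data()] object (by
#'   default its test rows are used)
#' @param role which role's rows to use when `data` is a `subsage_data`
#' @return the ensemble with `p_left`/`p_right` filled in on every node
#' @export
estimate_node_probabilities <- function(ensemble, data, role = "test") {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  x <- if (inherits(data, "subsage_data")) data_matrix(data, role) else as.matrix(data)
  if (nrow(x) < 1L) stop("probability estimation needs at least one data row")
  if (anyNA(x)) stop("missing feature values are not supported")
  if (ncol(x) < ensemble$n_features)
    stop("data has fewer columns than the model's feature count")
  est <- cpp_estimate_probs(.flatten_ensemble(ensemble), x, seq_len(nrow(x)))
  if (est$n_fallback > 0)
    warning(sprintf("%d node(s) had an empty ancestor-restricted interval; fell back to the marginal estimate",
                    est$n_fallback))
  off <- 0L
  for (ti in seq_along(ensemble$trees)) {
    nd <- ensemble$trees[[ti]]$nodes
    idx <- off + seq_len(nrow(nd))
    nd$p_left <- est$p_left[idx]
    nd$p_right <- est$p_right[idx]
    ensemble$trees[[ti]]$nodes <- nd
    off <- off + nrow(nd)
  }
  attr(ensemble, "n_fallback") <- est$n_fallback
  ensemble
}

#' Conditional expectation of a single tree given a coalition
#'
#' Recursive reference implementation: at a node whose split feature is in
#' the coalition `S`, follow the branch dictated by the instance; at any
#' other internal node return the probability-weighted sum of both
#' subtrees; at a leaf return its value.  This estimates the expectation of
#' the tree output over the excluded features, given the observed values of
#' the features in `S`, under feature independence.
#'
#' @param tree a `regression_tree` with estimated probabilities
#' @param coalition integer vector of feature indices treated as known
#' @param x numeric instance; must supply values for every feature in
#'   `coalition` that the tree splits on
#' @return scalar conditional expectation estimate
#' @export
cond_exp_tree <- function(tree, coalition, x) {
  nd <- tree$nodes
  coalition <- as.integer(coalition)
  rec <- function(id) {
    i <- match(id, nd$id)
    f <- nd$feature[i]
    if (is.na(f)) return(nd$value[i])
    if (f %in% coalition) {
      if (length(x) < f || is.na(x[f]))
        stop(sprintf("instance is missing a value for coalition feature %d", f))
      return(if (x[f] < nd$threshold[i]) rec(nd$yes[i]) else rec(nd$no[i]))
    }
    if (is.na(nd$p_left[i]))
      stop("traversal probabilities are unset; call estimate_node_probabilities() first")
    nd$p_left[i] * rec(nd$yes[i]) + nd$p_right[i] * rec(nd$no[i])
  }
  rec(nd$id[1L])
}

#' Conditional expectation of the ensemble margin given a coalition
#'
#' By linearity of the expectation this is the offset plus the sum of the
#' per-tree conditional expectations; it is the plug-in value function
#' v(S) evaluated at the instance, on the margin scale.
#'
#' @inheritParams cond_exp_tree
#' @param ensemble a `tree_ensemble` with estimated probabilities
#' @return scalar margin-scale value
#' @export
ensemble_value <- function(ensemble, coalition, x) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  vals <- vapply(ensemble$trees, cond_exp_tree, 0.0, coalition = coalition, x = x)
  ensemble$offset + sum(vals)
}
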