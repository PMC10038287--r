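#' Exact per-instance SHAP values for a tree ensemble
#'
#' Computes interventional (independent-feature) SHAP values exactly by
#' per-tree enumeration: each tree defines a cooperative game over its own
#' split features, whose conditional-expectation values are evaluated for
#' every subset of those features; Shapley weights over that small feature
#' set attribute the tree's prediction, features absent from a tree get
#' zero from it, and the per-tree attributions add up across the ensemble
#' (linearity of the Shapley value).  Exact for trees with at most 12
#' distinct split features — ample for the shallow boosters this package
#' targets.
#'
#' The base value `phi0` is the conditional expectation of the margin given
#' nothing, i.e. `ensemble_value(empty set)`.  Local accuracy holds by
#' construction: `phi0 + rowSums(phi)` equals the margin prediction of
#' every instance.
#'
#' @param ensemble `tree_ensemble` with estimated traversal probabilities
#' @param x numeric feature matrix of instances to explain
#' @return object of class `shap_matrix`: list with `phi` (N x M matrix,
#'   margin units) and scalar `phi0`
#' @export
tree_shap_exact <- function(ensemble, x) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing feature values are not supported")
  if (!has_node_probabilities(ensemble))
    stop("traversal probabilities are unset; call estimate_node_probabilities() first")
  M <- ensemble$n_features
  n <- nrow(x)
  flat <- .flatten_ensemble(ensemble)
  pv <- cpp_pattern_values(flat, flat$p_left, flat$p_right, x, seq_len(n), M)
  phi <- matrix(0, n, M)
  phi0 <- ensemble$offset
  for (tr in pv) {
    d <- length(tr$features)
    V <- tr$values
    phi0 <- phi0 + V[1L, 1L]  # v(empty) is constant across rows
    if (d == 0L) next
    masks <- 0:(2^d - 1L)
    sizes <- vapply(masks, function(m) sum(bitwAnd(m, 2L^(seq_len(d) - 1L)) > 0L), 1L)
    for (qi in seq_len(d)) {
      bit <- 2L^(qi - 1L)
      no_q <- masks[bitwAnd(masks, bit) == 0L]
      wts <- exp(lgamma(sizes[no_q + 1L] + 1) + lgamma(d - sizes[no_q + 1L]) -
                   lgamma(d + 1))
      contrib <- (V[, no_q + bit + 1L, drop = FALSE] -
                    V[, no_q + 1L, drop = FALSE]) %*% wts
      phi[, tr$features[qi]] <- phi[, tr$features[qi]] + contrib
    }
  }
  if (!is.null(ensemble$feature_names)) colnames(phi) <- ensemble$feature_names
  structure(list(phi = phi, phi0 = phi0), class = "shap_matrix")
}

#' Expected relative feature contribution (ERFC)
#'
#' Per-feature mean, over instances, of the feature's absolute SHAP share
#' of the instance's total attribution `|phi0| + sum_j |phi_j|`.  Scores
#' therefore lie in `[0, 1]` and a feature the model never consults scores
#' exactly zero.  Because ERFC measures only what the *model* does, it may
#' legitimately be computed on the data the model was trained on, unlike a
#' Sub-SAGE estimate.  Instances with an all-zero denominator (a constant
#' zero model) contribute nothing, with a warning.
#'
#' @param shap a `shap_matrix` from [tree_shap_exact()]
#' @return object of class `erfc_scores`: data.frame with `feature`,
#'   `name`, `erfc`, `rank`, sorted by descending score
#' @export
erfc_scores <- function(shap) {
  stopifnot(inherits(shap, "shap_matrix"))
  absphi <- abs(shap$phi)
  denom <- abs(shap$phi0) + rowSums(absphi)
  zero <- denom == 0
  if (any(zero)) {
    warning(sprintf("%d instance(s) have zero total attribution and contribute 0", sum(zero)))
    denom[zero] <- 1  # numerator is 0 there as well
  }
  kappa <- colMeans(absphi / denom)
  nm <- colnames(shap$phi)
  if (is.null(nm)) nm <- paste0("x", seq_along(kappa))
  out <- data.frame(feature = seq_along(kappa), name = nm, erfc = unname(kappa))
  out <- out[order(-out$erfc, out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("erfc_scores", "data.frame"))
}
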