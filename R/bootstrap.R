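#' Paired bootstrap of the Sub-SAGE estimator
#'
#' Quantifies the sampling uncertainty of the plug-in Sub-SAGE estimate by
#' resampling the independent test rows (feature vector and response
#' jointly) with replacement, holding the fitted model fixed.  Every
#' replicate re-estimates all node traversal probabilities on the
#' resampled rows — the probabilities are part of the plug-in estimator,
#' so they must follow the bootstrap empirical measure — and recomputes
#' the estimate.  Tree structure, thresholds and leaf values are never
#' refit.
#'
#' Replicate `b` draws its row indices from a counter-derived substream of
#' the root seed, so runs are reproducible and each replicate is
#' independent of how many others were computed.
#'
#' @inheritParams subsage_estimate
#' @param k focal feature index, or a vector of indices (the expensive
#'   per-replicate work is shared across features)
#' @param B number of bootstrap replicates (at least 100)
#' @param alpha per-tail level; the percentile interval has nominal
#'   coverage `1 - 2*alpha`
#' @param seed integer root seed for the resampling
#' @return for scalar `k`, an object of class `bootstrap_result` with the
#'   point estimate, the `B` replicates, the percentile interval and the
#'   seed; for vector `k`, a named list of such objects
#' @export
paired_bootstrap <- function(ensemble, data, k, loss = ensemble$loss,
                             B = 1000L, alpha = 0.025, seed = 1L) {
  loss <- match.arg(loss, c("squared", "xent"))
  stopifnot(inherits(ensemble, "tree_ensemble"), inherits(data, "subsage_data"))
  .check_test_independent(data)
  if (B < 100L) stop("B must be at least 100")
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)")
  ks <- as.integer(k)
  for (kk in ks) coalition_family(ensemble$n_features, kk)  # range checks
  td <- .resolve_test(ensemble, data)
  if (loss == "xent" && !all(td$y %in% c(0, 1)))
    stop("cross-entropy requires responses in {0,1}")
  flat <- .flatten_ensemble(ensemble)
  rows <- seq_len(nrow(td$x))
  point <- cpp_subsage(flat, flat$p_left, flat$p_right, td$x, td$y, rows, ks,
                       ensemble$n_features, ensemble$offset, loss == "xent")
  reps <- cpp_paired_bootstrap(flat, td$x, td$y, rows, ks,
                               ensemble$n_features, ensemble$offset,
                               loss == "xent", as.integer(B), as.numeric(seed))
  out <- lapply(seq_along(ks), function(j) {
    structure(list(feature = ks[j], estimate = point[[j]]$psi,
                   replicates = reps[, j], B = as.integer(B), alpha = alpha,
                   percentile = percentile_interval(reps[, j], alpha),
                   bca = NULL, seed = as.integer(seed), loss = loss,
                   n_test = nrow(td$x)),
              class = "bootstrap_result")
  })
  if (length(ks) == 1L) out[[1L]] else stats::setNames(out, as.character(ks))
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("paired bootstrap for feature %d: psi_hat = %.6g, B = %d\n",
              x$feature, x$estimate, x$B))
  cat(sprintf("  %.1f%% percentile interval: (%.6g, %.6g)\n",
              100 * (1 - 2 * x$alpha), x$percentile[1], x$percentile[2]))
  if (!is.null(x$bca))
    cat(sprintf("  BCa interval: (%.6g, %.6g)  [z0 = %.4f, a = %.4f]\n",
                x$bca$lower, x$bca$upper, x$bca$z0, x$bca$a))
  invisible(x)
}

# The B*alpha-th least value, with the ceiling taken when B*alpha is not an
# integer (so B = 1000, alpha = 0.025 picks exactly the 25th order
# statistic).
.order_stat <- function(sorted, B, level) {
  sorted[min(max(ceiling(B * level), 1L), B)]
}

#' Bootstrap percentile interval
#'
#' Order-statistic interval: the lower endpoint is the `ceiling(B*alpha)`-th
#' smallest replicate and the upper endpoint the `ceiling(B*(1-alpha))`-th.
#'
#' @param replicates numeric vector of bootstrap replicates
#' @param alpha per-tail level in (0, 0.5)
#' @return numeric `c(lower, upper)`
#' @export
percentile_interval <- function(replicates, alpha) {
  if (!length(replicates)) stop("empty replicate vector")
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)")
  s <- sort(replicates)
  B <- length(s)
  c(lower = .order_stat(s, B, alpha), upper = .order_stat(s, B, 1 - alpha))
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Adjusts the percentile interval for median bias (`z0`, the normal
#' quantile of the fraction of replicates strictly below the point
#' estimate) and for a skewness-dependent acceleration `a`, estimated
#' either by the jackknife over the test rows (leave-one-out re-estimates
#' of the Sub-SAGE value, probabilities included) or fixed at zero when the
#' replicate distribution is nearly symmetric — for large test sets the
#' jackknife is expensive and zero acceleration is usually adequate.
#'
#' @param result a `bootstrap_result` from [paired_bootstrap()]
#' @param acceleration `"jackknife"` or `"zero"`
#' @param ensemble,data required for `"jackknife"`: the same model and data
#'   the bootstrap was run on
#' @param alpha per-tail level; defaults to the bootstrap's
#' @return list with `lower`, `upper`, `z0`, `a` and the adjusted quantile
#'   levels; also attached to a copy of `result` as `$bca` (returned
#'   invisibly via attribute `result`)
#' @export
bca_interval <- function(result, acceleration = c("jackknife", "zero"),
                         ensemble = NULL, data = NULL, alpha = result$alpha) {
  acceleration <- match.arg(acceleration)
  stopifnot(inherits(result, "bootstrap_result"))
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)")
  reps <- result$replicates
  B <- length(reps)
  frac <- mean(reps < result$estimate)
  if (frac <= 0 || frac >= 1)
    stop(sprintf(paste("all %d replicates lie on one side of the point estimate",
                       "(fraction below = %g); the bias correction z0 is infinite",
                       "and the BCa interval is undefined"), B, frac))
  z0 <- stats::qnorm(frac)
  a <- 0
  if (acceleration == "jackknife") {
    if (is.null(ensemble) || is.null(data))
      stop("jackknife acceleration needs the ensemble and the data")
    td <- .resolve_test(ensemble, data)
    flat <- .flatten_ensemble(ensemble)
    loo <- cpp_jackknife_psi(flat, td$x, td$y, seq_len(nrow(td$x)),
                             result$feature, ensemble$n_features,
                             ensemble$offset, result$loss == "xent")
    d <- mean(loo) - loo
    denom <- sum(d^2)^1.5
    a <- if (denom > 0) sum(d^3) / (6 * denom) else 0
  }
  adj <- function(z_alpha) {
    z <- z0 + z_alpha
    stats::pnorm(z0 + z / (1 - a * z))
  }
  a1 <- adj(stats::qnorm(alpha))
  a2 <- adj(stats::qnorm(1 - alpha))
  s <- sort(reps)
  list(lower = .order_stat(s, B, a1), upper = .order_stat(s, B, a2),
       z0 = z0, a = a, alpha_adjusted = c(a1, a2))
}

#' One-sided bootstrap importance decision
#'
#' Tests the null hypothesis that the Sub-SAGE value of the feature is at
#' most zero: the null is rejected at level `alpha` when the one-sided
#' `(1-alpha)` lower percentile bound of the replicates exceeds zero.  No
#' multiple-testing adjustment is applied; when several features are
#' screened the caller must control the family-wise error externally.
#'
#' @param result a `bootstrap_result`
#' @param alpha test level
#' @return list with `feature`, `lower_bound`, `alpha` and logical `reject`
#' @export
one_sided_importance_test <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "bootstrap_result"))
  s <- sort(result$replicates)
  bound <- .order_stat(s, length(s), alpha)
  list(feature = result$feature, lower_bound = unname(bound), alpha = alpha,
       reject = unname(bound > 0))
}
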