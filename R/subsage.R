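#' The Sub-SAGE coalition family and its weights
#'
#' For a focal feature `k` among `M` features, the family contains the
#' empty set, every other singleton `{m}` and the set of all features
#' except `k` — the coalitions that capture the marginal effect of `k`,
#' its pairwise interactions, and its effect in the presence of everything
#' else.  The Shapley-style weight `|S|! (M-|S|-1)! / (3 (M-1)!)` reduces
#' to the closed forms 1/3 for the empty set, `1/(3(M-1))` per singleton
#' and 1/3 for the all-but-k set, so each of the three subset sizes carries
#' total weight 1/3 and the weights sum to one.  Closed forms are used
#' throughout: no factorials are ever evaluated, so `M` in the hundreds is
#' exact.
#'
#' @param M feature count; must be at least 3 (below that the three subset
#'   sizes collide and the family degenerates)
#' @param k focal feature index (1-based)
#' @return an object of class `coalition_family`: a list with `k`, `M`,
#'   `coalitions` (list of integer vectors) and `weights`
#' @export
coalition_family <- function(M, k) {
  M <- as.integer(M); k <- as.integer(k)
  if (is.na(M) || M < 3L)
    stop("M must be >= 3: with fewer features the singleton and all-but-k coalitions collide")
  if (is.na(k) || k < 1L || k > M) stop("focal feature k out of range")
  others <- setdiff(seq_len(M), k)
  coalitions <- c(list(integer(0)), lapply(others, function(m) m), list(others))
  weights <- c(1 / 3, rep(1 / (3 * (M - 1)), M - 1L), 1 / 3)
  structure(list(k = k, M = M, coalitions = coalitions, weights = weights),
            class = "coalition_family")
}

#' @export
print.coalition_family <- function(x, ...) {
  cat(sprintf("coalition_family: k = %d, M = %d, %d coalitions (weights 1/3, %d x 1/%d, 1/3)\n",
              x$k, x$M, length(x$coalitions), x$M - 1L, 3L * (x$M - 1L)))
  invisible(x)
}

.xent_loss <- function(y, margin) {
  # (1-y) m + log(1+e^{-m}), numerically safe for any margin
  (1 - y) * margin + ifelse(margin > 0, log1p(exp(-margin)),
                            -margin + log1p(exp(margin)))
}

.resolve_test <- function(ensemble, data, role = "test") {
  x <- data_matrix(data, role)
  y <- data_response(data, role)
  if (nrow(x) == 0L) stop("no rows with role '", role, "'")
  if (!has_node_probabilities(ensemble))
    stop("traversal probabilities are unset; call estimate_node_probabilities() first")
  list(x = x, y = y)
}

#' Direct (naive) estimate of the loss difference w(S u {k}) - w(S)
#'
#' Reference path used as the oracle for the decomposed estimators: for
#' every test row it evaluates the full ensemble conditional expectation
#' under `S` and under `S u {k}` via [ensemble_value()], applies the loss
#' to each (for cross-entropy the conditional expectation sits on the
#' margin *inside* the loss), and returns the difference of mean losses.
#' Quadratic in ensemble size per row; intended for small models and tests.
#'
#' @param ensemble `tree_ensemble` with probabilities estimated on the same
#'   rows used here
#' @param data a [subsage_data()]; the test rows are used
#' @param k focal feature (must not be in `S`)
#' @param S coalition (integer feature indices, possibly empty)
#' @param loss `"squared"` or `"xent"`
#' @return scalar estimated loss difference
#' @export
naive_delta_loss <- function(ensemble, data, k, S = integer(0),
                             loss = ensemble$loss) {
  loss <- match.arg(loss, c("squared", "xent"))
  if (k %in% S) stop("k must not be an element of S")
  td <- .resolve_test(ensemble, data)
  vS <- apply(td$x, 1L, function(r) ensemble_value(ensemble, S, r))
  vSk <- apply(td$x, 1L, function(r) ensemble_value(ensemble, sort(c(S, k)), r))
  if (loss == "squared") {
    mean((td$y - vS)^2) - mean((td$y - vSk)^2)
  } else {
    if (!all(td$y %in% c(0, 1))) stop("cross-entropy requires responses in {0,1}")
    mean(.xent_loss(td$y, vS)) - mean(.xent_loss(td$y, vSk))
  }
}

# Decomposed delta for an arbitrary coalition: per-tree conditional
# expectations split by tau_k, combined through the algebraic expansion of
# the loss difference (identical to naive_delta_loss up to float error).
.delta_decomposed <- function(ensemble, data, k, S, loss) {
  td <- .resolve_test(ensemble, data)
  if (k %in% S) stop("k must not be an element of S")
  if (loss == "xent" && !all(td$y %in% c(0, 1)))
    stop("cross-entropy requires responses in {0,1}")
  flat <- .flatten_ensemble(ensemble)
  M <- ensemble$n_features
  pv <- cpp_pattern_values(flat, flat$p_left, flat$p_right, td$x,
                           seq_len(nrow(td$x)), M)
  tk <- trees_using_feature(ensemble, k)
  n <- nrow(td$x)
  AS <- ASk <- CS <- numeric(n)
  col_for <- function(tree, coal) {
    sub <- intersect(coal, tree$features)
    1L + sum(2L^(match(sub, tree$features) - 1L))
  }
  for (ti in seq_along(pv)) {
    tr <- pv[[ti]]
    if (ti %in% tk) {
      AS <- AS + tr$values[, col_for(tr, S)]
      ASk <- ASk + tr$values[, col_for(tr, sort(c(S, k)))]
    } else {
      CS <- CS + tr$values[, col_for(tr, S)]
    }
  }
  if (loss == "squared") {
    dA <- ASk - AS
    mean(2 * td$y * dA + AS^2 - ASk^2 - 2 * (CS + ensemble$offset) * dA)
  } else {
    mS <- AS + CS + ensemble$offset
    mSk <- ASk + CS + ensemble$offset
    mean((1 - td$y) * (AS - ASk) +
           ifelse(mS > 0, log1p(exp(-mS)), -mS + log1p(exp(mS))) -
           ifelse(mSk > 0, log1p(exp(-mSk)), -mSk + log1p(exp(mSk))))
  }
}

#' Decomposed squared-error loss difference
#'
#' Computes the same quantity as [naive_delta_loss()] with squared-error
#' loss, but through the decomposition over the trees that split on `k`:
#' only the response cross term, the squared sums of the tau_k trees under
#' `S` and `S u {k}`, and a cross term with the remaining trees (plus the
#' margin offset) are needed.  The two paths agree to floating-point
#' accuracy; the decomposition is what makes the coalition sweep cheap.
#'
#' @inheritParams naive_delta_loss
#' @export
delta_loss_squared <- function(ensemble, data, k, S = integer(0)) {
  .delta_decomposed(ensemble, data, k, S, "squared")
}

#' Decomposed binary cross-entropy loss difference
#'
#' Margin-scale decomposition of the cross-entropy difference: the linear
#' term involves only the trees splitting on `k`, while the log-partition
#' term uses the full margins under `S` and `S u {k}`.  Evaluated with
#' overflow-safe `log1p`/`exp` branches, finite for any margin.
#'
#' @inheritParams naive_delta_loss
#' @export
delta_loss_xent <- function(ensemble, data, k, S = integer(0)) {
  .delta_decomposed(ensemble, data, k, S, "xent")
}

# Shared fast path: psi and per-coalition deltas for one or more focal
# features on an explicit row set, with probabilities estimated on exactly
# those rows (used by the point estimate, the bootstrap identity check and
# the calibration code).
.psi_on_rows <- function(ensemble, x, y, rows, ks, loss) {
  flat <- .flatten_ensemble(ensemble)
  est <- cpp_estimate_probs(flat, x, rows)
  cpp_subsage(flat, est$p_left, est$p_right, x, y, rows, as.integer(ks),
              ensemble$n_features, ensemble$offset, loss == "xent")
}

#' Sub-SAGE plug-in estimate for one feature
#'
#' Weighted sum of the decomposed loss differences over the coalition
#' family of `k`, computed on the independent test rows with the node
#' probabilities already estimated on those rows.  Refuses to run unless
#' the data's test rows are flagged independent of model fitting.
#'
#' @param ensemble `tree_ensemble` with probabilities estimated on the test
#'   rows of `data`
#' @param data a [subsage_data()] whose test rows are independent of the
#'   model fit (see [mark_test_independent()])
#' @param k focal feature index
#' @param loss loss to decompose; defaults to the ensemble's own
#' @return an object of class `subsage_estimate`: feature, estimate,
#'   loss, `n_test`, and a `deltas` data.frame (coalition, size, weight,
#'   delta) whose weighted delta sum equals the estimate
#' @export
subsage_estimate <- function(ensemble, data, k, loss = ensemble$loss) {
  loss <- match.arg(loss, c("squared", "xent"))
  stopifnot(inherits(ensemble, "tree_ensemble"), inherits(data, "subsage_data"))
  .check_test_independent(data)
  M <- ensemble$n_features
  fam <- coalition_family(M, k)  # validates M >= 3 and k in range
  td <- .resolve_test(ensemble, data)
  if (loss == "xent" && !all(td$y %in% c(0, 1)))
    stop("cross-entropy requires responses in {0,1}")
  flat <- .flatten_ensemble(ensemble)
  res <- cpp_subsage(flat, flat$p_left, flat$p_right, td$x, td$y,
                     seq_len(nrow(td$x)), as.integer(k), M, ensemble$offset,
                     loss == "xent")[[1L]]
  others <- setdiff(seq_len(M), k)
  nm <- ensemble$feature_names
  lab <- function(i) if (is.null(nm)) paste0("x", i) else nm[i]
  deltas <- data.frame(
    coalition = c("{}", sprintf("{%s}", vapply(others, lab, "")),
                  sprintf("all-but-%s", lab(k))),
    size = c(0L, rep(1L, M - 1L), M - 1L),
    weight = fam$weights,
    delta = c(res$d_empty, res$d_single[others], res$d_all))
  structure(list(feature = as.integer(k), feature_name = lab(k),
                 estimate = res$psi, loss = loss, n_test = nrow(td$x),
                 deltas = deltas),
            class = "subsage_estimate")
}

#' @export
print.subsage_estimate <- function(x, ...) {
  cat(sprintf("Sub-SAGE estimate for feature %s: %.6g (%s loss, N_I = %d)\n",
              x$feature_name, x$estimate, x$loss, x$n_test))
  invisible(x)
}

#' Sub-SAGE estimates for several features as a table
#'
#' @inheritParams subsage_estimate
#' @param features integer vector of focal features
#' @return data.frame with columns `feature`, `name`, `psi_hat`
#' @export
subsage_table <- function(ensemble, data, features, loss = ensemble$loss) {
  est <- lapply(features, function(k) subsage_estimate(ensemble, data, k, loss))
  data.frame(feature = vapply(est, `[[`, 1L, "feature"),
             name = vapply(est, `[[`, "", "feature_name"),
             psi_hat = vapply(est, `[[`, 0.0, "estimate"))
}

#' Exact SAGE values by exhaustive Shapley enumeration
#'
#' Brute-force Shapley attribution for a cooperative game given by an
#' arbitrary value function over feature subsets: every subset of the
#' effective features is enumerated, so the cost is `2^d` evaluations of
#' `value_fn`.  Features outside `features` are null players and receive
#' exactly zero (returned when `n_features` is supplied).
#'
#' @param value_fn function taking an integer vector (a coalition, subset
#'   of `features`) and returning the scalar value w(S)
#' @param features integer vector of effective features (at most 15)
#' @param n_features optionally the full feature count; the return is then
#'   a length-`n_features` vector with zeros for the dummies
#' @return named numeric vector of per-feature Shapley values
#' @export
sage_bruteforce <- function(value_fn, features, n_features = NULL) {
  d <- length(features)
  if (d > 15L) stop("more than 15 effective features; exhaustive enumeration refused")
  masks <- 0:(2^d - 1L)
  w <- vapply(masks, function(m) {
    value_fn(features[bitwAnd(m, 2L^(seq_len(d) - 1L)) > 0L])
  }, 0.0)
  lgam <- lgamma(seq_len(d) + 1)  # log factorials 1!..d!
  wt <- function(s) exp(lgamma(s + 1) + lgamma(d - s) - lgam[d])
  phi <- numeric(d)
  for (qi in seq_len(d)) {
    bit <- 2L^(qi - 1L)
    no_q <- masks[bitwAnd(masks, bit) == 0L]
    sizes <- vapply(no_q, function(m) sum(bitwAnd(m, 2L^(seq_len(d) - 1L)) > 0L), 1L)
    phi[qi] <- sum(wt(sizes) * (w[no_q + bit + 1L] - w[no_q + 1L]))
  }
  names(phi) <- as.character(features)
  if (!is.null(n_features)) {
    out <- numeric(n_features)
    out[features] <- phi
    names(out) <- as.character(seq_len(n_features))
    return(out)
  }
  phi
}

#' Moment summary of a linear fit on independent test data
#'
#' Collects the fitted coefficients together with the per-feature sample
#' covariance with the response and the sample variance, all computed on
#' held-out test data, as needed for the closed-form Sub-SAGE value of a
#' linear regression model.
#'
#' @param fit an `lm` object, or a coefficient vector aligned with the
#'   columns of `x` (an intercept entry named `"(Intercept)"` is dropped)
#' @param x test feature matrix
#' @param y test response
#' @return an object of class `linear_fit_summary` with `beta`, `cov_xy`,
#'   `var_x`
#' @export
linear_fit_summary <- function(fit, x, y) {
  x <- as.matrix(x)
  beta <- if (inherits(fit, "lm")) stats::coef(fit) else fit
  beta <- beta[setdiff(names(beta), "(Intercept)")]
  if (is.null(names(beta)) || !all(names(beta) %in% colnames(x)))
    beta <- stats::setNames(as.numeric(beta), colnames(x)[seq_along(beta)])
  beta <- beta[colnames(x)]
  cov_xy <- as.numeric(stats::cov(x, y))
  var_x <- apply(x, 2L, stats::var)
  structure(list(beta = beta, cov_xy = stats::setNames(cov_xy, colnames(x)),
                 var_x = var_x),
            class = "linear_fit_summary")
}

#' Closed-form Sub-SAGE value for a linear regression model
#'
#' For a fitted linear model evaluated with squared-error loss on
#' independent test data, the loss difference for feature `k` is the same
#' for every coalition in the family and equals
#' `2 beta_k Cov(Y, X_k) - beta_k^2 Var(X_k)`; this is therefore also the
#' Sub-SAGE value.  The first term measures how much of the fitted effect
#' is reproduced in fresh data; the second is the variance the model pays
#' for carrying the feature, which is why a spuriously fitted feature gets
#' a negative value.
#'
#' @param summary a [linear_fit_summary()]
#' @param k feature index or name
#' @return scalar closed-form Sub-SAGE value
#' @export
linear_subsage_closed_form <- function(summary, k) {
  stopifnot(inherits(summary, "linear_fit_summary"))
  b <- summary$beta[k]
  unname(2 * b * summary$cov_xy[k] - b^2 * summary$var_x[k])
}
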