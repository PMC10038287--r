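# Builders for hand-made and random shallow ensembles plus small oracles
# used across the tests.  All fixtures are generated in code.

# depth-2 tree on explicit features/thresholds/leaves (root, two internal
# children, four leaves)
depth2_tree <- function(f_root, t_root, f_left, t_left, f_right, t_right,
                        leaves) {
  regression_tree(data.frame(
    id = 0:6,
    feature = c(f_root, f_left, f_right, NA, NA, NA, NA),
    threshold = c(t_root, t_left, t_right, NA, NA, NA, NA),
    yes = c(1L, 3L, 5L, NA, NA, NA, NA),
    no = c(2L, 4L, 6L, NA, NA, NA, NA),
    value = c(0, 0, 0, leaves)))
}

rand_tree <- function(M) {
  if (stats::runif(1) < 0.3) {
    stump(sample.int(M, 1), stats::rnorm(1), stats::rnorm(1, sd = 0.5),
          stats::rnorm(1, sd = 0.5))
  } else {
    fs <- sample.int(M, 3, replace = TRUE)
    depth2_tree(fs[1], stats::rnorm(1), fs[2], stats::rnorm(1),
                fs[3], stats::rnorm(1), stats::rnorm(4, sd = 0.5))
  }
}

rand_ensemble <- function(n_trees, M, loss = "squared", offset = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree_ensemble(replicate(n_trees, rand_tree(M), simplify = FALSE),
                n_features = M, offset = offset, loss = loss)
}

rand_dataset <- function(n, M, seed = NULL, binary = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(stats::rnorm(n * M), n, M)
  y <- if (binary) stats::rbinom(n, 1, 0.5) else stats::rnorm(n)
  subsage_data(x, y, test_independent = TRUE)
}

# Exhaustive-permutation Shapley oracle for a small value function.
perm_shapley <- function(value_fn, features) {
  d <- length(features)
  perms <- if (d == 1L) matrix(1L) else do.call(rbind, combinat_perms(d))
  phi <- numeric(d)
  for (r in seq_len(nrow(perms))) {
    S <- integer(0)
    for (j in perms[r, ]) {
      phi[j] <- phi[j] + value_fn(sort(c(S, features[j]))) - value_fn(S)
      S <- sort(c(S, features[j]))
    }
  }
  stats::setNames(phi / nrow(perms), as.character(features))
}

combinat_perms <- function(d) {
  if (d == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(d)) {
    for (p in combinat_perms(d - 1L)) {
      rest <- setdiff(seq_len(d), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

# Full 2^M per-instance Shapley values via ensemble_value (brute force).
brute_shap_instance <- function(ensemble, x) {
  M <- ensemble$n_features
  value_fn <- function(S) ensemble_value(ensemble, S, x)
  perm_free_shapley(value_fn, M)
}

# Subset-enumeration Shapley (weights form, avoids factorial permutations).
perm_free_shapley <- function(value_fn, M) {
  masks <- 0:(2^M - 1L)
  w <- vapply(masks, function(m) value_fn(which(bitwAnd(m, 2L^(0:(M - 1))) > 0L)), 0)
  phi <- numeric(M)
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, 2L^(0:(M - 1))) > 0L), 1L)
  for (k in seq_len(M)) {
    bit <- 2L^(k - 1L)
    no_k <- masks[bitwAnd(masks, bit) == 0L]
    s <- sizes[no_k + 1L]
    wt <- exp(lgamma(s + 1) + lgamma(M - s) - lgamma(M + 1))
    phi[k] <- sum(wt * (w[no_k + bit + 1L] - w[no_k + 1L]))
  }
  phi
}

# Naive loss-difference deltas with cached conditional values, for sweeps
# over many (k, S) pairs: identical arithmetic to naive_delta_loss but each
# coalition's per-row values are computed once.
naive_delta_cached <- function(ensemble, data, loss) {
  x <- data_matrix(data, "test")
  y <- data_response(data, "test")
  cache <- new.env(parent = emptyenv())
  vfor <- function(S) {
    key <- paste0("s", paste(sort(S), collapse = "."))
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- apply(x, 1L, function(r) ensemble_value(ensemble, S, r))
    cache[[key]] <- v
    v
  }
  lossfn <- if (loss == "squared") {
    function(v) mean((y - v)^2)
  } else {
    function(v) mean((1 - y) * v + ifelse(v > 0, log1p(exp(-v)),
                                          -v + log1p(exp(v))))
  }
  function(k, S) lossfn(vfor(S)) - lossfn(vfor(sort(c(S, k))))
}

# random depth-2 trees can re-split a feature into an empty ancestor
# interval; the documented marginal fallback then warns, which is noise in
# these sweeps
est_probs_q <- function(ensemble, data, ...) {
  suppressWarnings(estimate_node_probabilities(ensemble, data, ...))
}
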