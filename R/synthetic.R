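#' Configuration of the synthetic benchmark
#'
#' The benchmark response is a known nonlinear function of six influential
#' features plus Gaussian noise:
#'
#' `f(x) = a0 + a1 x1 + a2 x2 + a21 x1 exp(x2) + a3 x3^2 + a4 sin(x4) +
#'  a5 log(1 + x5) - x5 1(x6 > 7)`
#'
#' with `x1 ~ Binom(2, 0.4)` (a common-variant-like genotype),
#' `x2 ~ Binom(2, 0.04)` (rare-variant-like), `x3 ~ Gamma(10, rate 2)`,
#' `x4 ~ Unif(0, pi)`, `x5 ~ Pois(15)`, `x6 ~ N(0, 10)` and
#' `eps ~ N(0, 2)`.  On top sit 41 Gaussian and 53 Binomial(2, p) noise
#' features whose per-feature parameters are drawn once from uniform
#' ranges (`mu ~ U(-3,3)`, `sigma ~ U(0.5,3)`, `p ~ U(0.05,0.5)`); being
#' null players they never affect the true importance values.
#'
#' @param n total sample size
#' @param fractions train/valid/test split fractions (must sum to 1)
#' @param noise_sd standard deviation of the response noise
#' @param a0,a1,a2,a21,a3,a4,a5 signal coefficients
#' @param n_noise_normal,n_noise_binom counts of Gaussian / Binomial noise
#'   features (41 and 53 give the benchmark's 100 features in total)
#' @return an object of class `synthetic_config`
#' @export
synthetic_config <- function(n = 16000L, fractions = c(0.5, 0.3, 0.2),
                             noise_sd = 2,
                             a0 = -0.5, a1 = 0.03, a2 = -0.05, a21 = 0.3,
                             a3 = 0.02, a4 = 0.35, a5 = -0.2,
                             n_noise_normal = 41L, n_noise_binom = 53L) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three positive numbers summing to 1")
  structure(list(n = as.integer(n), fractions = fractions, noise_sd = noise_sd,
                 a0 = a0, a1 = a1, a2 = a2, a21 = a21, a3 = a3, a4 = a4, a5 = a5,
                 n_noise_normal = as.integer(n_noise_normal),
                 n_noise_binom = as.integer(n_noise_binom),
                 M = 6L + as.integer(n_noise_normal) + as.integer(n_noise_binom)),
            class = "synthetic_config")
}

.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# 1-D moments of the influential-feature laws used for exact conditional
# means under independence.  E[log(1+X5)] is a convergent Poisson sum,
# truncated far beyond machine precision.
.synth_moments <- function() {
  j <- 0:200
  list(E1 = 0.8, E2 = 0.08, Ee2 = (0.96 + 0.04 * exp(1))^2,
       E3sq = 27.5, Esin4 = 2 / pi,
       Elog5 = sum(log1p(j) * stats::dpois(j, 15)),
       E5 = 15, P6 = stats::pnorm(7, 0, 10, lower.tail = FALSE))
}

# E[f(X) | X_S = x_S] under the benchmark laws, vectorised over rows of a
# 6-column matrix.  Every term factors over independent features, so
# excluded features contribute their exact marginal moments.
.synth_cond_mean <- function(z, S, config) {
  m <- .synth_moments()
  has <- function(j) j %in% S
  x1 <- if (has(1)) z[, 1] else m$E1
  x2lin <- if (has(2)) z[, 2] else m$E2
  x2exp <- if (has(2)) exp(z[, 2]) else m$Ee2
  x3sq <- if (has(3)) z[, 3]^2 else m$E3sq
  s4 <- if (has(4)) sin(z[, 4]) else m$Esin4
  x5log <- if (has(5)) log1p(z[, 5]) else m$Elog5
  x5 <- if (has(5)) z[, 5] else m$E5
  i6 <- if (has(6)) as.numeric(z[, 6] > 7) else m$P6
  config$a0 + config$a1 * x1 + config$a2 * x2lin + config$a21 * x1 * x2exp +
    config$a3 * x3sq + config$a4 * s4 + config$a5 * x5log - x5 * i6
}

#' Noise-free benchmark signal
#'
#' @param x matrix with at least six columns (the influential features)
#' @param config a [synthetic_config()]
#' @return numeric vector of signal values
#' @export
synthetic_signal <- function(x, config = synthetic_config()) {
  .synth_cond_mean(as.matrix(x), 1:6, config)
}

.draw_real_features <- function(n) {
  cbind(x1 = stats::rbinom(n, 2, 0.4), x2 = stats::rbinom(n, 2, 0.04),
        x3 = stats::rgamma(n, shape = 10, rate = 2),
        x4 = stats::runif(n, 0, pi), x5 = stats::rpois(n, 15),
        x6 = stats::rnorm(n, 0, 10))
}

#' Generate the synthetic benchmark dataset
#'
#' Draws the six influential features and the noise features, forms the
#' response `f(x) + eps`, and assigns disjoint train/valid/test roles by a
#' random split.  Noise-feature parameters come from a substream derived
#' deterministically from `seed`, so they are drawn once per seed and
#' recorded in the `noise_params` attribute.  The returned data are
#' flagged test-independent: roles are fixed before any model sees them.
#'
#' @param config a [synthetic_config()]
#' @param seed integer seed
#' @return a [subsage_data()] with feature names `x1..xM`
#' @export
generate_synthetic <- function(config = synthetic_config(), seed = 1L) {
  n <- config$n
  nn <- config$n_noise_normal
  nb <- config$n_noise_binom
  pseed <- (as.numeric(seed) * 48271 + 11) %% 2147483647
  np <- .with_seed(pseed, list(mu = stats::runif(nn, -3, 3),
                               sigma = stats::runif(nn, 0.5, 3),
                               p = stats::runif(nb, 0.05, 0.5)))
  .with_seed(seed, {
    z <- .draw_real_features(n)
    noise_n <- vapply(seq_len(nn), function(j) stats::rnorm(n, np$mu[j], np$sigma[j]),
                      numeric(n))
    noise_b <- vapply(seq_len(nb), function(j) stats::rbinom(n, 2, np$p[j]),
                      numeric(n))
    x <- cbind(z, noise_n, noise_b)
    colnames(x) <- paste0("x", seq_len(ncol(x)))
    y <- synthetic_signal(z, config) + stats::rnorm(n, 0, config$noise_sd)
    idx <- sample.int(n)
    n_tr <- round(config$fractions[1] * n)
    n_va <- round(config$fractions[2] * n)
    role <- character(n)
    role[idx[seq_len(n_tr)]] <- "train"
    role[idx[n_tr + seq_len(n_va)]] <- "valid"
    role[idx[(n_tr + n_va + 1):n]] <- "test"
    out <- subsage_data(x, y, role, test_independent = TRUE)
    attr(out, "config") <- config
    attr(out, "noise_params") <- np
    attr(out, "seed") <- as.integer(seed)
    out
  })
}

#' Train the benchmark gradient-boosting model
#'
#' Fits an XGBoost regression ensemble on the training rows with
#' validation-based early stopping (depth 2, learning rate 0.05, row
#' subsampling 0.7, column subsampling 0.8, L2 penalty 1, squared-error
#' loss, patience 20 rounds) and converts the result to a
#' [tree_ensemble()] via the JSON dump.  The converted model reproduces
#' the booster's margin predictions up to float32 rounding.
#'
#' @param data a [subsage_data()] with train and valid roles
#' @param nrounds maximum boosting rounds (early stopping decides the
#'   actual count)
#' @param seed seed passed to the trainer
#' @param params named list overriding the default hyperparameters
#' @return a `tree_ensemble`
#' @export
train_demo_model <- function(data, nrounds = 1000L, seed = 1L, params = list()) {
  if (!requireNamespace("xgboost", quietly = TRUE))
    stop("the 'xgboost' package is required to train the benchmark model; ",
         "all other functionality works on ensembles built or read directly")
  stopifnot(inherits(data, "subsage_data"))
  p <- utils::modifyList(
    list(max_depth = 2, eta = 0.05, subsample = 0.7, colsample_bytree = 0.8,
         lambda = 1, gamma = 0, objective = "reg:squarederror",
         seed = as.integer(seed), nthread = 1),
    params)
  dtr <- xgboost::xgb.DMatrix(data_matrix(data, "train"),
                              label = data_response(data, "train"))
  dva <- xgboost::xgb.DMatrix(data_matrix(data, "valid"),
                              label = data_response(data, "valid"))
  booster <- xgboost::xgb.train(p, dtr, nrounds = as.integer(nrounds),
                                evals = list(valid = dva),
                                early_stopping_rounds = 20L, verbose = 0L)
  loss <- if (grepl("binary", p$objective)) "xent" else "squared"
  as_tree_ensemble(booster, loss = loss,
                   feature_names = colnames(data_matrix(data)))
}

#' True-model conditional expectation by Monte Carlo
#'
#' Estimates `E[f(X) | X_S = x_S]` for the noiseless benchmark signal by
#' sampling the excluded coordinates from their marginal laws (features
#' are independent by construction).  With all six influential features in
#' `S` the value is exact and the standard error zero.
#'
#' @param coalition integer vector of conditioned features
#' @param x instance values (a vector indexable by the coalition features)
#' @param config a [synthetic_config()]
#' @param mc Monte-Carlo sample size
#' @param seed integer seed
#' @return list with `value`, `se` and `mc`
#' @export
true_model_value <- function(coalition, x, config = synthetic_config(),
                             mc = 1e4, seed = 1L) {
  .with_seed(seed, {
    z <- .draw_real_features(mc)
    for (j in intersect(coalition, 1:6)) z[, j] <- x[j]
    v <- synthetic_signal(z, config)
    list(value = mean(v), se = stats::sd(v) / sqrt(mc), mc = mc)
  })
}

# Per-draw squared-error losses (Y - v_S)^2 for the coalitions needed,
# sharing one set of draws so differences are positively coupled.
.true_sq_loss <- function(z, y, S, config) (y - .synth_cond_mean(z, S, config))^2

#' True-model Sub-SAGE value by Monte Carlo
#'
#' Evaluates the Sub-SAGE definition with the model replaced by the true
#' benchmark signal and all expectations taken under the true feature and
#' noise laws.  The 94 noise features are null players, so their
#' singleton coalitions contribute the empty-set delta and their own
#' Sub-SAGE values are exactly zero; only coalitions intersected with the
#' six influential features need evaluating.  The additive response noise
#' inflates both loss terms of every delta equally and cancels in
#' expectation.  The weights use the full benchmark feature count `M`.
#'
#' @param k feature index
#' @param config a [synthetic_config()]
#' @param mc Monte-Carlo draws (at least 1e4)
#' @param seed integer seed
#' @return list with `value`, `se`, `mc`, `feature`
#' @export
true_subsage_mc <- function(k, config = synthetic_config(), mc = 1e5, seed = 1L) {
  if (mc < 1e4) stop("mc too small for a stable oracle; use at least 1e4")
  M <- config$M
  if (k > 6)
    return(list(value = 0, se = 0, mc = 0, feature = k))
  .with_seed(seed, {
    z <- .draw_real_features(mc)
    y <- synthetic_signal(z, config) + stats::rnorm(mc, 0, config$noise_sd)
    R <- setdiff(1:6, k)
    l_empty <- .true_sq_loss(z, y, integer(0), config)
    l_k <- .true_sq_loss(z, y, k, config)
    w_single <- 1 / (3 * (M - 1))
    g <- (1 / 3) * (l_empty - l_k) +
      w_single * (M - 6) * (l_empty - l_k)  # noise singletons = empty set
    for (m in R)
      g <- g + w_single * (.true_sq_loss(z, y, m, config) -
                             .true_sq_loss(z, y, sort(c(m, k)), config))
    g <- g + (1 / 3) * (.true_sq_loss(z, y, R, config) -
                          .true_sq_loss(z, y, 1:6, config))
    list(value = mean(g), se = stats::sd(g) / sqrt(mc), mc = mc, feature = k)
  })
}

#' True-model SAGE value by Monte Carlo
#'
#' Exact Shapley weighting over the six influential features (the noise
#' features are null players, so the full-game SAGE value coincides with
#' the six-player value), with every subset value estimated by Monte Carlo
#' from one shared set of draws.  Subset weighting is delegated to
#' [sage_bruteforce()].
#'
#' @inheritParams true_subsage_mc
#' @export
true_sage_mc <- function(k, config = synthetic_config(), mc = 1e5, seed = 1L) {
  if (mc < 1e4) stop("mc too small for a stable oracle; use at least 1e4")
  if (k > 6)
    return(list(value = 0, se = 0, mc = 0, feature = k))
  .with_seed(seed, {
    z <- .draw_real_features(mc)
    y <- synthetic_signal(z, config) + stats::rnorm(mc, 0, config$noise_sd)
    R <- setdiff(1:6, k)
    mean_empty <- mean(.true_sq_loss(z, y, integer(0), config))
    wbar <- new.env(parent = emptyenv())
    key <- function(S) paste0("s", paste(sort(S), collapse = ","))
    g <- numeric(mc)
    for (mask in 0:(2^5 - 1L)) {
      S <- R[bitwAnd(mask, 2L^(0:4)) > 0L]
      lS <- .true_sq_loss(z, y, S, config)
      lSk <- .true_sq_loss(z, y, sort(c(S, k)), config)
      assign(key(S), mean_empty - mean(lS), envir = wbar)
      assign(key(c(S, k)), mean_empty - mean(lSk), envir = wbar)
      s <- length(S)
      g <- g + exp(lgamma(s + 1) + lgamma(6 - s) - lgamma(7)) * (lS - lSk)
    }
    value <- sage_bruteforce(function(S) get(key(S), envir = wbar),
                             features = 1:6)[[as.character(k)]]
    list(value = value, se = stats::sd(g) / sqrt(mc), mc = mc, feature = k)
  })
}

#' True-model pointwise SHAP value by Monte Carlo
#'
#' Shapley value of feature `k` for the true signal at a single instance,
#' brute-forced over subsets of the six influential features with the
#' conditional expectations estimated from one shared set of marginal
#' draws (excluded coordinates resampled, conditioned coordinates fixed at
#' the instance).  Noise features receive exactly zero.
#'
#' @param x instance (vector with the influential features in positions
#'   1..6)
#' @inheritParams true_subsage_mc
#' @export
true_shap_point_mc <- function(x, k, config = synthetic_config(), mc = 1e5,
                               seed = 1L) {
  if (k > 6)
    return(list(value = 0, se = 0, mc = 0, feature = k))
  .with_seed(seed, {
    z <- .draw_real_features(mc)
    fval <- function(U) {
      zz <- z
      for (j in U) zz[, j] <- x[j]
      synthetic_signal(zz, config)
    }
    R <- setdiff(1:6, k)
    g <- numeric(mc)
    for (mask in 0:(2^5 - 1L)) {
      U <- R[bitwAnd(mask, 2L^(0:4)) > 0L]
      s <- length(U)
      g <- g + exp(lgamma(s + 1) + lgamma(6 - s) - lgamma(7)) *
        (fval(sort(c(U, k))) - fval(U))
    }
    list(value = mean(g), se = stats::sd(g) / sqrt(mc), mc = mc, feature = k)
  })
}

#' Simulate a small genotype-shaped dataset (synthetic)
#'
#' Generates a SNP-dosage-style classification problem: minor-allele
#' counts 0/1/2 with per-SNP allele frequencies, a logistic response
#' driven by a few causal SNPs, and train/valid/test roles assigned before
#' any model fitting.  Entirely synthetic; it exists so that the
#' classification (cross-entropy) code paths can be exercised on data with
#' the shape of real genotype matrices.
#'
#' @param n samples
#' @param n_snps SNP count
#' @param seed integer seed
#' @return a [subsage_data()] with 0/1 response and rs-style column names
#' @export
simulate_genotype_demo <- function(n = 600L, n_snps = 12L, seed = 1L) {
  .with_seed(seed, {
    maf <- stats::runif(n_snps, 0.08, 0.45)
    g <- vapply(maf, function(p) stats::rbinom(n, 2, p), numeric(n))
    colnames(g) <- sprintf("rs%06d", sample.int(999999, n_snps))
    beta <- numeric(n_snps)
    beta[1:3] <- c(0.8, -0.6, 0.5)
    eta <- -0.4 + as.vector(g %*% beta)
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    idx <- sample.int(n)
    n_tr <- round(0.5 * n); n_va <- round(0.3 * n)
    role <- character(n)
    role[idx[seq_len(n_tr)]] <- "train"
    role[idx[n_tr + seq_len(n_va)]] <- "valid"
    role[idx[(n_tr + n_va + 1):n]] <- "test"
    out <- subsage_data(g, y, role, test_independent = TRUE)
    attr(out, "causal") <- which(beta != 0)
    out
  })
}
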