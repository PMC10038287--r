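test_that("the coalition family has the closed-form weights", {
  fam <- coalition_family(4, 2)
  expect_length(fam$coalitions, 5)
  expect_equal(fam$coalitions, list(integer(0), 1L, 3L, 4L, c(1L, 3L, 4L)))
  expect_equal(fam$weights, c(1 / 3, 1 / 9, 1 / 9, 1 / 9, 1 / 3))
  expect_error(coalition_family(2, 1), "M must be >= 3")
})

test_that("weights sum to one and to a third per subset size for any M", {
  for (M in c(3, 5, 17, 100, 600)) {
    k <- sample.int(M, 1)
    fam <- coalition_family(M, k)
    expect_length(fam$coalitions, M + 1)
    expect_equal(sum(fam$weights), 1, tolerance = 1e-12)
    sizes <- lengths(fam$coalitions)
    for (s in unique(sizes))
      expect_equal(sum(fam$weights[sizes == s]), 1 / 3, tolerance = 1e-12)
  }
})

test_that("naive loss differences match hand computations", {
  # stump on k: leaves 0 / 2 with p_left 0.5, rows (low, y=0), (high, y=2):
  # mean[(y-1)^2] - mean[(y-v({k}))^2] = 1 - 0 = 1
  ens <- tree_ensemble(list(stump(1, 0, 0, 2)), n_features = 3)
  d <- subsage_data(cbind(c(-1, 1), 0, 0), c(0, 2), test_independent = TRUE)
  ens <- est_probs_q(ens, d)
  expect_equal(naive_delta_loss(ens, d, 1, integer(0)), 1)
  expect_equal(delta_loss_squared(ens, d, 1, integer(0)), 1)
  expect_error(naive_delta_loss(ens, d, 1, c(1, 2)), "element of S")

  # a feature used by no tree changes nothing, for any coalition
  for (S in list(integer(0), 1L, c(1L, 2L)))
    expect_equal(naive_delta_loss(ens, d, 3, S), 0)
})

test_that("decomposed and naive deltas agree for both losses on random ensembles", {
  for (seed in 1:4) {
    M <- 5
    ens <- rand_ensemble(8, M, seed = seed)
    d <- rand_dataset(60, M, seed = seed + 50)
    ens <- est_probs_q(ens, d)
    k <- (seed %% M) + 1L
    fam <- coalition_family(M, k)
    for (S in fam$coalitions[c(1, 2, M, M + 1)]) {
      expect_equal(delta_loss_squared(ens, d, k, S),
                   naive_delta_loss(ens, d, k, S, loss = "squared"),
                   tolerance = 1e-10)
    }
    db <- rand_dataset(60, M, seed = seed + 90, binary = TRUE)
    ensb <- est_probs_q(
      tree_ensemble(ens$trees, M, offset = 0.2, loss = "xent"), db)
    for (S in fam$coalitions[c(1, 3, M + 1)]) {
      expect_equal(delta_loss_xent(ensb, db, k, S),
                   naive_delta_loss(ensb, db, k, S, loss = "xent"),
                   tolerance = 1e-10)
    }
  }
})

test_that("cross-entropy deltas vanish in degenerate cases and stay finite at large margins", {
  M <- 3
  # constant-margin model: a single leaf-only structure via equal leaves
  ens <- tree_ensemble(list(stump(1, 0, 0.7, 0.7)), M, loss = "xent")
  d <- rand_dataset(40, M, seed = 3, binary = TRUE)
  ens <- est_probs_q(ens, d)
  expect_equal(naive_delta_loss(ens, d, 1, integer(0)), 0)
  expect_equal(delta_loss_xent(ens, d, 2, 3L), 0)

  # margins around +-50 remain finite through the log1p/exp branches
  big <- tree_ensemble(list(stump(1, 0, -25, 25)), M, offset = 25, loss = "xent")
  big <- est_probs_q(big, d)
  v <- delta_loss_xent(big, d, 1, integer(0))
  expect_true(is.finite(v))
  expect_equal(v, naive_delta_loss(big, d, 1, integer(0)), tolerance = 1e-10)

  # y = 1 everywhere with identical margins on both sides
  d1 <- subsage_data(data_matrix(d), rep(1, 40), test_independent = TRUE)
  expect_equal(delta_loss_xent(ens, d1, 1, 2L), 0)
})

test_that("the estimate is the weighted sum of its stored deltas", {
  M <- 6
  ens <- rand_ensemble(10, M, seed = 21)
  d <- rand_dataset(90, M, seed = 22)
  ens <- est_probs_q(ens, d)
  est <- subsage_estimate(ens, d, 2)
  expect_equal(sum(est$deltas$weight * est$deltas$delta), est$estimate,
               tolerance = 1e-12)
  expect_equal(nrow(est$deltas), M + 1)
  expect_equal(est$n_test, 90)
})

test_that("a feature absent from every tree has Sub-SAGE exactly zero", {
  ens <- tree_ensemble(list(stump(1, 0, -1, 1), stump(2, 0.5, 0, 1)),
                       n_features = 5)
  d <- rand_dataset(50, 5, seed = 31)
  ens <- est_probs_q(ens, d)
  expect_identical(subsage_estimate(ens, d, 4)$estimate, 0)
  expect_identical(subsage_estimate(ens, d, 5)$estimate, 0)
})

test_that("exchangeable features receive equal estimates", {
  set.seed(77)
  x <- matrix(rnorm(80 * 2), 80, 2)
  x <- cbind(x, x[, 1])  # feature 3 duplicates feature 1
  y <- x[, 1] + rnorm(80, sd = 0.5)
  d <- subsage_data(x, y, test_independent = TRUE)
  ens <- tree_ensemble(list(stump(1, 0.2, -1, 1), stump(3, 0.2, -1, 1)),
                       n_features = 3)
  ens <- est_probs_q(ens, d)
  e1 <- subsage_estimate(ens, d, 1)
  e3 <- subsage_estimate(ens, d, 3)
  expect_equal(e1$estimate, e3$estimate, tolerance = 1e-12)
})

test_that("estimates are refused on data not flagged as held out", {
  ens <- rand_ensemble(4, 4, seed = 41)
  d <- rand_dataset(30, 4, seed = 42)
  ens <- est_probs_q(ens, d)
  d_unflagged <- mark_test_independent(d, FALSE)
  expect_error(subsage_estimate(ens, d_unflagged, 1), "not flagged")
  expect_error(paired_bootstrap(ens, d_unflagged, 1, B = 100), "not flagged")
})

test_that("brute-force SAGE matches a permutation-average oracle", {
  # 3-feature toy game with a tabulated, non-additive value function
  tab <- c(s = 0, s1 = 1, s2 = 0.5, s3 = -0.2, s12 = 2.5, s13 = 0.9,
           s23 = 0.4, s123 = 3.4)
  vf <- function(S) tab[[paste0("s", paste(sort(S), collapse = ""))]]
  got <- sage_bruteforce(vf, 1:3)
  want <- perm_shapley(vf, 1:3)
  expect_equal(got, want, tolerance = 1e-12)
  # efficiency of the full Shapley decomposition
  expect_equal(sum(got), vf(1:3) - vf(integer(0)), tolerance = 1e-12)

  # additive game: each feature recovers its own marginal delta
  a <- c(0.3, -1, 2)
  vf_add <- function(S) sum(a[S])
  expect_equal(unname(sage_bruteforce(vf_add, 1:3)), a, tolerance = 1e-12)

  # constant value function: all zeros; dummies padded with zero
  z <- sage_bruteforce(function(S) 7, 1:3, n_features = 5)
  expect_equal(unname(z), rep(0, 5))
  expect_error(sage_bruteforce(function(S) 0, 1:16), "15")
})

test_that("the linear-regression closed form matches direct loss differences", {
  expect_equal(linear_subsage_closed_form(
    structure(list(beta = c(x1 = 0), cov_xy = c(x1 = 5), var_x = c(x1 = 2)),
              class = "linear_fit_summary"), "x1"), 0)
  expect_equal(linear_subsage_closed_form(
    structure(list(beta = c(x1 = 1), cov_xy = c(x1 = 1), var_x = c(x1 = 1)),
              class = "linear_fit_summary"), "x1"), 1)

  set.seed(11)
  M <- 5
  beta_true <- c(1, -0.5, 0.25, 0, 0.8)
  ntr <- 400; nte <- 20000
  xtr <- matrix(rnorm(ntr * M), ntr, M, dimnames = list(NULL, paste0("x", 1:M)))
  ytr <- drop(xtr %*% beta_true) + rnorm(ntr)
  fit <- lm(ytr ~ ., data = as.data.frame(xtr))
  xte <- matrix(rnorm(nte * M), nte, M, dimnames = list(NULL, paste0("x", 1:M)))
  yte <- drop(xte %*% beta_true) + rnorm(nte)
  sm <- linear_fit_summary(fit, xte, yte)

  bhat <- coef(fit)
  mu <- colMeans(xte)
  pred_S <- function(S) {
    xx <- xte
    for (j in setdiff(1:M, S)) xx[, j] <- mu[j]
    drop(bhat[1] + xx %*% bhat[-1])
  }
  for (k in c(1, 4)) {
    deltas <- vapply(coalition_family(M, k)$coalitions, function(S) {
      mean((yte - pred_S(S))^2) - mean((yte - pred_S(sort(c(S, k))))^2)
    }, 0.0)
    # every coalition gives (nearly) the same delta ...
    expect_lt(max(deltas) - min(deltas), 0.02)
    # ... equal to the closed form, within Monte-Carlo error
    expect_equal(mean(deltas), linear_subsage_closed_form(sm, k),
                 tolerance = 0.02)
  }
})

test_that("a pure-noise linear fit has non-positive mean importance on fresh data", {
  # the variance-penalty term of the closed form drives null features negative
  set.seed(123)
  vals <- replicate(50, {
    M <- 4; ntr <- 60; nte <- 300
    xtr <- matrix(rnorm(ntr * M), ntr, M, dimnames = list(NULL, paste0("x", 1:M)))
    ytr <- rnorm(ntr)  # no signal at all
    fit <- lm(ytr ~ ., data = as.data.frame(xtr))
    xte <- matrix(rnorm(nte * M), nte, M, dimnames = list(NULL, paste0("x", 1:M)))
    yte <- rnorm(nte)
    sm <- linear_fit_summary(fit, xte, yte)
    mean(vapply(1:M, function(k) linear_subsage_closed_form(sm, k), 0.0))
  })
  expect_lt(mean(vals), 0)
})
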