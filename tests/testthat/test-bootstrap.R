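make_result <- function(replicates, estimate, alpha = 0.025) {
  structure(list(feature = 1L, estimate = estimate, replicates = replicates,
                 B = length(replicates), alpha = alpha,
                 percentile = percentile_interval(replicates, alpha),
                 bca = NULL, seed = 1L, loss = "squared",
                 n_test = 10L),
            class = "bootstrap_result")
}

test_that("percentile endpoints are the prescribed order statistics", {
  expect_equal(unname(percentile_interval(1:1000, 0.025)), c(25, 975))
  expect_equal(unname(percentile_interval(rep(3.5, 50), 0.1)), c(3.5, 3.5))
  # alpha just below one half pins both endpoints to the median region
  iv <- percentile_interval(1:1000, 0.4999)
  expect_true(all(iv >= 499 & iv <= 501))
  expect_error(percentile_interval(1:10, 0.6), "alpha")
  expect_error(percentile_interval(numeric(0), 0.1), "empty")
})

test_that("bootstrapping a feature the model ignores yields a degenerate interval", {
  ens <- tree_ensemble(list(stump(1, 0, -1, 1)), n_features = 4)
  d <- rand_dataset(40, 4, seed = 1)
  ens <- est_probs_q(ens, d)
  r <- paired_bootstrap(ens, d, 3, B = 100, seed = 5)
  expect_true(all(r$replicates == 0))
  expect_equal(unname(r$percentile), c(0, 0))
})

test_that("replicates are reproducible and form counter-derived substreams", {
  ens <- rand_ensemble(6, 4, seed = 2)
  d <- rand_dataset(50, 4, seed = 3)
  ens <- est_probs_q(ens, d)
  r1 <- paired_bootstrap(ens, d, 1, B = 120, seed = 99)
  r2 <- paired_bootstrap(ens, d, 1, B = 120, seed = 99)
  expect_identical(r1$replicates, r2$replicates)
  r3 <- paired_bootstrap(ens, d, 1, B = 120, seed = 100)
  expect_false(identical(r1$replicates, r3$replicates))
  # replicate b depends only on (seed, b), not on how many others ran
  r4 <- paired_bootstrap(ens, d, 1, B = 100, seed = 99)
  expect_identical(r1$replicates[1:100], r4$replicates)
})

test_that("an identity resample reproduces the point estimate", {
  ens <- rand_ensemble(6, 5, seed = 8)
  d <- rand_dataset(60, 5, seed = 9)
  ens <- est_probs_q(ens, d)
  est <- subsage_estimate(ens, d, 2)
  x <- data_matrix(d, "test")
  psi <- subsage:::.psi_on_rows(ens, x, data_response(d, "test"),
                                seq_len(nrow(x)), 2L, "squared")[[1]]$psi
  expect_equal(psi, est$estimate, tolerance = 1e-12)
})

test_that("widening alpha shrinks the percentile interval", {
  set.seed(4)
  reps <- rnorm(500)
  narrow <- percentile_interval(reps, 0.25)
  wide <- percentile_interval(reps, 0.025)
  expect_gte(narrow["lower"], wide["lower"])
  expect_lte(narrow["upper"], wide["upper"])
})

test_that("parameter validation guards the bootstrap", {
  ens <- rand_ensemble(3, 4, seed = 11)
  d <- rand_dataset(30, 4, seed = 12)
  ens <- est_probs_q(ens, d)
  expect_error(paired_bootstrap(ens, d, 1, B = 50), "at least 100")
  expect_error(paired_bootstrap(ens, d, 1, B = 100, alpha = 0.7), "alpha")
})

test_that("BCa reduces to the percentile interval for symmetric replicates", {
  reps <- c(seq(-1, 1, length.out = 500), -seq(-1, 1, length.out = 500))
  r <- make_result(reps, estimate = 0)
  b <- bca_interval(r, acceleration = "zero")
  expect_equal(b$z0, 0, tolerance = 1e-12)
  expect_equal(b$a, 0)
  expect_equal(c(b$lower, b$upper), unname(r$percentile))
})

test_that("the bias constant is the normal quantile of the below fraction", {
  reps <- c(rep(-1, 60), rep(1, 40))  # 60% strictly below an estimate of 0
  r <- make_result(reps, estimate = 0)
  b <- bca_interval(r, acceleration = "zero")
  expect_equal(b$z0, qnorm(0.6), tolerance = 1e-12)
})

test_that("one-sided replicates make the BCa correction undefined", {
  r <- make_result(abs(rnorm(200)) + 1, estimate = 0.5)
  expect_error(bca_interval(r, "zero"), "one side")
})

test_that("jackknife acceleration is finite and close to zero for a stable stump", {
  ens <- tree_ensemble(list(stump(1, 0, -1, 1), stump(2, 0, 0, 0.5)),
                       n_features = 4)
  d <- rand_dataset(80, 4, seed = 13)
  ens <- est_probs_q(ens, d)
  r <- paired_bootstrap(ens, d, 1, B = 200, seed = 21)
  b <- bca_interval(r, "jackknife", ensemble = ens, data = d)
  expect_true(is.finite(b$a))
  expect_lt(abs(b$a), 0.5)
  expect_lte(b$lower, b$upper)
})

test_that("the one-sided importance decision follows the lower bound", {
  r_pos <- make_result(runif(200, 0.5, 1), estimate = 0.7)
  t_pos <- one_sided_importance_test(r_pos, 0.05)
  expect_true(t_pos$reject)
  expect_gt(t_pos$lower_bound, 0)

  set.seed(6)
  sym <- rnorm(400)
  r_sym <- make_result(sym, estimate = mean(sym))
  expect_false(one_sided_importance_test(r_sym, 0.05)$reject)
})
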