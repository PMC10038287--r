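test_that("a single-stump dump is parsed and routes instances by its split", {
  dump <- '[{"nodeid":0,"split":"f0","split_condition":0.5,"yes":1,"no":2,"missing":1,
             "children":[{"nodeid":1,"leaf":-1},{"nodeid":2,"leaf":1}]}]'
  ens <- read_xgboost_dump(dump, n_features = 1)
  expect_s3_class(ens, "tree_ensemble")
  expect_equal(predict(ens, matrix(c(0, 1), 2, 1)), c(-1, 1))
})

test_that("malformed dumps are rejected with clear errors", {
  expect_error(read_xgboost_dump('[{"nodeid":0,'), "malformed JSON")
  # child id referenced by yes/no but absent from children
  bad_child <- '[{"nodeid":0,"split":"f0","split_condition":0,"yes":1,"no":9,
                  "children":[{"nodeid":1,"leaf":0},{"nodeid":2,"leaf":1}]}]'
  expect_error(read_xgboost_dump(bad_child, n_features = 1), "child ids")
  non_binary <- '[{"nodeid":0,"split":"f0","split_condition":0,"yes":1,"no":2,
                   "children":[{"nodeid":1,"leaf":0}]}]'
  expect_error(read_xgboost_dump(non_binary, n_features = 1), "not binary")
})

test_that("a dumped booster round-trips to matching margins", {
  skip_if_not_installed("xgboost")
  set.seed(7)
  n <- 50; M <- 4
  # pass the data through float32 so that R-side double comparisons agree
  # with the booster's single-precision threshold comparisons
  f32 <- function(v) readBin(writeBin(v, raw(), size = 4L), "numeric",
                             size = 4L, n = length(v))
  x <- matrix(f32(rnorm(n * M)), n, M, dimnames = list(NULL, paste0("x", 1:M)))
  y <- x[, 1] - 0.5 * x[, 2] + rnorm(n, sd = 0.3)
  booster <- xgboost::xgb.train(
    list(max_depth = 2, eta = 0.3, objective = "reg:squarederror", nthread = 1),
    xgboost::xgb.DMatrix(x, label = y), nrounds = 15, verbose = 0)
  ens <- as_tree_ensemble(booster)
  # the booster accumulates in float32; the parsed leaf values are the exact
  # float32 parameters, so agreement is to single-precision rounding
  expect_lt(max(abs(predict(ens, x) -
                      predict(booster, x, outputmargin = TRUE))), 1e-5)
})

test_that("traversal probabilities are same-feature interval fractions", {
  # stump at 0 with values {-2,-1,1,3}: half the mass is below
  ens <- tree_ensemble(list(stump(1, 0, -1, 1)), n_features = 1)
  ens <- estimate_node_probabilities(ens, matrix(c(-2, -1, 1, 3), 4, 1))
  expect_equal(ens$trees[[1]]$nodes$p_left[1], 0.5)

  # split at 5 beneath an ancestor that sent the path to x > 3:
  # p_left = #{x in (3,5]} / #{x in (3,Inf)} = 1/3
  nested <- regression_tree(data.frame(
    id = 0:4, feature = c(1, NA, 1, NA, NA), threshold = c(3, NA, 5, NA, NA),
    yes = c(1L, NA, 3L, NA, NA), no = c(2L, NA, 4L, NA, NA),
    value = c(0, 10, 0, 20, 30)))
  ens2 <- estimate_node_probabilities(tree_ensemble(list(nested), 1),
                                      matrix(c(1, 4, 6, 8), 4, 1))
  expect_equal(ens2$trees[[1]]$nodes$p_left[3], 1 / 3)

  # all data below an unconstrained threshold: degenerate but well-defined
  ens3 <- estimate_node_probabilities(tree_ensemble(list(stump(1, 10, 0, 1)), 1),
                                      matrix(1:4, 4, 1))
  expect_equal(ens3$trees[[1]]$nodes$p_left[1], 1)
  expect_equal(ens3$trees[[1]]$nodes$p_right[1], 0)
})

test_that("sibling probabilities sum to one on random ensembles", {
  for (seed in 1:3) {
    ens <- rand_ensemble(8, 5, seed = seed)
    d <- rand_dataset(60, 5, seed = seed + 100)
    ens <- est_probs_q(ens, d)
    for (tr in ens$trees) {
      internal <- !is.na(tr$nodes$feature)
      expect_true(all(abs(tr$nodes$p_left[internal] +
                            tr$nodes$p_right[internal] - 1) < 1e-12))
      expect_true(all(tr$nodes$p_left[internal] >= 0 &
                        tr$nodes$p_left[internal] <= 1))
    }
  }
})

test_that("the root split probability is the empirical cdf at the threshold", {
  set.seed(42)
  x <- matrix(rnorm(500), 500, 1)
  thr <- 0.31
  ens <- estimate_node_probabilities(tree_ensemble(list(stump(1, thr, -1, 1)), 1), x)
  # independent sort-and-count oracle
  expect_equal(ens$trees[[1]]$nodes$p_left[1], sum(sort(x[, 1]) < thr) / 500)
})

test_that("conditional expectations follow the recursive algorithm", {
  # depth-2 tree: root on feature 2 at 5, left child splits feature 1 at 20;
  # with x2 = 3 known and x1 unknown the value is p*v_left + (1-p)*v_right
  tr <- regression_tree(data.frame(
    id = 0:4, feature = c(2, 1, NA, NA, NA), threshold = c(5, 20, NA, NA, NA),
    yes = c(1L, 3L, NA, NA, NA), no = c(2L, 4L, NA, NA, NA),
    value = c(0, 0, 7, 2, 4)))
  set.seed(1)
  xdat <- cbind(runif(100, 0, 40), runif(100, 0, 10))
  ens <- estimate_node_probabilities(tree_ensemble(list(tr), 2), xdat)
  nd <- ens$trees[[1]]$nodes
  p <- nd$p_left[2]
  expect_equal(cond_exp_tree(ens$trees[[1]], 2, c(NA, 3)), p * 2 + (1 - p) * 4)

  # stump with hand-set probabilities and the empty coalition: 0.4*(-1)+0.6*1
  st <- stump(1, 0, -1, 1)
  st$nodes$p_left <- c(0.4, NA, NA)
  st$nodes$p_right <- c(0.6, NA, NA)
  expect_equal(cond_exp_tree(st, integer(0), numeric(0)), 0.2)

  # full coalition reproduces the exact prediction on random instances
  M <- 5
  ens2 <- rand_ensemble(6, M, seed = 9)
  d <- rand_dataset(80, M, seed = 10)
  ens2 <- est_probs_q(ens2, d)
  x <- data_matrix(d)[1:100 %% 80 + 1, , drop = FALSE]
  pred <- predict(ens2, x)
  for (i in seq_len(nrow(x)))
    expect_equal(ensemble_value(ens2, 1:M, x[i, ]), pred[i], tolerance = 1e-12)
})

test_that("ensemble_value is offset plus per-tree terms", {
  st <- stump(1, 0, -1, 1)
  st$nodes$p_left <- c(0.4, NA, NA)
  st$nodes$p_right <- c(0.6, NA, NA)
  ens <- tree_ensemble(list(st, st), n_features = 3, offset = 0.5)
  expect_equal(ensemble_value(ens, integer(0), numeric(0)), 0.5 + 2 * 0.2)
  # zero trees: the offset for every coalition
  empty <- tree_ensemble(list(), n_features = 3, offset = 1.25)
  expect_equal(ensemble_value(empty, integer(0), numeric(0)), 1.25)
  expect_equal(ensemble_value(empty, c(1, 3), c(9, 9, 9)), 1.25)
})

test_that("stump ensembles average to the empirical margin mean under no coalition", {
  set.seed(5)
  M <- 4
  trees <- replicate(6, stump(sample.int(M, 1), rnorm(1), rnorm(1), rnorm(1)),
                     simplify = FALSE)
  ens <- tree_ensemble(trees, n_features = M, offset = 0.3)
  d <- rand_dataset(120, M, seed = 6)
  ens <- estimate_node_probabilities(ens, d)
  v0 <- ensemble_value(ens, integer(0), numeric(0))
  expect_equal(v0, mean(predict(ens, data_matrix(d))), tolerance = 1e-9)
})

test_that("trees_using_feature enumerates the tau_k partition", {
  ens <- tree_ensemble(list(stump(1, 0, 0, 1), stump(3, 0, 0, 1),
                            stump(1, 1, 0, 1)),
                       n_features = 4)
  expect_equal(trees_using_feature(ens, 3), 2L)
  expect_equal(trees_using_feature(ens, 1), c(1L, 3L))
  expect_length(trees_using_feature(ens, 4), 0)
  expect_error(trees_using_feature(ens, 5), "out of range")
})

test_that("invalid tree structures and data are rejected", {
  # unresolvable child
  expect_error(regression_tree(data.frame(
    id = 0:2, feature = c(1, NA, NA), threshold = c(0, NA, NA),
    yes = c(1L, NA, NA), no = c(5L, NA, NA), value = c(0, -1, 1))),
    "unresolvable")
  # leaf/internal count mismatch (a node referenced twice)
  expect_error(regression_tree(data.frame(
    id = 0:1, feature = c(1, NA), threshold = c(0, NA),
    yes = c(1L, NA), no = c(1L, NA), value = c(0, 1))), "child more than once")
  expect_error(subsage_data(matrix(c(1, NA), 2, 1), c(1, 2)), "missing values")
  expect_error(subsage_data(matrix(1:4, 2, 2), c(1, 2), role = c("test", "potato")),
               "unknown role")
})
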