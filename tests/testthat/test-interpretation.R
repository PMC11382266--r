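test_that("stump-forest contributions match direct in-bag enumeration", {
  tbl <- separable_table(40, seed = 3)
  f <- train_forest(tbl, num_trees = 3, seed = 3, max.depth = 1)
  pr <- decompose(f, tbl)
  # hand enumeration: for a stump, contribution(split feature) must equal
  # leaf probability minus root probability, from raw in-bag counts
  rf <- f$rf
  tn <- predict(rf, tbl[c("f1", "f2")], type = "terminalNodes",
                num.threads = 1)$predictions
  y <- tbl$class
  exp_contrib <- matrix(0, nrow(tbl), 2,
                        dimnames = list(NULL, c("f1", "f2")))
  exp_bias <- 0
  for (t in 1:3) {
    ib <- rf$inbag.counts[[t]]
    leaf <- tn[, t]
    p_leaf <- vapply(sort(unique(leaf)), function(L) {
      sum(ib[leaf == L & y == "cytosol"]) / sum(ib[leaf == L])
    }, numeric(1))
    names(p_leaf) <- sort(unique(leaf))
    p_root <- sum(ib[y == "cytosol"]) / sum(ib)
    ti <- ranger::treeInfo(rf, t)
    sv <- ti$splitvarName[1]
    exp_bias <- exp_bias + p_root / 3
    exp_contrib[, sv] <- exp_contrib[, sv] +
      (p_leaf[as.character(leaf)] - p_root) / 3
  }
  expect_equal(pr$bias, exp_bias, tolerance = 1e-12)
  expect_equal(unname(pr$contributions), unname(exp_contrib),
               tolerance = 1e-12)
})

test_that("bias plus contributions reconstruct the forest probability", {
  tbl <- make_planted_table(n_per_class = 100, seed = 14)
  for (ntree in c(1, 10, 200)) {
    f <- train_forest(balanced_split(tbl, 0.7, 1)$train,
                      num_trees = ntree, seed = 14)
    pr <- decompose(f, tbl)
    p_cyto <- 1 - predict(f, tbl, type = "prob")
    expect_lt(max(abs(pr$bias + rowSums(pr$contributions) - p_cyto)), 1e-9)
    expect_equal(pr$prediction, unname(p_cyto), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("contributions toward the two classes are exact negatives", {
  tbl <- make_planted_table(n_per_class = 60, n_noise_features = 2,
                            seed = 9)
  train <- balanced_split(tbl, 0.7, 2)$train
  f_sec <- train_forest(train, num_trees = 50, seed = 9)
  f_cyt <- train_forest(train, num_trees = 50, seed = 9,
                        positive = "cytosol")
  pr1 <- decompose(f_sec, tbl)   # toward cytosol
  pr2 <- decompose(f_cyt, tbl)   # toward secreted
  expect_equal(pr1$contributions, -pr2$contributions, tolerance = 1e-12)
  expect_equal(pr1$bias + pr2$bias, 1, tolerance = 1e-12)
})

test_that("threshold extraction finds a planted sign flip exactly", {
  values <- c(seq(7.0, 8.9, by = 0.1), seq(9.1, 11.0, by = 0.1))
  contrib <- ifelse(values < 9, -0.2, 0.2)   # negative = secreted side
  th <- extract_threshold(values, contrib)
  expect_equal(th$boundary, 9.0)
  expect_equal(th$separation, 1.0)
  expect_equal(th$secreted_side, "<")
  # flipped orientation
  th2 <- extract_threshold(values, -contrib)
  expect_equal(th2$boundary, 9.0)
  expect_equal(th2$secreted_side, ">")
})

test_that("non-discriminative profiles warn instead of inventing bounds", {
  expect_warning(th <- extract_threshold(runif(50), rep(0.1, 50)),
                 "no boundary")
  expect_true(is.na(th$boundary))
  expect_error(extract_threshold(1:5, c(1, -1, 1, -1, 1)), "at least 10")
})

test_that("planted boundaries are recovered with correct directions", {
  for (seed in c(2, 23, 47)) {
    tbl <- make_planted_table(n_per_class = 400, seed = seed)
    fit <- surf_rf(tbl, n_iterations = 4, num_trees = 150, seed = seed)
    rep3 <- threshold_report(fit, tbl, top_n = 3)
    rep3 <- rep3[order(rep3$feature), ]
    expect_equal(rep3$feature, c("f1", "f2", "f3"))
    expect_equal(rep3$secreted_side, c("<", ">", ">"))
    expect_lt(max(abs(rep3$boundary - c(9.0, 1.8, 5.8))), 0.5)
    expect_true(all(rep3$separation > 0.9))
  }
})

test_that("contribution signs transition monotonically across the rule", {
  tbl <- make_planted_table(
    n_per_class = 200,
    rules = list(list(feature = "f1", op = "<", boundary = 9)),
    noise_rate = 0.05, n_noise_features = 3, seed = 18)
  f <- train_forest(balanced_split(tbl, 0.7, 3)$train, num_trees = 200,
                    seed = 18)
  pr <- decompose(f, tbl)
  below <- tbl$f1 < 9
  contrib <- pr$contributions[, "f1"]
  # secreted (f1 < 9) rows push toward secreted: negative cytosol-side sign
  expect_gt(mean(contrib[below] < 0), 0.9)
  expect_gt(mean(contrib[!below] > 0), 0.9)
})

test_that("decomposition demands the training schema", {
  tbl <- make_planted_table(n_per_class = 40, seed = 4)
  f <- train_forest(balanced_split(tbl, 0.7, 1)$train, num_trees = 20,
                    seed = 4)
  expect_error(decompose(f, tbl[c("f1", "f2")]), "feature-name")
})
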