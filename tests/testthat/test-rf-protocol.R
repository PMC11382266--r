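make_label_table <- function(n_a, n_b) {
  set.seed(99)
  data.frame(f1 = rnorm(n_a + n_b), f2 = rnorm(n_a + n_b),
             class = factor(rep(c("cytosol", "secreted"), c(n_a, n_b))))
}

test_that("balanced splits reproduce the published split arithmetic", {
  # 708 rows split 70/30 -> 496 training (248 per class), 212 test
  tbl <- make_label_table(354, 354)
  sp <- balanced_split(tbl, 0.7, seed = 1)
  expect_equal(nrow(sp$train), 496L)
  expect_equal(unname(table(sp$train$class)), c(248L, 248L),
               ignore_attr = TRUE)
  expect_equal(nrow(sp$test), 212L)
  expect_length(intersect(attr(sp, "train_idx"), attr(sp, "test_idx")), 0)

  sp2 <- balanced_split(make_label_table(10, 10), 0.5, seed = 2)
  expect_equal(unname(table(sp2$train$class)), c(5L, 5L),
               ignore_attr = TRUE)
  expect_equal(nrow(sp2$test), 10L)

  expect_error(balanced_split(make_label_table(300, 100), 0.7, seed = 3),
               "insufficient class")
})

test_that("splits are a pure function of table and seed", {
  tbl <- make_label_table(50, 50)
  a <- balanced_split(tbl, 0.7, seed = 7)
  b <- balanced_split(tbl, 0.7, seed = 7)
  c <- balanced_split(tbl, 0.7, seed = 8)
  expect_identical(attr(a, "train_idx"), attr(b, "train_idx"))
  expect_false(identical(attr(a, "train_idx"), attr(c, "train_idx")))
})

test_that("forests fit separable data perfectly and deterministically", {
  tbl <- separable_table(40)
  f <- train_forest(tbl, num_trees = 100, seed = 5)
  expect_equal(mean(predict(f, tbl, type = "class") == tbl$class), 1)
  f2 <- train_forest(tbl, num_trees = 100, seed = 5)
  expect_identical(predict(f, tbl, type = "prob"),
                   predict(f2, tbl, type = "prob"))

  one <- tbl[tbl$class == "cytosol", ]
  expect_error(train_forest(one), "degenerate training")
})

test_that("a planted-rule table is learned above 90% held-out accuracy", {
  tbl <- make_planted_table(n_per_class = 200, seed = 21)
  sp <- balanced_split(tbl, 0.7, seed = 4)
  f <- train_forest(sp$train, num_trees = 200, seed = 4)
  m <- evaluate_forest(f, sp$test)
  expect_gt(m$accuracy, 0.90)
  expect_equal(sum(m$confusion), nrow(sp$test))
})

test_that("metrics reproduce the published precision/recall arithmetic", {
  # 2 * .939 * .930 / (.939 + .930) = 0.93448: agrees with the printed
  # 0.935 to one unit in the last printed digit
  expect_lt(abs(f1_score(0.939, 0.930) - 0.935), 1e-3)
  expect_equal(round(f1_score(0.906, 0.906), 3), 0.906)
  expect_equal(f1_score(0, 0), 0)
})

test_that("perfect predictions give unit metrics and AUC matches pROC", {
  tbl <- separable_table(60)
  sp <- balanced_split(tbl, 0.5, seed = 9)
  f <- train_forest(sp$train, num_trees = 150, seed = 9)
  m <- evaluate_forest(f, sp$test)
  if (m$accuracy == 1) {
    expect_equal(m$precision, 1)
    expect_equal(m$recall, 1)
    expect_equal(m$f1, 1)
    expect_equal(m$auc, 1)
  }
  # independent AUC cross-check on a noisy problem
  tbl2 <- make_planted_table(n_per_class = 100, noise_rate = 0.15, seed = 2)
  sp2 <- balanced_split(tbl2, 0.7, seed = 2)
  f2 <- train_forest(sp2$train, num_trees = 100, seed = 2)
  m2 <- evaluate_forest(f2, sp2$test)
  p <- predict(f2, sp2$test, type = "prob")
  ref <- pROC::auc(pROC::roc(response = sp2$test$class == "secreted",
                             predictor = p, quiet = TRUE))
  expect_equal(m2$auc, as.numeric(ref), tolerance = 1e-9)
})

test_that("evaluation rejects schema-mismatched test data", {
  tbl <- separable_table(40)
  f <- train_forest(tbl, num_trees = 20, seed = 1)
  bad <- tbl[c("f1", "class")]
  expect_error(predict(f, bad), "feature-name")
})

test_that("the protocol records runs, seeds and a best model", {
  tbl <- make_planted_table(n_per_class = 80, n_noise_features = 3, seed = 6)
  fit <- surf_rf(tbl, n_iterations = 6, num_trees = 100, seed = 13)
  expect_equal(nrow(fit$runs), 6L)
  expect_false(anyNA(fit$runs$seed))
  expect_equal(fit$best$metrics$accuracy, max(fit$runs$accuracy))
  # importances sum to one per run and after averaging
  expect_equal(unname(rowSums(fit$importances)), rep(1, 6),
               tolerance = 1e-9)
  expect_equal(sum(fit$avg_importance), 1, tolerance = 1e-9)
  # f1 internal consistency on every run
  with_f1 <- mapply(f1_score, fit$runs$precision, fit$runs$recall)
  expect_equal(round(fit$runs$f1, 3), round(with_f1, 3))
  # single-iteration degenerate case
  fit1 <- surf_rf(tbl, n_iterations = 1, num_trees = 50, seed = 2)
  expect_equal(fit1$best$iteration, 1L)
  expect_equal(fit1$spec$top_k, 1L)

  expect_output(print(fit), "balanced repeated-split")
  expect_s3_class(summary(fit), "summary.surf_rf")
  expect_equal(coef(fit), fit$avg_importance)
})

test_that("protocol accuracy is stable across repeated splits", {
  tbl <- make_planted_table(n_per_class = 400, seed = 31)
  fit <- surf_rf(tbl, n_iterations = 10, num_trees = 100, seed = 17)
  expect_lt(abs(mean(fit$runs$accuracy) - fit$runs$accuracy[1]), 0.02)
  expect_lt(sd(fit$runs$accuracy), 0.02)
})

test_that("the planted feature dominates averaged importance across seeds", {
  hits <- vapply(1:10, function(seed) {
    tbl <- make_planted_table(n_per_class = 100,
                              rules = list(list(feature = "f1", op = "<",
                                                boundary = 9)),
                              n_noise_features = 4, seed = seed)
    fit <- surf_rf(tbl, n_iterations = 3, num_trees = 100, seed = seed)
    names(which.max(fit$avg_importance)) == "f1"
  }, logical(1))
  expect_true(all(hits))
})

test_that("importance pruning is strict below the floor with a 2-guard", {
  fit <- list(avg_importance = c(f1 = 0.60, f2 = 0.38, f3 = 0.02,
                                 f4 = 0.00))
  class(fit) <- "surf_rf"
  keep <- prune_by_importance(fit, floor = 0.02)
  expect_setequal(as.character(keep), c("f1", "f2", "f3"))  # 2% exactly kept
  expect_identical(attr(keep, "dropped"), "f4")
  all_big <- list(avg_importance = c(a = 0.5, b = 0.5))
  class(all_big) <- "surf_rf"
  expect_setequal(as.character(prune_by_importance(all_big)), c("a", "b"))
  tiny <- list(avg_importance = c(a = 0.999, b = 0.0005, c = 0.0005))
  class(tiny) <- "surf_rf"
  expect_length(prune_by_importance(tiny), 2)   # guard keeps two features
})

test_that("algorithm comparison favours the forest on axis-aligned rules", {
  tbl <- make_planted_table(n_per_class = 100, n_noise_features = 3,
                            seed = 12)
  cmp <- compare_algorithms(tbl, n_iterations = 4, num_trees = 100,
                            seed = 12)
  expect_true(all(as.matrix(cmp$accuracy) >= 0 &
                    as.matrix(cmp$accuracy) <= 1))
  expect_gte(mean(cmp$accuracy$random_forest), mean(cmp$accuracy$logistic))

  # no-signal table: everything sits near chance
  set.seed(5)
  flat <- data.frame(f1 = rnorm(120), f2 = rnorm(120),
                     class = factor(rep(c("cytosol", "secreted"), 60)))
  cmp0 <- compare_algorithms(flat, n_iterations = 3, num_trees = 50,
                             seed = 5)
  expect_true(all(abs(colMeans(cmp0$accuracy) - 0.5) < 0.2))
})
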