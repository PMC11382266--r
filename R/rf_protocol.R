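# Balanced repeated-split random-forest training protocol: class-balanced
# 70/30 splits, forest fitting, test metrics, Gini-importance averaging over
# the top models, and importance-floor pruning.

#' Class-balanced train/test split
#'
#' The training set holds `round(train_fraction * nrow(tbl))` rows, split
#' equally between the two classes (`floor(train_size / 2)` per class),
#' sampled without replacement using an independent seeded stream per
#' class; every remaining row goes to the test set.
#'
#' @param tbl Feature table with a two-level `class` column.
#' @param train_fraction Fraction of rows allocated to training.
#' @param seed Integer seed; the split is a pure function of table + seed.
#' @return List with data.frames `train` and `test`; row indices are kept
#'   in attributes `train_idx` / `test_idx`.
#' @export
#' @examples
#' tbl <- make_planted_table(n_per_class = 20, seed = 3)
#' sp <- balanced_split(tbl, 0.7, seed = 1)
#' nrow(sp$train); nrow(sp$test)
balanced_split <- function(tbl, train_fraction = 0.7, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            "class" %in% names(tbl))
  cls <- factor(tbl$class)
  if (nlevels(cls) != 2) stop("balanced_split needs exactly two classes")
  n_train <- round(train_fraction * nrow(tbl))
  n_per_class <- n_train %/% 2L
  train_idx <- integer(0)
  for (k in seq_len(nlevels(cls))) {
    rows <- which(cls == levels(cls)[k])
    if (length(rows) < n_per_class)
      stop("insufficient class \"", levels(cls)[k], "\": ", length(rows),
           " rows < ", n_per_class, " required for training", call. = FALSE)
    picked <- with_seed(derive_seed(seed, k), sample(rows, n_per_class))
    train_idx <- c(train_idx, picked)
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(nrow(tbl)), train_idx)
  out <- list(train = tbl[train_idx, , drop = FALSE],
              test = tbl[test_idx, , drop = FALSE])
  attr(out, "train_idx") <- train_idx
  attr(out, "test_idx") <- test_idx
  out
}

default_positive <- function(levels) {
  if ("secreted" %in% levels) "secreted" else levels[2]
}

#' Train a probability random forest
#'
#' Fits a forest of fully grown trees (no depth limit, minimum node size
#' 1) on bootstrap samples with `sqrt(p)` candidate features per split and
#' probability aggregation, via \pkg{ranger}.  Gini (impurity) importances
#' and in-bag counts are retained for interpretation.
#'
#' @param train Training data.frame with a two-level `class` column.
#' @param num_trees Number of trees.
#' @param mtry Candidate features per split; default `floor(sqrt(p))`.
#' @param seed Integer seed; same data + seed give identical forests.
#' @param positive Name of the positive class; defaults to `"secreted"`
#'   when present, else the second factor level.
#' @param ... Further arguments passed to [ranger::ranger()] (e.g.
#'   `max.depth` for stump forests in diagnostics).
#' @return A `surf_forest`: the ranger fit plus feature names, class
#'   levels, the training data and the positive/negative orientation.
#' @export
train_forest <- function(train, num_trees = 500, mtry = NULL, seed = 1,
                         positive = NULL, ...) {
  stopifnot("class" %in% names(train))
  y <- droplevels(factor(train$class))
  if (nlevels(y) < 2)
    stop("degenerate training set: a single class present", call. = FALSE)
  feats <- feature_columns(train)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(feats))))
  positive <- positive %||% default_positive(levels(y))
  stopifnot(positive %in% levels(y))
  dat <- train[feats]
  dat$.class <- y
  rf <- ranger::ranger(
    dependent.variable.name = ".class", data = dat,
    num.trees = num_trees, mtry = mtry, min.node.size = 1,
    replace = TRUE, probability = TRUE, importance = "impurity",
    keep.inbag = TRUE, seed = seed, num.threads = 1, ...)
  structure(list(rf = rf,
                 features = feats,
                 levels = levels(y),
                 positive = positive,
                 negative = setdiff(levels(y), positive)[1],
                 train = train,
                 seed = seed,
                 cache = new.env(parent = emptyenv())),
            class = "surf_forest")
}

#' @export
print.surf_forest <- function(x, ...) {
  cat("<surf_forest> ", x$rf$num.trees, " trees, ",
      length(x$features), " features, positive class \"", x$positive,
      "\"\n", sep = "")
  invisible(x)
}

check_schema <- function(forest, newdata) {
  missing_f <- setdiff(forest$features, names(newdata))
  if (length(missing_f))
    stop("feature-name error: newdata lacks ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  newdata[forest$features]
}

#' @export
#' @rdname train_forest
#' @param object,newdata,type,... Prediction interface: `type = "prob"`
#'   returns the positive-class probability, `"class"` the predicted label.
predict.surf_forest <- function(object, newdata,
                                type = c("prob", "class"), ...) {
  type <- match.arg(type)
  nd <- check_schema(object, newdata)
  p <- predict(object$rf, data = nd, num.threads = 1)$predictions
  p_pos <- p[, object$positive]
  if (type == "prob") return(p_pos)
  factor(ifelse(p_pos >= 0.5, object$positive, object$negative),
         levels = object$levels)
}

#' Evaluate a forest on a test set
#'
#' Confusion counts (positive = secreted), accuracy, precision, recall,
#' f1 = 2PR/(P+R), the ROC curve over probability thresholds and its
#' trapezoidal AUC.
#'
#' @param forest A `surf_forest`.
#' @param test Test data.frame with the training schema and a `class`
#'   column.
#' @return List of class `surf_metrics`.
#' @export
evaluate_forest <- function(forest, test) {
  stopifnot(nrow(test) > 0, "class" %in% names(test))
  p <- predict(forest, test, type = "prob")
  truth <- factor(as.character(test$class), levels = forest$levels)
  pos <- truth == forest$positive
  pred_pos <- p >= 0.5
  tp <- sum(pred_pos & pos); fp <- sum(pred_pos & !pos)
  fn <- sum(!pred_pos & pos); tn <- sum(!pred_pos & !pos)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  structure(list(confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 accuracy = (tp + tn) / length(p),
                 precision = precision,
                 recall = recall,
                 f1 = f1_score(precision, recall),
                 roc = roc_points(p, pos),
                 auc = roc_auc(p, pos),
                 positive = forest$positive),
            class = "surf_metrics")
}

#' f1 score from precision and recall
#'
#' @param precision,recall Scalars in `[0, 1]`.
#' @return `2 * precision * recall / (precision + recall)` (0 when both
#'   are 0).
#' @export
#' @examples
#' f1_score(0.939, 0.930)
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

# ROC over all probability thresholds; points sorted by increasing FPR.
roc_points <- function(p, pos) {
  th <- sort(unique(c(-Inf, p, Inf)), decreasing = TRUE)
  tpr <- vapply(th, function(t) if (any(pos)) mean(p[pos] >= t) else 0,
                numeric(1))
  fpr <- vapply(th, function(t) if (any(!pos)) mean(p[!pos] >= t) else 0,
                numeric(1))
  data.frame(threshold = th, fpr = fpr, tpr = tpr)
}

roc_auc <- function(p, pos) {
  r <- roc_points(p, pos)
  sum(diff(r$fpr) * (head(r$tpr, -1) + r$tpr[-1]) / 2)
}

#' @export
print.surf_metrics <- function(x, ...) {
  cat(sprintf(paste0("<surf_metrics> accuracy %.3f  precision %.3f  ",
                     "recall %.3f  f1 %.3f  auc %.3f\n"),
              x$accuracy, x$precision, x$recall, x$f1, x$auc))
  invisible(x)
}

normalized_importance <- function(forest) {
  imp <- forest$rf$variable.importance
  imp[imp < 0] <- 0
  if (sum(imp) == 0) return(imp)
  imp / sum(imp)
}

#' Fit the repeated balanced-split forest protocol
#'
#' The central fitting routine: over `n_iterations` class-balanced
#' train/test splits (one recorded derived seed each) it trains a
#' probability random forest, evaluates it on the held-out rows, and
#' records test metrics and normalised Gini importances.  The best run is
#' the one with the highest test accuracy; feature importances are
#' averaged over the `top_k` best runs.
#'
#' @param data Feature table with a two-level `class` column.
#' @param n_iterations Number of independent splits.
#' @param train_fraction Training fraction per split.
#' @param num_trees,mtry Forest hyperparameters, see [train_forest()].
#' @param top_k Number of best runs over which importances are averaged.
#' @param seed Master seed; per-iteration seeds are derived and recorded.
#' @param positive Positive class, see [train_forest()].
#' @return An object of class `surf_rf` with components `runs` (per-run
#'   metrics data.frame), `importances` (runs x features matrix),
#'   `avg_importance` (named, over the top-k runs, summing to 1), `best`
#'   (iteration, forest, metrics, test indices) and `spec`.
#' @seealso [predict.surf_rf()], [threshold_report()],
#'   [prune_by_importance()]
#' @export
#' @examples
#' tbl <- make_planted_table(n_per_class = 60, n_noise_features = 2, seed = 5)
#' fit <- surf_rf(tbl, n_iterations = 3, num_trees = 50, seed = 11)
#' fit
surf_rf <- function(data, n_iterations = 150, train_fraction = 0.7,
                    num_trees = 500, mtry = NULL, top_k = 7, seed = 1,
                    positive = NULL) {
  stopifnot(n_iterations >= 1)
  feats <- feature_columns(data)
  runs <- data.frame(iteration = seq_len(n_iterations),
                     seed = NA_integer_, accuracy = NA_real_,
                     precision = NA_real_, recall = NA_real_,
                     f1 = NA_real_, auc = NA_real_)
  importances <- matrix(NA_real_, n_iterations, length(feats),
                        dimnames = list(NULL, feats))
  best <- NULL
  for (i in seq_len(n_iterations)) {
    seed_i <- derive_seed(seed, i)
    sp <- balanced_split(data, train_fraction, seed = seed_i)
    forest <- train_forest(sp$train, num_trees = num_trees, mtry = mtry,
                           seed = seed_i, positive = positive)
    m <- evaluate_forest(forest, sp$test)
    runs$seed[i] <- seed_i
    runs$accuracy[i] <- m$accuracy
    runs$precision[i] <- m$precision
    runs$recall[i] <- m$recall
    runs$f1[i] <- m$f1
    runs$auc[i] <- m$auc
    importances[i, ] <- normalized_importance(forest)[feats]
    if (is.null(best) || m$accuracy > best$metrics$accuracy)
      best <- list(iteration = i, forest = forest, metrics = m,
                   test_idx = attr(sp, "test_idx"))
  }
  top_k_eff <- min(top_k, n_iterations)
  top_idx <- order(-runs$accuracy)[seq_len(top_k_eff)]
  avg <- colMeans(importances[top_idx, , drop = FALSE])
  avg <- avg / sum(avg)
  structure(list(runs = runs,
                 importances = importances,
                 top_runs = top_idx,
                 avg_importance = avg,
                 best = best,
                 spec = list(n_iterations = n_iterations,
                             train_fraction = train_fraction,
                             num_trees = num_trees,
                             mtry = mtry, top_k = top_k_eff, seed = seed),
                 call = match.call()),
            class = "surf_rf")
}

#' @export
print.surf_rf <- function(x, ...) {
  cat("<surf_rf> balanced repeated-split random-forest protocol\n")
  cat(sprintf("  iterations: %d  (train fraction %.2f, %d trees)\n",
              x$spec$n_iterations, x$spec$train_fraction, x$spec$num_trees))
  cat(sprintf("  test accuracy: mean %.3f  sd %.3f  best %.3f (run %d)\n",
              mean(x$runs$accuracy), sd(x$runs$accuracy),
              x$best$metrics$accuracy, x$best$iteration))
  top <- sort(x$avg_importance, decreasing = TRUE)
  cat("  top features (mean importance over top-", x$spec$top_k, " runs):\n",
      sep = "")
  for (i in seq_len(min(3, length(top))))
    cat(sprintf("    %-24s %.3f\n", names(top)[i], top[i]))
  invisible(x)
}

#' @export
summary.surf_rf <- function(object, ...) {
  out <- list(accuracy = summary(object$runs$accuracy),
              f1 = summary(object$runs$f1),
              best = object$best$metrics,
              avg_importance = sort(object$avg_importance,
                                    decreasing = TRUE))
  class(out) <- "summary.surf_rf"
  out
}

#' @export
print.summary.surf_rf <- function(x, ...) {
  cat("Accuracy across runs:\n"); print(x$accuracy)
  cat("Best run:\n"); print(x$best)
  cat("Averaged importances:\n")
  print(round(x$avg_importance, 4))
  invisible(x)
}

#' Predict with the best forest of a protocol fit
#'
#' @param object A `surf_rf` fit.
#' @param newdata Data with the training feature columns.
#' @param type `"prob"` or `"class"`.
#' @param ... Unused.
#' @return See [predict.surf_forest()].
#' @export
predict.surf_rf <- function(object, newdata, type = c("prob", "class"),
                            ...) {
  predict(object$best$forest, newdata, type = match.arg(type))
}

#' @export
coef.surf_rf <- function(object, ...) object$avg_importance

#' Accuracy density plot of a protocol fit
#'
#' @param x A `surf_rf` fit.
#' @param ... Passed to [plot()].
#' @export
plot.surf_rf <- function(x, ...) {
  d <- density(x$runs$accuracy)
  plot(d, main = "Test accuracy across splits",
       xlab = "accuracy", ...)
  abline(v = x$best$metrics$accuracy, lty = 2)
  invisible(x)
}

#' Drop features below an importance floor
#'
#' Features whose averaged top-k importance is strictly below `floor` are
#' dropped; at least the two most important features are always retained.
#'
#' @param fit A `surf_rf` fit.
#' @param floor Importance floor as a fraction (default 0.02 = 2%).
#' @return Character vector of retained feature names (importance order),
#'   with the dropped names in attribute `dropped`.
#' @export
prune_by_importance <- function(fit, floor = 0.02) {
  stopifnot(inherits(fit, "surf_rf"))
  imp <- sort(fit$avg_importance, decreasing = TRUE)
  keep <- names(imp)[imp >= floor]
  if (length(keep) < 2) keep <- names(imp)[seq_len(min(2, length(imp)))]
  out <- keep
  attr(out, "dropped") <- setdiff(names(imp), keep)
  out
}

#' Repeat the split protocol for five classifier families
#'
#' Runs the same balanced splits for logistic regression, k-nearest
#' neighbours, a support-vector machine, a single-hidden-layer neural
#' network and the random forest, and collects per-split test accuracies.
#' All but the forest see features standardised by the training mean and
#' SD.
#'
#' @param data Feature table with a two-level `class` column.
#' @param n_iterations Number of splits.
#' @param train_fraction Training fraction.
#' @param num_trees Trees for the forest.
#' @param knn_k Neighbours for KNN.
#' @param nnet_size Hidden units for the neural network.
#' @param seed Master seed.
#' @return List with `accuracy` (iterations x algorithms data.frame) and
#'   `densities` (per-algorithm [stats::density()]).
#' @export
compare_algorithms <- function(data, n_iterations = 50, train_fraction = 0.7,
                               num_trees = 500, knn_k = 5, nnet_size = 8,
                               seed = 1) {
  algs <- c("random_forest", "logistic", "knn", "svm", "ann")
  acc <- matrix(NA_real_, n_iterations, length(algs),
                dimnames = list(NULL, algs))
  feats <- feature_columns(data)
  for (i in seq_len(n_iterations)) {
    seed_i <- derive_seed(seed, i)
    sp <- balanced_split(data, train_fraction, seed = seed_i)
    ytr <- droplevels(factor(sp$train$class))
    yte <- factor(as.character(sp$test$class), levels = levels(ytr))
    xtr <- as.matrix(sp$train[feats]); xte <- as.matrix(sp$test[feats])
    mu <- colMeans(xtr); sdev <- apply(xtr, 2, sd); sdev[sdev == 0] <- 1
    ztr <- scale(xtr, mu, sdev); zte <- scale(xte, mu, sdev)

    forest <- train_forest(sp$train, num_trees = num_trees, seed = seed_i)
    acc[i, "random_forest"] <- mean(predict(forest, sp$test,
                                            type = "class") == yte)

    lr_df <- data.frame(ztr); lr_df$.y <- ytr
    lr <- suppressWarnings(stats::glm(.y ~ ., data = lr_df,
                                      family = stats::binomial()))
    p_lr <- predict(lr, newdata = data.frame(zte), type = "response")
    pred_lr <- levels(ytr)[1 + (p_lr >= 0.5)]
    acc[i, "logistic"] <- mean(pred_lr == as.character(yte))

    acc[i, "knn"] <- mean(class::knn(ztr, zte, ytr, k = knn_k) == yte)

    sv <- e1071::svm(ztr, ytr, kernel = "radial")
    acc[i, "svm"] <- mean(predict(sv, zte) == yte)

    nn <- with_seed(seed_i,
                    nnet::nnet(ztr, class.ind_matrix(ytr), size = nnet_size,
                               decay = 0.01, maxit = 200, trace = FALSE,
                               softmax = TRUE))
    pred_nn <- levels(ytr)[max.col(predict(nn, zte))]
    acc[i, "ann"] <- mean(pred_nn == as.character(yte))
  }
  acc <- as.data.frame(acc)
  list(accuracy = acc,
       densities = lapply(acc, function(a)
         if (sd(a) > 0) density(a) else NULL))
}

# one-hot class indicator for nnet's softmax interface
class.ind_matrix <- function(y) {
  m <- matrix(0, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}
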