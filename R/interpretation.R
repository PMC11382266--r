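# Decision-path contribution decomposition of forest predictions and
# extraction of quantitative class-boundary thresholds.

# Per-tree node table: class probabilities at every node (in-bag training
# distribution), parent links, and the cumulative per-feature contribution
# vector of every leaf.  Cached on the forest.
tree_tables <- function(forest) {
  cache <- forest$cache
  if (!is.null(cache$tables)) return(cache$tables)
  rf <- forest$rf
  feats <- forest$features
  ntree <- rf$num.trees
  train_x <- forest$train[feats]
  tn_train <- predict(rf, data = train_x, type = "terminalNodes",
                      num.threads = 1)$predictions
  y <- factor(as.character(forest$train$class), levels = forest$levels)
  neg <- forest$negative
  tables <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    ti <- ranger::treeInfo(rf, t)
    nn <- nrow(ti)
    stopifnot(identical(ti$nodeID, 0:(nn - 1)))
    w <- rf$inbag.counts[[t]]
    leaf_of <- tn_train[, t]
    cnt_neg <- numeric(nn); cnt_all <- numeric(nn)
    agg_all <- rowsum(w, leaf_of)
    agg_neg <- rowsum(w * (y == neg), leaf_of)
    at <- as.integer(rownames(agg_all)) + 1L
    cnt_all[at] <- agg_all; cnt_neg[at] <- agg_neg
    # children always carry larger nodeIDs: accumulate bottom-up
    for (r in nn:1) {
      if (ti$terminal[r]) next
      l <- ti$leftChild[r] + 1L; rt <- ti$rightChild[r] + 1L
      cnt_all[r] <- cnt_all[l] + cnt_all[rt]
      cnt_neg[r] <- cnt_neg[l] + cnt_neg[rt]
    }
    p <- ifelse(cnt_all > 0, cnt_neg / cnt_all, NA_real_)
    parent <- integer(nn); pfeat <- integer(nn)
    inner <- which(!ti$terminal)
    parent[ti$leftChild[inner] + 1L] <- inner
    parent[ti$rightChild[inner] + 1L] <- inner
    fidx <- match(ti$splitvarName, feats)
    # cumulative contribution per leaf: walk each leaf up to the root
    leaves <- which(ti$terminal)
    contrib <- matrix(0, length(leaves), length(feats))
    for (k in seq_along(leaves)) {
      node <- leaves[k]
      while (node != 1L) {
        par <- parent[node]
        f <- fidx[par]
        contrib[k, f] <- contrib[k, f] + (p[node] - p[par])
        node <- par
      }
    }
    tables[[t]] <- list(leaf_ids = ti$nodeID[leaves],
                        contrib = contrib,
                        bias = p[1])
  }
  cache$tables <- tables
  tables
}

#' Decompose forest predictions into per-feature contributions
#'
#' Walks every sample root-to-leaf through every tree; at each split the
#' change in the node's class probability (the in-bag training
#' distribution at the node) is credited to the split's feature, and
#' contributions are averaged over trees.  By construction
#' `bias + rowSums(contributions)` equals the forest's predicted
#' probability of the orientation class for every sample.  Positive
#' contributions push the prediction toward the cytosol (negative) class,
#' matching the orientation of contribution-versus-value plots.
#'
#' @param forest A `surf_forest` (see [train_forest()]).
#' @param samples Data with the training feature columns.
#' @return Object of class `contribution_profile`: `bias` (mean root
#'   probability), `contributions` (samples x features matrix), `values`
#'   (feature values), `prediction` (`bias + rowSums(contributions)`) and
#'   `toward` (the class positive contributions point to).
#' @export
#' @examples
#' tbl <- make_planted_table(n_per_class = 40, n_noise_features = 1, seed = 2)
#' f <- train_forest(balanced_split(tbl, 0.7, 1)$train, num_trees = 25)
#' pr <- decompose(f, tbl)
#' max(abs(pr$bias + rowSums(pr$contributions) - pr$prediction))
decompose <- function(forest, samples) {
  stopifnot(inherits(forest, "surf_forest"))
  nd <- check_schema(forest, samples)
  tabs <- tree_tables(forest)
  tn <- predict(forest$rf, data = nd, type = "terminalNodes",
                num.threads = 1)$predictions
  n <- nrow(nd); pfeats <- length(forest$features)
  total <- matrix(0, n, pfeats,
                  dimnames = list(rownames(nd), forest$features))
  bias <- 0
  for (t in seq_along(tabs)) {
    tab <- tabs[[t]]
    idx <- match(tn[, t], tab$leaf_ids)
    total <- total + tab$contrib[idx, , drop = FALSE]
    bias <- bias + tab$bias
  }
  ntree <- length(tabs)
  structure(list(bias = bias / ntree,
                 contributions = total / ntree,
                 values = nd,
                 prediction = bias / ntree + rowSums(total) / ntree,
                 toward = forest$negative),
            class = "contribution_profile")
}

#' @export
print.contribution_profile <- function(x, ...) {
  cat("<contribution_profile> ", nrow(x$contributions), " samples, ",
      ncol(x$contributions), " features; bias ", round(x$bias, 3),
      " toward \"", x$toward, "\"\n", sep = "")
  invisible(x)
}

#' Extract a class-boundary threshold from a contribution profile
#'
#' Fits a one-dimensional stump on the sign of the contribution: the
#' boundary is the feature value that best separates samples with positive
#' (cytosol-side) from negative (secreted-side) contributions, reported as
#' the midpoint of the two straddling sample values, rounded to one
#' decimal.  The separation score is the fraction of samples whose
#' contribution sign matches their side.
#'
#' @param values Feature values (percent).
#' @param contributions Signed contributions of the same feature (positive
#'   = toward cytosol).
#' @param min_samples Minimum number of samples with nonzero contribution.
#' @return List: `boundary`, `secreted_side` (`"<"` or `">"`, the side on
#'   which the feature votes secreted), `separation` in `[0.5, 1]`, `n`.
#'   All-same-sign profiles give a warning and `NA` fields (the feature
#'   does not discriminate).
#' @export
extract_threshold <- function(values, contributions, min_samples = 10) {
  stopifnot(length(values) == length(contributions))
  nz <- contributions != 0
  if (sum(nz) < min_samples)
    stop("need at least ", min_samples,
         " samples with nonzero contributions", call. = FALSE)
  v <- values[nz]; s <- sign(contributions[nz])
  if (all(s > 0) || all(s < 0)) {
    warning("no boundary: all contributions share one sign ",
            "(feature non-discriminative)")
    return(list(boundary = NA_real_, secreted_side = NA_character_,
                separation = NA_real_, n = sum(nz)))
  }
  ord <- order(v)
  v <- v[ord]; s <- s[ord]
  n <- length(v)
  pos_cum <- cumsum(s > 0)
  neg_cum <- cumsum(s < 0)
  cuts <- which(v[-n] < v[-1])        # only between distinct values
  if (!length(cuts)) {
    warning("no boundary: all values identical")
    return(list(boundary = NA_real_, secreted_side = NA_character_,
                separation = NA_real_, n = n))
  }
  # score for "positive (cytosol) contributions lie left of the cut"
  left_pos <- (pos_cum[cuts] + (neg_cum[n] - neg_cum[cuts])) / n
  score <- pmax(left_pos, 1 - left_pos)
  k <- cuts[which.max(score)]
  boundary <- round((v[k] + v[k + 1]) / 2, 1)
  # secreted = side with negative mean contribution
  left_mean <- mean(s[seq_len(k)])
  secreted_side <- if (left_mean < mean(s[(k + 1):n])) "<" else ">"
  list(boundary = boundary, secreted_side = secreted_side,
       separation = max(score), n = n)
}

#' Boundary thresholds for the most important features
#'
#' Decomposes the best forest's predictions on a table and extracts a
#' boundary threshold for each of the `top_n` features by averaged
#' importance, with the direction expressed for the secreted class.
#'
#' @param fit A `surf_rf` protocol fit.
#' @param table Feature table (typically the full data).
#' @param top_n Number of top features to report.
#' @return A data.frame of class `threshold_report`: `feature`,
#'   `importance`, `boundary`, `secreted_side`, `separation`.
#' @export
threshold_report <- function(fit, table, top_n = 3) {
  stopifnot(inherits(fit, "surf_rf"), top_n >= 1)
  imp <- sort(fit$avg_importance, decreasing = TRUE)
  feats <- names(imp)[seq_len(min(top_n, length(imp)))]
  prof <- decompose(fit$best$forest, table)
  rows <- lapply(feats, function(f) {
    th <- withCallingHandlers(
      extract_threshold(table[[f]], prof$contributions[, f]),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(feature = f, importance = unname(imp[f]),
               boundary = th$boundary, secreted_side = th$secreted_side,
               separation = th$separation, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_report", "data.frame")
  out
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("Boundary values for the secreted class:\n")
  for (i in seq_len(nrow(x))) {
    if (is.na(x$boundary[i])) {
      cat(sprintf("  %-24s (no boundary)\n", x$feature[i]))
    } else {
      cat(sprintf("  %-24s secreted %s%.1f%%   (separation %.2f)\n",
                  x$feature[i], x$secreted_side[i], x$boundary[i],
                  x$separation[i]))
    }
  }
  invisible(x)
}
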