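# End-to-end orchestration: features -> prune -> train -> interpret, with a
# manifest recording every seed, cutoff and artifact hash.

#' Assemble a run configuration
#'
#' @param table Path to a feature-table CSV (columns = descriptors plus
#'   `class`), or `NULL` when `structures`/`labels` are given.
#' @param structures Character vector of structure file paths (PDB/mmCIF).
#' @param labels Path to a two-column TSV `protein_id <TAB> class`, or a
#'   named character vector.
#' @param output_dir Directory for artifacts (created if missing).
#' @param seed Global seed; per-stage seeds are derived from it and
#'   recorded in the manifest.
#' @param sasa [sasa_params()].
#' @param correlation_threshold Pairwise `|r|` above which one feature of a
#'   pair is removed.
#' @param importance_floor Averaged-importance floor below which features
#'   are dropped.
#' @param n_iterations,train_fraction,num_trees,top_k Protocol settings,
#'   see [surf_rf()].
#' @param top_n Number of features in the threshold report.
#' @return List of class `run_config`.
#' @export
run_config <- function(table = NULL, structures = NULL, labels = NULL,
                       output_dir = tempfile("surfclass_run_"), seed = 1,
                       sasa = sasa_params(),
                       correlation_threshold = 0.85,
                       importance_floor = 0.02,
                       n_iterations = 150, train_fraction = 0.7,
                       num_trees = 500, top_k = 7, top_n = 3) {
  stopifnot(xor(is.null(table), is.null(structures)),
            correlation_threshold > 0, correlation_threshold < 1,
            importance_floor >= 0, importance_floor < 1)
  for (f in c(table, structures))
    if (!file.exists(f)) stop("input file not found: ", f)
  if (is.character(labels) && length(labels) == 1 && file.exists(labels))
    labels <- labels
  structure(list(table = table, structures = structures, labels = labels,
                 output_dir = output_dir, seed = seed, sasa = sasa,
                 correlation_threshold = correlation_threshold,
                 importance_floor = importance_floor,
                 n_iterations = n_iterations,
                 train_fraction = train_fraction,
                 num_trees = num_trees, top_k = top_k, top_n = top_n),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [run_config()]; `sasa` may be a
#' mapping with `probe_radius`, `n_sphere_points`, `rel_cutoff`.
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sasa <- do.call(sasa_params, y$sasa %||% list())
  args <- y[setdiff(names(y), "sasa")]
  args$sasa <- sasa
  do.call(run_config, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes feature extraction (or loads a prepared table), correlation
#' pruning, the repeated-split forest protocol, importance pruning and
#' threshold extraction, writing each stage's artifact plus a JSON
#' manifest (seeds, cutoffs, md5 hashes) sufficient to reproduce the run.
#'
#' @param config A `run_config`, or a path to a YAML file.
#' @return The manifest, invisibly (also written to
#'   `output_dir/manifest.json`).
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  artifacts <- character(0)

  tbl <- stage("features", {
    if (!is.null(config$table)) {
      t0 <- read.csv(config$table, stringsAsFactors = FALSE)
      if (!"class" %in% names(t0)) stop("table has no class column")
      t0$class <- factor(t0$class)
      t0
    } else {
      labs <- config$labels
      if (is.character(labs) && length(labs) == 1 && file.exists(labs)) {
        lt <- read.delim(labs, header = TRUE, stringsAsFactors = FALSE)
        labs <- setNames(lt[[2]], lt[[1]])
      }
      structures <- lapply(config$structures, read_structure)
      build_feature_table(structures, labs, config$sasa)
    }
  })
  write.csv(tbl, out("features.csv"), row.names = FALSE)
  artifacts <- c(artifacts, "features.csv")

  pruned <- stage("prune", prune_correlated(tbl, config$correlation_threshold))
  write.csv(pruned$table, out("features_pruned.csv"), row.names = FALSE)
  writeLines(pruned$removed, out("removed_features.txt"))
  artifacts <- c(artifacts, "features_pruned.csv")

  fit <- stage("train", surf_rf(
    pruned$table, n_iterations = config$n_iterations,
    train_fraction = config$train_fraction, num_trees = config$num_trees,
    top_k = config$top_k, seed = derive_seed(config$seed, 1001)))
  write.csv(fit$runs, out("runs.csv"), row.names = FALSE)
  imp <- data.frame(feature = names(fit$avg_importance),
                    importance = unname(fit$avg_importance))
  write.csv(imp[order(-imp$importance), ], out("importance.csv"),
            row.names = FALSE)
  retained <- prune_by_importance(fit, config$importance_floor)
  writeLines(retained, out("retained_features.txt"))
  artifacts <- c(artifacts, "runs.csv", "importance.csv")

  thr <- stage("interpret",
               threshold_report(fit, pruned$table, config$top_n))
  write.table(thr, out("thresholds.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  artifacts <- c(artifacts, "thresholds.tsv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("surfclass")),
    seed = config$seed,
    derived_seeds = list(protocol = derive_seed(config$seed, 1001),
                         iterations = fit$runs$seed),
    parameters = list(
      sasa = unclass(config$sasa),
      correlation_threshold = config$correlation_threshold,
      importance_floor = config$importance_floor,
      n_iterations = config$n_iterations,
      train_fraction = config$train_fraction,
      num_trees = config$num_trees,
      top_k = config$top_k, top_n = config$top_n),
    inputs = as.list(tools::md5sum(c(config$table, config$structures))),
    best_run = list(iteration = fit$best$iteration,
                    accuracy = fit$best$metrics$accuracy,
                    f1 = fit$best$metrics$f1),
    removed_by_correlation = pruned$removed,
    retained_features = as.character(retained),
    artifacts = as.list(tools::md5sum(file.path(config$output_dir,
                                                artifacts))))
  names(manifest$artifacts) <- artifacts
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
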