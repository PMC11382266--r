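params_fast <- sasa_params(n_sphere_points = 480)

dv <- function(s) {
  descriptor_vector(s, surface_profile(s, params_fast), assign_ss(s))
}

test_that("surface compositions are plain percentages of surface residues", {
  s <- make_structure("EECL", geometry = "extended")  # all 4 exposed
  v <- dv(s)
  expect_equal(unname(v["surf_GLU"]), 50)
  expect_equal(unname(v["surf_CYS"]), 25)
  expect_equal(unname(v["surf_LEU"]), 25)
  expect_equal(sum(v[paste0("surf_", surfclass:::AA3)]), 100,
               tolerance = 1e-9)
  expect_equal(unname(v["surf_ALA"]), 0)
  expect_equal(unname(v["surface_ratio"]), 100)
})

test_that("residue-class compositions follow the class definitions", {
  v <- dv(make_structure("RHK", geometry = "extended"))
  expect_equal(unname(v["surf_positive"]), 100)
  expect_equal(unname(v["surf_hydrophilic"]), 100)
  expect_equal(unname(v["surf_hydrophobic"]), 0)
  # Gly belongs to no class: class percentages all zero
  vg <- dv(make_structure("GGG", geometry = "extended"))
  expect_equal(unname(vg["surf_GLY"]), 100)
  expect_equal(unname(vg[paste0("surf_", c("positive", "negative",
                                           "polar_uncharged", "hydrophobic",
                                           "hydrophilic"))]),
               rep(0, 5))
  cls <- residue_classes()
  expect_length(unique(unlist(cls[c("positive", "negative",
                                    "polar_uncharged", "hydrophobic")])), 17)
})

test_that("hydrophilic equals positive + negative + polar_uncharged", {
  for (seq in c("AEKLVGSTAD", "RNDCQEGHIL", "KMFPSTWYVA")) {
    v <- dv(make_structure(seq, geometry = "coil", seed = 2))
    expect_equal(unname(v["surf_hydrophilic"]),
                 unname(v["surf_positive"] + v["surf_negative"] +
                          v["surf_polar_uncharged"]),
                 tolerance = 1e-12)
  }
})

test_that("feature tables are deterministic with one row per protein", {
  seqs <- c("AEKLVGSTAD", "RNDCQEGHIL", "KMFPSTWYVA")
  structs <- lapply(seq_along(seqs), function(i)
    make_structure(seqs[i], geometry = "coil", seed = i,
                   protein_id = paste0("p", i)))
  tbl <- build_feature_table(structs, c("cytosol", "secreted", "cytosol"),
                             params_fast)
  expect_equal(dim(tbl), c(3L, 35L))
  expect_true(all(!is.na(as.matrix(tbl[descriptor_names()]))))
  expect_named(tbl, c(descriptor_names(), "class"))

  # identical structure under two ids gives identical rows
  s1 <- make_structure("AEKLV", geometry = "helix", protein_id = "a")
  s2 <- make_structure("AEKLV", geometry = "helix", protein_id = "b")
  t2 <- build_feature_table(list(s1, s2), c("cytosol", "secreted"),
                            params_fast)
  expect_equal(unname(as.numeric(t2[1, descriptor_names()])),
               unname(as.numeric(t2[2, descriptor_names()])))

  expect_error(
    build_feature_table(list(s1, s1), c("cytosol", "secreted"), params_fast),
    "duplicate")
})

test_that("zero surface residues raise an undefined-composition error", {
  s <- make_structure("AAA", geometry = "extended")
  prof <- surface_profile(s, params_fast)
  prof$is_surface[] <- FALSE
  expect_error(descriptor_vector(s, prof, assign_ss(s)),
               "undefined composition")
})

test_that("correlation pruning removes the higher-cumulative member", {
  set.seed(10)
  n <- 60
  f1 <- runif(n, 0, 10)
  tbl <- data.frame(f1 = f1,
                    f2 = 2 * f1 + rnorm(n, 0, 0.01),
                    f3 = runif(n, 0, 10),
                    class = factor(rep(c("a", "b"), n / 2)))
  res <- prune_correlated(tbl, 0.85)
  # brute-force oracle: member of the offending pair with larger total |r|
  r <- abs(cor(tbl[c("f1", "f2", "f3")])); diag(r) <- 0
  expected_drop <- c("f1", "f2")[which.max(c(sum(r["f1", ]), sum(r["f2", ])))]
  expect_identical(res$removed, expected_drop)
  expect_setequal(names(res$table),
                  c(setdiff(c("f1", "f2", "f3"), expected_drop), "class"))
})

test_that("pruning is strict at the threshold and idempotent", {
  set.seed(3)
  n <- 50
  x <- rnorm(n)
  tbl <- data.frame(f1 = x, f2 = 0.6 * x + rnorm(n), f3 = rnorm(n),
                    class = factor(rep(c("a", "b"), n / 2)))
  r12 <- abs(cor(tbl$f1, tbl$f2))
  # a pair exactly AT the threshold is kept (strictly "above")
  res_at <- prune_correlated(tbl, threshold = r12)
  expect_length(res_at$removed, 0)
  expect_identical(res_at$table, tbl)
  # just below the pair's |r| it is pruned, and pruning again is a no-op
  res <- prune_correlated(tbl, threshold = r12 - 1e-9)
  expect_length(res$removed, 1)
  res2 <- prune_correlated(res$table, threshold = r12 - 1e-9)
  expect_length(res2$removed, 0)
})

test_that("no surviving pair exceeds the threshold on random tables", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    base <- matrix(rnorm(n * 3), n, 3)
    x <- cbind(base,
               base[, 1] + rnorm(n, 0, 0.2),
               base[, 2] + rnorm(n, 0, 0.3),
               base[, 1] - base[, 2] + rnorm(n, 0, 0.2))
    colnames(x) <- paste0("g", 1:6)
    tbl <- as.data.frame(x)
    res <- prune_correlated(tbl, 0.85)
    r <- abs(cor(res$table)); diag(r) <- 0
    expect_true(all(r <= 0.85))
    expect_length(prune_correlated(res$table, 0.85)$removed, 0)
  }
})

test_that("zero-variance columns are flagged and removed", {
  tbl <- data.frame(f1 = rnorm(30), f2 = rnorm(30), flat = rep(5, 30),
                    class = factor(rep(c("a", "b"), 15)))
  expect_warning(res <- prune_correlated(tbl, 0.85), "zero-variance")
  expect_true("flat" %in% res$removed)
})

test_that("group_report behaves under null, shifted and degenerate data", {
  # null: both classes from the same distribution
  null_p <- vapply(1:200, function(seed) {
    set.seed(seed)
    tbl <- data.frame(d = rnorm(50), class = factor(rep(c("a", "b"), 25)))
    group_report(tbl, "d")$p_value
  }, numeric(1))
  expect_gte(mean(null_p > 0.05), 0.90)

  set.seed(1)
  shifted <- data.frame(d = c(rnorm(100), rnorm(100, 5)),
                        class = factor(rep(c("a", "b"), each = 100)))
  rep_s <- group_report(shifted, "d")
  expect_lt(rep_s$p_value, 1e-10)
  expect_equal(sum(unlist(rep_s$counts)), 200)

  flat <- data.frame(d = rep(2, 20), class = factor(rep(c("a", "b"), 10)))
  expect_warning(rep_f <- group_report(flat, "d"), "degenerate")
  expect_equal(rep_f$p_value, 1)

  single <- data.frame(d = rnorm(10), class = factor(rep("a", 10)))
  expect_error(group_report(single, "d"), "single class")
})
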