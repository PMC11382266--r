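# Per-protein surface-chemistry descriptors, feature tables, correlation
# pruning and group comparison reports.

#' Residue property classes
#'
#' The four residue classes used for grouped surface compositions:
#' positively charged (Arg, His, Lys), negatively charged (Asp, Glu),
#' polar uncharged (Ser, Thr, Asn, Gln) and hydrophobic (Ala, Ile, Leu,
#' Met, Phe, Trp, Tyr, Val); hydrophilic is the union of the first three.
#' Gly, Pro and Cys belong to none of the four classes, so class
#' percentages need not sum to 100.
#'
#' @return Named list of three-letter code vectors.
#' @export
residue_classes <- function() {
  positive <- c("ARG", "HIS", "LYS")
  negative <- c("ASP", "GLU")
  polar_uncharged <- c("SER", "THR", "ASN", "GLN")
  list(positive = positive,
       negative = negative,
       polar_uncharged = polar_uncharged,
       hydrophobic = c("ALA", "ILE", "LEU", "MET", "PHE", "TRP", "TYR", "VAL"),
       hydrophilic = c(positive, negative, polar_uncharged))
}

# side-chain functional-group bearers
FUNCTIONAL_GROUPS <- list(amide = c("ASN", "GLN"),
                          hydroxyl = c("SER", "THR", "TYR"),
                          carboxyl = c("ASP", "GLU"),
                          thiol = "CYS")

#' Names of the default descriptor registry
#'
#' The default registry holds 34 descriptors, all in percent units: the 20
#' surface amino-acid compositions (`surf_ALA` ... `surf_VAL`), five
#' surface residue-class compositions, surface and overall helix/sheet
#' compositions, the surface-residue ratio, and four surface functional-
#' group compositions (amide, hydroxyl, carboxyl, thiol side chains).
#'
#' @return Character vector of descriptor names.
#' @export
descriptor_names <- function() {
  c(paste0("surf_", AA3),
    paste0("surf_", c("hydrophilic", "hydrophobic", "positive", "negative",
                      "polar_uncharged")),
    "surf_helix", "surf_sheet", "overall_helix", "overall_sheet",
    "surface_ratio",
    paste0("surf_", names(FUNCTIONAL_GROUPS)))
}

#' Compute the descriptor vector of one protein
#'
#' Surface compositions are computed over surface residues only (the
#' `is_surface` flag of the profile); overall quantities over all
#' residues.  All values are percentages.
#'
#' @param s A `surf_structure`.
#' @param prof Its [surface_profile()].
#' @param ss Its [assign_ss()] labels.
#' @return Named numeric vector over [descriptor_names()], with the
#'   protein id as attribute `protein_id`.
#' @export
descriptor_vector <- function(s, prof, ss) {
  stopifnot(inherits(s, "surf_structure"),
            inherits(prof, "surface_profile"),
            length(ss) == nrow(prof))
  surf <- prof$is_surface
  if (!any(surf))
    stop("undefined composition: structure has no surface residues",
         call. = FALSE)
  res_surf <- prof$resid[surf]
  pct <- function(members, pool) 100 * mean(pool %in% members)
  v <- setNames(numeric(length(descriptor_names())), descriptor_names())
  for (aa in AA3) v[paste0("surf_", aa)] <- pct(aa, res_surf)
  cls <- residue_classes()
  for (nm in names(cls)) v[paste0("surf_", nm)] <- pct(cls[[nm]], res_surf)
  sc <- ss_composition(ss, mask = surf)
  oc <- ss_composition(ss)
  v["surf_helix"] <- sc[["H"]]
  v["surf_sheet"] <- sc[["E"]]
  v["overall_helix"] <- oc[["H"]]
  v["overall_sheet"] <- oc[["E"]]
  v["surface_ratio"] <- 100 * mean(surf)
  for (nm in names(FUNCTIONAL_GROUPS))
    v[paste0("surf_", nm)] <- pct(FUNCTIONAL_GROUPS[[nm]], res_surf)
  attr(v, "protein_id") <- s$protein_id
  v
}

#' Build a feature table from labelled structures
#'
#' Applies the full descriptor registry uniformly to each structure and
#' assembles the proteins x descriptors table that the training protocol
#' consumes.
#'
#' @param structures List of `surf_structure` objects with unique
#'   `protein_id`s.
#' @param labels Character vector of class labels (`cytosol`, `secreted`,
#'   or `both`), either unnamed and parallel to `structures` or named by
#'   protein id.
#' @param params [sasa_params()] used for every structure.
#' @return A data.frame with `protein_id` rownames, descriptor columns and
#'   a `class` factor column.
#' @export
build_feature_table <- function(structures, labels, params = sasa_params()) {
  stopifnot(length(structures) >= 1)
  ids <- vapply(structures, function(s) s$protein_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate protein_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (!is.null(names(labels))) labels <- labels[ids]
  stopifnot(length(labels) == length(structures), !anyNA(labels))
  rows <- lapply(structures, function(s) {
    prof <- surface_profile(s, params)
    descriptor_vector(s, prof, assign_ss(s))
  })
  tbl <- as.data.frame(do.call(rbind, rows))
  rownames(tbl) <- ids
  tbl$class <- factor(as.character(labels))
  tbl
}

feature_columns <- function(tbl) setdiff(names(tbl), "class")

#' Remove one feature of every highly correlated pair
#'
#' Finds feature pairs with `|Pearson r|` strictly above `threshold` and,
#' working through the pairs in descending `|r|` order, removes from each
#' the member with the larger cumulative `|r|` against all other features
#' (pairs whose members were already removed are skipped).  Zero-variance
#' columns are removed up front with a warning since their correlation is
#' undefined.  The label column is untouched.
#'
#' @param tbl A feature table (data.frame, optional `class` column).
#' @param threshold Correlation threshold; pairs at exactly the threshold
#'   are kept.
#' @return List with `table` (pruned), `removed` (character vector in
#'   removal order) and `pairs` (the offending pairs examined).
#' @export
prune_correlated <- function(tbl, threshold = 0.85) {
  feats <- feature_columns(tbl)
  if (length(feats) < 2) stop("need at least two feature columns")
  x <- as.matrix(tbl[feats])
  if (nrow(x) < 3) stop("need at least three rows")
  constant <- apply(x, 2, function(col) sd(col) == 0 || !is.finite(sd(col)))
  removed <- character(0)
  if (any(constant)) {
    warning("removing zero-variance feature(s): ",
            paste(feats[constant], collapse = ", "))
    removed <- feats[constant]
    x <- x[, !constant, drop = FALSE]
  }
  r <- abs(cor(x))
  diag(r) <- 0
  cum_r <- rowSums(r)
  pairs <- which(upper.tri(r) & r > threshold, arr.ind = TRUE)
  out_pairs <- NULL
  if (nrow(pairs)) {
    nm <- colnames(r)
    pr <- data.frame(a = nm[pairs[, 1]], b = nm[pairs[, 2]],
                     r = r[pairs], stringsAsFactors = FALSE)
    # deterministic order: descending |r|, then lexicographic
    pr <- pr[order(-pr$r, pr$a, pr$b), , drop = FALSE]
    for (k in seq_len(nrow(pr))) {
      a <- pr$a[k]; b <- pr$b[k]
      if (a %in% removed || b %in% removed) next
      drop <- if (cum_r[a] > cum_r[b]) a
              else if (cum_r[b] > cum_r[a]) b
              else sort(c(a, b))[2]   # tie-break by name
      removed <- c(removed, drop)
    }
    out_pairs <- pr
  }
  keep <- setdiff(names(tbl), removed)
  list(table = tbl[keep], removed = removed, pairs = out_pairs)
}

#' Compare one descriptor between classes
#'
#' Histogram counts on shared bins, per-class mean and SD, and a
#' Mann-Whitney U (Wilcoxon rank-sum) p-value for the two-class
#' difference.
#'
#' @param tbl Feature table with a `class` column.
#' @param descriptor Name of the descriptor column to compare.
#' @param n_bins Number of shared histogram bins.
#' @return List of class `group_report`: `descriptor`, `breaks`, `counts`
#'   (per class), `means`, `sds`, `n`, `p_value`, `test`.
#' @export
group_report <- function(tbl, descriptor, n_bins = 30) {
  if (!descriptor %in% names(tbl)) stop("unknown descriptor: ", descriptor)
  if (!"class" %in% names(tbl)) stop("table has no class column")
  cls <- droplevels(factor(tbl$class))
  if (nlevels(cls) < 2)
    stop("no comparison possible: a single class present", call. = FALSE)
  if (nlevels(cls) > 2)
    stop("group_report compares exactly two classes")
  if (any(table(cls) < 2)) stop("need at least two rows per class")
  v <- tbl[[descriptor]]
  breaks <- seq(min(v), max(v), length.out = n_bins + 1)
  if (min(v) == max(v)) breaks <- min(v) + c(-0.5, 0.5)
  counts <- lapply(split(v, cls), function(g)
    hist(g, breaks = breaks, plot = FALSE, include.lowest = TRUE)$counts)
  g1 <- v[cls == levels(cls)[1]]
  g2 <- v[cls == levels(cls)[2]]
  if (sd(g1) == 0 && sd(g2) == 0 && g1[1] == g2[1]) {
    warning("degenerate test: descriptor constant in both classes")
    p <- 1
  } else {
    p <- suppressWarnings(wilcox.test(g1, g2)$p.value)
  }
  structure(list(descriptor = descriptor,
                 breaks = breaks,
                 counts = counts,
                 means = vapply(split(v, cls), mean, numeric(1)),
                 sds = vapply(split(v, cls), sd, numeric(1)),
                 n = table(cls),
                 p_value = p,
                 test = "Mann-Whitney U (Wilcoxon rank-sum)"),
            class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  cat("<group_report> ", x$descriptor, "\n", sep = "")
  for (g in names(x$means))
    cat(sprintf("  %-10s n = %3d  mean = %7.3f  sd = %6.3f\n",
                g, x$n[[g]], x$means[[g]], x$sds[[g]]))
  cat(sprintf("  %s p = %.3g\n", x$test, x$p_value))
  invisible(x)
}
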