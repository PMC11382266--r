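# Generators for synthetic test inputs: ideal-geometry polypeptides and
# planted-threshold feature tables.

BOND_N_CA <- 1.458; BOND_CA_C <- 1.525; BOND_C_N <- 1.329
BOND_C_O <- 1.231; BOND_CA_CB <- 1.521
ANG_N_CA_C <- 111.2; ANG_CA_C_N <- 116.2; ANG_C_N_CA <- 121.7
ANG_CA_C_O <- 120.8; ANG_C_CA_CB <- 110.1
OMEGA <- 180
IDEAL_PHI_PSI <- list(helix = c(-57, -47),
                      strand = c(-139, 135),
                      extended = c(180, 180))

#' Build a synthetic polypeptide structure with ideal geometry
#'
#' Constructs an all-heavy-atom backbone (N, CA, C, O) from ideal bond
#' lengths and angles with geometry-specific dihedrals (helix phi/psi =
#' -57/-47, strand -139/+135, extended 180/180, coil = per-residue random
#' dihedrals), plus a C-beta stub for every residue except glycine.
#' Optional isotropic Gaussian noise perturbs all coordinates.  The result
#' is a pure function of its arguments: the same spec and seed give
#' bitwise-identical coordinates.
#'
#' @param sequence One-letter amino-acid sequence (20 standard letters).
#' @param geometry `"helix"`, `"strand"`, `"extended"` or `"coil"`.
#' @param perturbation_sd Standard deviation (angstrom) of Gaussian
#'   coordinate noise added per axis; 0 for ideal geometry.
#' @param seed Integer seed controlling coil dihedrals and perturbation.
#' @param protein_id Identifier for the structure.
#' @param chain Chain identifier.
#' @return A `surf_structure`.
#' @export
#' @examples
#' s <- make_structure("AAAAAAAAAAAAAAA", geometry = "helix")
#' residue_sequence(s)
make_structure <- function(sequence,
                           geometry = c("helix", "strand", "extended", "coil"),
                           perturbation_sd = 0, seed = 1,
                           protein_id = "synthetic", chain = "A") {
  geometry <- match.arg(geometry)
  stopifnot(perturbation_sd >= 0)
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(letters1, AA1)
  if (length(bad))
    stop("invalid sequence letter(s): ", paste(unique(bad), collapse = ", "))
  if (length(letters1) < 1) stop("empty sequence")
  res3 <- unname(AA3[letters1])
  n <- length(res3)

  with_seed(seed, {
    if (geometry == "coil") {
      # broad, loosely Ramachandran-plausible dihedral draws
      phi <- runif(n, -160, -50)
      psi <- runif(n, -60, 170)
    } else {
      phi <- rep(IDEAL_PHI_PSI[[geometry]][1], n)
      psi <- rep(IDEAL_PHI_PSI[[geometry]][2], n)
    }
    bb <- build_backbone(n, phi, psi)
    atoms <- assemble_atoms(bb, res3, chain)
    if (perturbation_sd > 0) {
      atoms$x <- atoms$x + rnorm(nrow(atoms), 0, perturbation_sd)
      atoms$y <- atoms$y + rnorm(nrow(atoms), 0, perturbation_sd)
      atoms$z <- atoms$z + rnorm(nrow(atoms), 0, perturbation_sd)
    }
    new_structure(protein_id, atoms)
  })
}

# NeRF chain extension for the backbone; returns per-residue coordinate list.
build_backbone <- function(n, phi, psi) {
  res <- vector("list", n)
  N <- c(0, 0, 0); CA <- c(BOND_N_CA, 0, 0)
  C <- place_atom(c(0, 1, 0), N, CA, BOND_CA_C, ANG_N_CA_C, 60)
  res[[1]] <- list(N = N, CA = CA, C = C)
  if (n > 1) {
    for (i in 2:n) {
      p <- res[[i - 1]]
      Np <- place_atom(p$N, p$CA, p$C, BOND_C_N, ANG_CA_C_N, psi[i - 1])
      CAp <- place_atom(p$CA, p$C, Np, BOND_N_CA, ANG_C_N_CA, OMEGA)
      Cp <- place_atom(p$C, Np, CAp, BOND_CA_C, ANG_N_CA_C, phi[i])
      res[[i]] <- list(N = Np, CA = CAp, C = Cp)
    }
  }
  for (i in seq_len(n)) {
    r <- res[[i]]
    # carbonyl O opposite the next amide N (same formula at the C terminus)
    res[[i]]$O <- place_atom(r$N, r$CA, r$C, BOND_C_O, ANG_CA_C_O,
                             psi[i] - 180)
    # L-configuration C-beta stub
    res[[i]]$CB <- place_atom(r$N, r$C, r$CA, BOND_CA_CB, ANG_C_CA_CB, 122.6)
  }
  res
}

assemble_atoms <- function(bb, res3, chain, radii = vdw_radii()) {
  rows <- list()
  for (i in seq_along(bb)) {
    names_i <- c("N", "CA", "C", "O")
    if (res3[i] != "GLY") names_i <- c(names_i, "CB")
    for (nm in names_i) {
      p <- bb[[i]][[nm]]
      ele <- substr(nm, 1, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, res_index = i - 1L, resid = res3[i], atom = nm,
        element = ele, x = p[1], y = p[2], z = p[3],
        radius = unname(radii[ele]), confidence = 90,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Build an ideal antiparallel two-strand structure
#'
#' Generates one ideal strand and places a rigid, 180-degree-flipped copy
#' alongside it (chain B) at a registry chosen so that the two strands form
#' a Kabsch-Sander antiparallel hydrogen-bond ladder.  Used to exercise
#' sheet assignment without real coordinates.
#'
#' @param sequence One-letter sequence for both strands (8 residues works
#'   well; the inter-strand registry was tuned for that length).
#' @param perturbation_sd,seed Passed to the coordinate noise step as in
#'   [make_structure()].
#' @param protein_id Identifier for the structure.
#' @return A two-chain `surf_structure` (chains A and B).
#' @export
make_strand_pair <- function(sequence, perturbation_sd = 0, seed = 1,
                             protein_id = "synthetic_sheet") {
  s1 <- make_structure(sequence, geometry = "strand", perturbation_sd = 0,
                       protein_id = protein_id, chain = "A")
  a <- s1$atoms
  ca <- as.matrix(a[a$atom == "CA", c("x", "y", "z")])
  axis <- unit3(ca[nrow(ca), ] - ca[1, ])
  center <- colMeans(ca)
  perp1 <- unit3(cross3(axis, c(0, 0, 1)))
  perp2 <- cross3(axis, perp1)
  # flip about perp1 (reverses chain direction) + frozen ladder registry
  shift <- -6.0 * perp1 + -1.5 * perp2 + -0.75 * axis
  flip <- function(p) {
    v <- p - center
    2 * sum(v * perp1) * perp1 - v + center + shift
  }
  b <- a
  xyz <- t(apply(as.matrix(a[, c("x", "y", "z")]), 1, flip))
  b$x <- xyz[, 1]; b$y <- xyz[, 2]; b$z <- xyz[, 3]
  b$chain <- "B"
  atoms <- rbind(a, b)
  if (perturbation_sd > 0) {
    atoms <- with_seed(seed, {
      atoms$x <- atoms$x + rnorm(nrow(atoms), 0, perturbation_sd)
      atoms$y <- atoms$y + rnorm(nrow(atoms), 0, perturbation_sd)
      atoms$z <- atoms$z + rnorm(nrow(atoms), 0, perturbation_sd)
      atoms
    })
  }
  new_structure(protein_id, atoms)
}

#' Generate a feature table with planted threshold rules
#'
#' Emulates the statistical structure the classification protocol assumes:
#' each rule is a one-sided threshold on a feature, and a row is labelled
#' `secreted` exactly when it satisfies the conjunction of all rules (then
#' labels are flipped at `noise_rate`).  Rule features are drawn uniformly
#' on a window spanning their boundary, noise features are drawn
#' class-independently, and an optional compositional block of 20
#' amino-acid columns is sampled on the simplex and scaled to 100.
#'
#' @param n_per_class Rows per class after balancing.
#' @param rules List of rules, each `list(feature =, op = "<" or ">",
#'   boundary =)` with the boundary in percent units (0, 100).  The default
#'   plants `f1 < 9.0`, `f2 > 1.8`, `f3 > 5.8` for the secreted class.
#' @param noise_rate Label-flip probability in `[0, 0.5)`.
#' @param n_noise_features Number of uninformative uniform features.
#' @param compositional If `TRUE`, add 20 `aa_*` columns summing to 100.
#' @param rule_window Half-width of the uniform window around each rule
#'   boundary.
#' @param seed Integer seed; the generator is a pure function of spec+seed.
#' @return A data.frame with feature columns and a `class` factor with
#'   levels `cytosol`, `secreted`.  Attributes `rules` and `flipped` record
#'   the ground truth.
#' @export
#' @examples
#' tbl <- make_planted_table(n_per_class = 50, seed = 7)
#' table(tbl$class)
make_planted_table <- function(n_per_class = 400,
                               rules = list(
                                 list(feature = "f1", op = "<", boundary = 9.0),
                                 list(feature = "f2", op = ">", boundary = 1.8),
                                 list(feature = "f3", op = ">", boundary = 5.8)),
                               noise_rate = 0.05,
                               n_noise_features = 10,
                               compositional = FALSE,
                               rule_window = 5,
                               seed = 1) {
  stopifnot(n_per_class >= 1, noise_rate >= 0, noise_rate < 0.5,
            n_noise_features >= 0, rule_window > 0)
  feats <- vapply(rules, `[[`, character(1), "feature")
  ops <- vapply(rules, `[[`, character(1), "op")
  bnds <- vapply(rules, `[[`, numeric(1), "boundary")
  stopifnot(all(ops %in% c("<", ">")), all(bnds > 0), all(bnds < 100))
  # contradictory rules on the same feature leave an empty secreted region
  for (f in unique(feats)) {
    i <- feats == f
    lo <- suppressWarnings(max(bnds[i][ops[i] == ">"], -Inf))
    hi <- suppressWarnings(min(bnds[i][ops[i] == "<"], Inf))
    if (lo >= hi)
      stop("contradictory rules for feature ", f, ": empty class region")
  }

  ufeats <- unique(feats)
  with_seed(seed, {
    draw <- function(m) {
      x <- data.frame(row.names = seq_len(m))
      for (f in ufeats) {
        b <- bnds[feats == f]
        lo <- max(0, min(b) - rule_window)
        x[[f]] <- runif(m, lo, max(b) + rule_window)
      }
      sec <- rep(TRUE, m)
      for (k in seq_along(rules)) {
        v <- x[[feats[k]]]
        sec <- sec & if (ops[k] == "<") v < bnds[k] else v > bnds[k]
      }
      x$label <- ifelse(sec, "secreted", "cytosol")
      x
    }
    acc <- NULL
    while (is.null(acc) ||
           min(table(factor(acc$label, c("cytosol", "secreted")))) <
             n_per_class) {
      acc <- rbind(acc, draw(4 * n_per_class))
    }
    keep <- c(which(acc$label == "cytosol")[seq_len(n_per_class)],
              which(acc$label == "secreted")[seq_len(n_per_class)])
    acc <- acc[keep, , drop = FALSE]
    n <- nrow(acc)

    out <- acc[ufeats]
    rownames(out) <- NULL
    if (n_noise_features > 0) {
      for (k in seq_len(n_noise_features))
        out[[sprintf("noise%02d", k)]] <- runif(n, 0, 15)
    }
    if (compositional) {
      g <- matrix(rexp(n * 20), n, 20)
      g <- 100 * g / rowSums(g)
      colnames(g) <- paste0("aa_", AA3)
      out <- cbind(out, as.data.frame(g))
    }
    flip <- runif(n) < noise_rate
    lab <- acc$label
    lab[flip] <- ifelse(lab[flip] == "secreted", "cytosol", "secreted")
    out$class <- factor(lab, levels = c("cytosol", "secreted"))
    rownames(out) <- NULL
    attr(out, "rules") <- rules
    attr(out, "flipped") <- flip
    out
  })
}
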