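# Three-state secondary structure (H/E/C) from backbone geometry, using the
# Kabsch-Sander electrostatic hydrogen-bond model.

KS_Q1Q2F <- 0.084 * 332   # partial-charge product times dielectric factor
KS_CUTOFF <- -0.5         # kcal/mol; bonds must be at least this favourable
KS_CA_CUTOFF <- 9.0       # angstrom; CA-CA prefilter

# Per-residue backbone coordinate table with amide H and (reconstructed) O.
backbone_frame <- function(s) {
  rs <- residue_sequence(s)
  n <- nrow(rs)
  a <- s$atoms
  akey <- paste(a$chain, a$res_index, a$atom)
  grab <- function(i, name) {
    j <- match(paste(rs$chain[i], rs$index[i], name), akey)
    if (is.na(j)) NULL else c(a$x[j], a$y[j], a$z[j])
  }
  bb <- vector("list", n)
  for (i in seq_len(n))
    bb[[i]] <- list(N = grab(i, "N"), CA = grab(i, "CA"), C = grab(i, "C"),
                    O = grab(i, "O"))
  same_chain <- function(i, j) !is.na(j) && j >= 1 && j <= n &&
    rs$chain[i] == rs$chain[j]
  # reconstruct missing carbonyl O in the peptide plane
  for (i in seq_len(n)) {
    if (!is.null(bb[[i]]$O)) next
    r <- bb[[i]]
    if (same_chain(i, i + 1) && !is.null(bb[[i + 1]]$N)) {
      dir <- unit3(unit3(r$C - r$CA) + unit3(r$C - bb[[i + 1]]$N))
    } else {
      dir <- unit3(r$C - r$CA)
    }
    bb[[i]]$O <- r$C + 1.231 * dir
  }
  # amide H along the previous peptide C=O direction (none for chain starts
  # and prolines)
  for (i in seq_len(n)) {
    if (!same_chain(i, i - 1) || rs$resid[i] == "PRO") next
    p <- bb[[i - 1]]
    bb[[i]]$H <- bb[[i]]$N + unit3(p$C - p$O)
  }
  list(rs = rs, bb = bb)
}

ks_bond_energy <- function(acceptor, donor) {
  if (is.null(donor$H)) return(Inf)
  d <- function(p, q) sqrt(sum((p - q)^2))
  KS_Q1Q2F * (1 / d(acceptor$O, donor$N) + 1 / d(acceptor$C, donor$H) -
                1 / d(acceptor$O, donor$H) - 1 / d(acceptor$C, donor$N))
}

# hb[x, y]: the carbonyl of residue x accepts a hydrogen bond from the
# amide of residue y.
hbond_matrix <- function(frame) {
  rs <- frame$rs; bb <- frame$bb
  n <- nrow(rs)
  ca <- t(vapply(bb, function(r) r$CA, numeric(3)))
  hb <- matrix(FALSE, n, n)
  for (x in seq_len(n)) for (y in seq_len(n)) {
    if (x == y) next
    if (rs$chain[x] == rs$chain[y] && abs(x - y) < 2) next  # peptide-bonded
    if (sum((ca[x, ] - ca[y, ])^2) > KS_CA_CUTOFF^2) next
    if (ks_bond_energy(bb[[x]], bb[[y]]) < KS_CUTOFF) hb[x, y] <- TRUE
  }
  hb
}

#' Assign three-state secondary structure
#'
#' Labels each residue H (alpha helix), E (extended strand) or C (coil)
#' from backbone hydrogen bonds under the Kabsch-Sander electrostatic
#' energy model (cutoff -0.5 kcal/mol).  A residue stretch becomes H when
#' two consecutive i -> i+4 turns are bonded; strands are built from
#' parallel/antiparallel bridge ladders, requiring at least two consecutive
#' bridge residues.  Missing carbonyl oxygens are reconstructed from the
#' N/CA/C geometry; chains shorter than three residues are all C.
#'
#' @param s A `surf_structure`.
#' @return Character vector of labels in `residue_sequence(s)` order,
#'   named `"chain:index"`.
#' @export
#' @examples
#' helix <- make_structure(strrep("A", 15), geometry = "helix")
#' assign_ss(helix)
assign_ss <- function(s) {
  stopifnot(inherits(s, "surf_structure"))
  frame <- backbone_frame(s)
  rs <- frame$rs
  n <- nrow(rs)
  lab <- rep("C", n)
  names(lab) <- paste(rs$chain, rs$index, sep = ":")
  if (n < 3) return(lab)
  hb <- hbond_matrix(frame)
  same_chain <- function(i, j) all(j >= 1) && all(j <= n) &&
    all(rs$chain[i] == rs$chain[j])

  # alpha helix: two consecutive i -> i+4 turns label i+1 .. i+4
  turn <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (same_chain(i, i + 4) && hb[i, i + 4]) turn[i] <- TRUE
  }
  for (i in seq_len(n - 1)) {
    if (turn[i] && turn[i + 1] && same_chain(i, i + 5))
      lab[(i + 1):(i + 4)] <- "H"
  }

  # beta bridges (Kabsch-Sander parallel and antiparallel patterns)
  bridge <- rep(FALSE, n)
  interior <- function(i) same_chain(i, c(i - 1, i + 1))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    if (rs$chain[a] == rs$chain[b] && abs(a - b) < 3) next
    if (!interior(a) || !interior(b)) next
    para <- (hb[a - 1, b] && hb[b, a + 1]) || (hb[b - 1, a] && hb[a, b + 1])
    anti <- (hb[a, b] && hb[b, a]) || (hb[a - 1, b + 1] && hb[b - 1, a + 1])
    if (para || anti) bridge[a] <- TRUE
  }
  eligible <- bridge & lab != "H"
  # ladders: at least two consecutive bridge residues in the same chain
  for (i in seq_len(n)) {
    if (!eligible[i]) next
    prev_ok <- i > 1 && eligible[i - 1] && rs$chain[i - 1] == rs$chain[i]
    next_ok <- i < n && eligible[i + 1] && rs$chain[i + 1] == rs$chain[i]
    if (prev_ok || next_ok) lab[i] <- "E"
  }
  lab
}

#' Secondary-structure composition
#'
#' Percentages of H, E and C labels over all residues, or over a masked
#' subset (e.g. surface residues only).
#'
#' @param labels Output of [assign_ss()].
#' @param mask Optional logical vector of the same length; only `TRUE`
#'   residues are counted.
#' @return Named numeric vector `c(H =, E =, C =)` in percent, summing
#'   to 100.
#' @export
ss_composition <- function(labels, mask = NULL) {
  stopifnot(is.character(labels), all(labels %in% c("H", "E", "C")))
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), length(mask) == length(labels))
    labels <- labels[mask]
  }
  if (length(labels) == 0L)
    stop("undefined composition: mask selects no residues", call. = FALSE)
  100 * c(H = mean(labels == "H"),
          E = mean(labels == "E"),
          C = mean(labels == "C"))
}
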