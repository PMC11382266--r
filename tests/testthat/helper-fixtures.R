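# Fixtures built in code and independent oracles used across the suite.

# Minimal one-residue glycine PDB text (N, CA, C, O).
gly_pdb_lines <- function() {
  c("ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00 90.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00 90.00           C",
    "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00 90.00           C",
    "ATOM      4  O   GLY A   1       1.251   2.390   0.000  1.00 90.00           O",
    "END")
}

# The same model as a minimal mmCIF atom_site loop.
gly_cif_lines <- function() {
  c("data_test", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . GLY A 1 1 ? 0.000 0.000 0.000 1.00 90.00 1 GLY A N 1",
    "ATOM 2 C CA . GLY A 1 1 ? 1.458 0.000 0.000 1.00 90.00 1 GLY A CA 1",
    "ATOM 3 C C . GLY A 1 1 ? 2.009 1.420 0.000 1.00 90.00 1 GLY A C 1",
    "ATOM 4 O O . GLY A 1 1 ? 1.251 2.390 0.000 1.00 90.00 1 GLY A O 1")
}

write_fixture <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Bare structure from an atom table; used for single-atom / two-atom
# geometric fixtures.
atoms_structure <- function(xyz, elements, radii = surfclass::vdw_radii()) {
  n <- nrow(xyz)
  atoms <- data.frame(chain = "A", res_index = 0L, resid = "GLY",
                      atom = paste0(elements, seq_len(n)),
                      element = elements,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      radius = unname(radii[elements]), confidence = 0,
                      stringsAsFactors = FALSE)
  structure(list(protein_id = "fixture", atoms = atoms),
            class = "surf_structure")
}

# Closed-form accessible area of sphere 1 (radius R1, probe-extended) partly
# occluded by sphere 2 at centre distance d: full area minus the buried
# spherical cap.
two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h
}

# Deletion oracle for the tripeptide-context maximum SASA: physically
# rebuild a structure containing only the residue and its in-chain
# neighbours (indices re-based so it passes full validation), run the
# standard full-structure SASA path, and sum the central residue.
deletion_max_sasa <- function(s, chain, index, params) {
  a <- s$atoms
  keep <- a$chain == chain & a$res_index %in% (index + (-1:1))
  at <- a[keep, , drop = FALSE]
  old <- sort(unique(at$res_index))
  at$res_index <- match(at$res_index, old) - 1L
  rownames(at) <- NULL
  red <- surfclass:::new_structure("oracle", at)
  per_res <- surfclass:::residue_sasa(red, params)
  unname(per_res[paste(chain, match(index, old) - 1L)])
}

# Independent Kabsch-Sander bond-energy calculator for SS oracles.
oracle_hbond_energy <- function(acc_C, acc_O, don_N, don_H) {
  d <- function(p, q) sqrt(sum((p - q)^2))
  0.084 * 332 * (1 / d(acc_O, don_N) + 1 / d(acc_C, don_H) -
                   1 / d(acc_O, don_H) - 1 / d(acc_C, don_N))
}

# Backbone atom lookup: coordinates of `name` in residue (chain, index).
bb_atom <- function(s, chain, index, name) {
  a <- s$atoms
  i <- which(a$chain == chain & a$res_index == index & a$atom == name)
  if (!length(i)) return(NULL)
  c(a$x[i], a$y[i], a$z[i])
}

# Rigid-body transform of a structure (rotation about z + translation).
transform_structure <- function(s, angle = 0.7, shift = c(5, -3, 2)) {
  R <- matrix(c(cos(angle), sin(angle), 0,
                -sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% R
  s$atoms$x <- xyz[, 1] + shift[1]
  s$atoms$y <- xyz[, 2] + shift[2]
  s$atoms$z <- xyz[, 3] + shift[3]
  s
}

# Small linearly separable two-feature table.
separable_table <- function(n = 40, seed = 1) {
  set.seed(seed)
  x1 <- c(runif(n / 2, 0, 4), runif(n / 2, 6, 10))
  tbl <- data.frame(f1 = x1, f2 = runif(n, 0, 10))
  tbl$class <- factor(rep(c("cytosol", "secreted"), each = n / 2))
  tbl
}
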