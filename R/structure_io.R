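# Structure model: heavy-atom coordinates with per-residue organisation.
#
# A `surf_structure` is a list with
#   protein_id : character scalar
#   atoms      : data.frame(chain, res_index, resid, atom, element,
#                           x, y, z, radius, confidence)
# res_index is 0-based and consecutive within each chain, in file order.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")
names(AA3) <- AA1

#' Default van der Waals radii for heavy atoms
#'
#' Radii (in angstrom) assigned to atoms at load time and used by the
#' Shrake-Rupley solvent-accessible surface area computation.  The default
#' set covers the elements found in standard amino acids (C 1.70, N 1.55,
#' O 1.52, S 1.80), plus selenium for mapped selenomethionine.
#'
#' @return Named numeric vector of radii in angstrom.
#' @export
#' @examples
#' vdw_radii()
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, SE = 1.90)
}

new_structure <- function(protein_id, atoms) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L,
            is.data.frame(atoms))
  need <- c("chain", "res_index", "resid", "atom", "element",
            "x", "y", "z", "radius", "confidence")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  s <- structure(list(protein_id = protein_id,
                      atoms = atoms[need]),
                 class = "surf_structure")
  validate_structure(s)
}

validate_structure <- function(s) {
  a <- s$atoms
  if (nrow(a) == 0L)
    stop("empty structure: no standard-residue heavy atoms", call. = FALSE)
  if (!all(is.finite(c(a$x, a$y, a$z))))
    stop("non-finite atom coordinates", call. = FALSE)
  if (any(!is.finite(a$radius)) || any(a$radius <= 0))
    stop("all atoms must carry a positive van der Waals radius", call. = FALSE)
  bad <- setdiff(unique(a$resid), AA3)
  if (length(bad))
    stop("nonstandard residue code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  # consecutive 0-based indices within each chain
  for (ch in unique(a$chain)) {
    idx <- unique(a$res_index[a$chain == ch])
    if (!identical(as.integer(idx), seq_along(idx) - 1L))
      stop("residue indices not consecutive within chain ", ch, call. = FALSE)
  }
  s
}

#' @export
print.surf_structure <- function(x, ...) {
  rs <- residue_sequence(x)
  cat("<surf_structure> ", x$protein_id, "\n",
      "  chains:   ", paste(unique(rs$chain), collapse = ", "), "\n",
      "  residues: ", nrow(rs), "\n",
      "  atoms:    ", nrow(x$atoms), "\n", sep = "")
  invisible(x)
}

element_from_name <- function(atom_name) {
  nm <- gsub("^[0-9 ]+", "", atom_name)
  two <- toupper(substr(nm, 1, 2))
  ifelse(two == "SE", "SE", toupper(substr(nm, 1, 1)))
}

#' Read a protein structure from PDB or mmCIF
#'
#' Parses a structure file into a validated heavy-atom model.  Hydrogens
#' are dropped, alternate locations are resolved to the highest occupancy,
#' waters and other heteroatoms are excluded, and only the first model of
#' a multi-model file is kept.  Every atom is assigned a van der Waals
#' radius from `radii`; the B-factor column is retained as a per-atom
#' confidence score (pLDDT in AlphaFold models).
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param format `"auto"` (by file extension), `"pdb"` or `"mmcif"`.
#' @param radii Named vector of van der Waals radii in angstrom, by element.
#' @param nonstandard How to treat non-standard residues not covered by
#'   `residue_map`: `"error"` (default) or `"drop"`.
#' @param residue_map Named character vector mapping non-standard residue
#'   codes to standard ones, e.g. `c(MSE = "MET")`.
#' @param min_confidence Optional minimum mean per-residue confidence
#'   (e.g. pLDDT); residues below it are dropped.  Default `NULL` keeps all
#'   residues.
#' @param protein_id Identifier stored on the structure; defaults to the
#'   file name without extension.
#' @return A `surf_structure`.
#' @seealso [residue_sequence()], [surface_profile()]
#' @export
read_structure <- function(path,
                           format = c("auto", "pdb", "mmcif"),
                           radii = vdw_radii(),
                           nonstandard = c("error", "drop"),
                           residue_map = c(MSE = "MET"),
                           min_confidence = NULL,
                           protein_id = NULL) {
  format <- match.arg(format)
  nonstandard <- match.arg(nonstandard)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "pdb") bio3d::read.pdb(path, multi = FALSE,
                                           rm.alt = FALSE, verbose = FALSE)
      else bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                           verbose = FALSE)),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  at <- at[at$type == "ATOM", , drop = FALSE]

  # element symbol: prefer the file's element column, fall back to atom name
  ele <- toupper(trimws(at$elesy %||% ""))
  miss <- is.na(ele) | ele == ""
  ele[miss] <- element_from_name(at$elety[miss])
  at$element <- ele
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]

  # map/reject nonstandard residues
  at$resid <- toupper(trimws(at$resid))
  mapped <- at$resid %in% names(residue_map)
  at$resid[mapped] <- unname(residue_map[at$resid[mapped]])
  nonstd <- setdiff(unique(at$resid), AA3)
  if (length(nonstd)) {
    if (nonstandard == "error")
      stop("nonstandard residue code(s): ", paste(nonstd, collapse = ", "),
           "; map them via residue_map or use nonstandard = \"drop\"",
           call. = FALSE)
    at <- at[at$resid %in% AA3, , drop = FALSE]
  }
  if (nrow(at) == 0L)
    stop("empty structure: no standard-residue heavy atoms in ", path,
         call. = FALSE)

  # altloc: keep blank altloc, otherwise the highest-occupancy copy per atom
  alt <- trimws(at$alt %||% "")
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, at$insert %||% "", at$elety)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[alt != ""])) {
      rows <- which(key == k)
      if (length(rows) > 1L) {
        best <- rows[which.max(occ[rows])]
        keep[setdiff(rows, best)] <- FALSE
      }
    }
    at <- at[keep, , drop = FALSE]
  }

  unknown <- setdiff(unique(at$element), names(radii))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  rkey <- paste(chain, at$resno, at$insert %||% "")
  # file-order residue numbering, 0-based within chain
  res_index <- integer(nrow(at))
  for (ch in unique(chain)) {
    sel <- chain == ch
    u <- unique(rkey[sel])
    res_index[sel] <- match(rkey[sel], u) - 1L
  }

  atoms <- data.frame(chain = chain,
                      res_index = res_index,
                      resid = at$resid,
                      atom = trimws(at$elety),
                      element = at$element,
                      x = at$x, y = at$y, z = at$z,
                      radius = unname(radii[at$element]),
                      confidence = at$b,
                      stringsAsFactors = FALSE)

  # residues must carry an intact N, CA, C backbone
  key <- paste(atoms$chain, atoms$res_index)
  ok <- vapply(split(atoms$atom, key),
               function(a) all(c("N", "CA", "C") %in% a), logical(1))
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " residue(s) with incomplete backbone")
    atoms <- atoms[ok[key], , drop = FALSE]
  }
  if (!is.null(min_confidence)) {
    key <- paste(atoms$chain, atoms$res_index)
    m <- tapply(atoms$confidence, key, mean)
    atoms <- atoms[m[key] >= min_confidence, , drop = FALSE]
  }
  if (nrow(atoms) == 0L)
    stop("empty structure: no residues left after filtering ", path,
         call. = FALSE)
  # re-index after any residue drops
  key <- paste(atoms$chain, atoms$res_index)
  for (ch in unique(atoms$chain)) {
    sel <- atoms$chain == ch
    u <- unique(key[sel])
    atoms$res_index[sel] <- match(key[sel], u) - 1L
  }
  rownames(atoms) <- NULL

  if (is.null(protein_id))
    protein_id <- sub("\\.(pdb|cif|ent)$", "", basename(path),
                      ignore.case = TRUE)
  new_structure(protein_id, atoms)
}

#' Residue sequence of a structure
#'
#' @param s A `surf_structure`.
#' @return A data.frame with one row per residue, in file order: `chain`,
#'   `index` (0-based within chain) and `resid` (three-letter code).
#' @export
residue_sequence <- function(s) {
  stopifnot(inherits(s, "surf_structure"))
  a <- s$atoms
  key <- paste(a$chain, a$res_index)
  first <- !duplicated(key)
  data.frame(chain = a$chain[first],
             index = a$res_index[first],
             resid = a$resid[first],
             stringsAsFactors = FALSE)
}

#' Write a structure as a minimal PDB file
#'
#' Emits plain `ATOM` records (plus `TER`/`END`); intended for fixtures and
#' round-trip checks, not as a general-purpose PDB writer.
#'
#' @param s A `surf_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "surf_structure"))
  a <- s$atoms
  lines <- character(0)
  serial <- 0L
  for (ch in unique(a$chain)) {
    sel <- which(a$chain == ch)
    for (i in sel) {
      serial <- serial + 1L
      nm <- a$atom[i]
      # PDB alignment: 1-char element names start in column 14
      nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, nm_fmt, a$resid[i], substr(ch, 1, 1),
        (a$res_index[i] + 1L) %% 10000L, a$x[i], a$y[i], a$z[i], 1,
        ifelse(is.na(a$confidence[i]), 0, a$confidence[i]), a$element[i]))
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
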