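# Shrake-Rupley solvent-accessible surface area and the tripeptide-context
# relative SASA used to call surface residues.

#' SASA parameters
#'
#' @param probe_radius Probe sphere radius in angstrom; 1.4 corresponds to a
#'   water molecule.
#' @param n_sphere_points Number of quadrature points per atom on the
#'   deterministic golden-spiral sphere.
#' @param rel_cutoff Relative-SASA cutoff at or above which a residue is
#'   called a surface residue (inclusive).
#' @return A list of class `sasa_params`.
#' @export
#' @examples
#' sasa_params()
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960,
                        rel_cutoff = 0.30) {
  stopifnot(probe_radius > 0,
            n_sphere_points >= 60,
            rel_cutoff > 0, rel_cutoff < 1)
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 rel_cutoff = rel_cutoff),
            class = "sasa_params")
}

# Deterministic, near-uniform unit sphere point set (golden spiral).
golden_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Express coordinates in a canonical principal-axes frame (centred,
# eigenvectors of the coordinate covariance with a fixed sign convention).
# Quadrature then depends only on the internal geometry, so areas are
# invariant under rigid-body placement of the input.
canonical_frame <- function(xyz) {
  n <- nrow(xyz)
  if (n < 2) return(xyz)
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(xc) / n, symmetric = TRUE)$vectors
  proj <- xc %*% ev
  # intrinsic sign fix: orient each axis along the first atom (in file
  # order) with a non-negligible projection on it
  for (j in 1:3) {
    k <- which(abs(proj[, j]) > 1e-8)
    if (length(k) && proj[k[1], j] < 0) proj[, j] <- -proj[, j]
  }
  proj
}

#' Per-atom solvent-accessible surface area
#'
#' Shrake-Rupley quadrature: each atom's sphere is expanded by the probe
#' radius and sampled with a deterministic golden-spiral point set; the
#' accessible area is the fraction of points not buried inside any other
#' expanded sphere, times the expanded sphere's area.  Coordinates are
#' first expressed in a canonical principal-axes frame, so areas depend
#' only on the molecule's internal geometry, not on its placement in the
#' file: rigid-body translations and rotations of the input leave every
#' area unchanged.
#'
#' @param s A `surf_structure`.
#' @param params A [sasa_params()] object.
#' @return Numeric vector of per-atom areas in square angstrom, in the
#'   order of `s$atoms`.
#' @export
atom_sasa <- function(s, params = sasa_params()) {
  stopifnot(inherits(s, "surf_structure"), inherits(params, "sasa_params"))
  a <- s$atoms
  xyz <- canonical_frame(cbind(a$x, a$y, a$z))
  sasa_quadrature(xyz, a$radius + params$probe_radius,
                  params$n_sphere_points)
}

# Occlusion core on fixed coordinates: for identical xyz, removing an atom
# can only free quadrature points, so areas are exactly monotone under
# deletion.
sasa_quadrature <- function(xyz, rext, n_sphere_points) {
  n <- nrow(xyz)
  pts <- golden_sphere(n_sphere_points)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rext[i] + rext)^2 & seq_len(n) != i)
    if (length(nb) && any(d2[nb] == 0))
      stop("degenerate geometry: distinct atoms at identical coordinates",
           call. = FALSE)
    if (!length(nb)) {
      areas[i] <- 4 * pi * rext[i]^2
      next
    }
    sp <- pts * rext[i]
    sp <- sweep(sp, 2, xyz[i, ], "+")
    free <- rep(TRUE, nrow(sp))
    # nearest occluders first prunes fastest
    for (j in nb[order(d2[nb])]) {
      if (!any(free)) break
      idx <- which(free)
      dj2 <- (sp[idx, 1] - xyz[j, 1])^2 + (sp[idx, 2] - xyz[j, 2])^2 +
        (sp[idx, 3] - xyz[j, 3])^2
      free[idx[dj2 < rext[j]^2]] <- FALSE
    }
    areas[i] <- 4 * pi * rext[i]^2 * mean(free)
  }
  areas
}

# Sum per-atom areas into per-residue areas (file order).
residue_sasa <- function(s, params = sasa_params()) {
  a <- s$atoms
  key <- paste(a$chain, a$res_index)
  areas <- atom_sasa(s, params)
  out <- rowsum(areas, factor(key, levels = unique(key)))
  setNames(as.numeric(out), rownames(out))
}

subset_structure <- function(s, chain, indices) {
  keep <- s$atoms$chain == chain & s$atoms$res_index %in% indices
  atoms <- s$atoms[keep, , drop = FALSE]
  # keep original indices; bypass the consecutive-index validator on purpose
  structure(list(protein_id = s$protein_id, atoms = atoms),
            class = "surf_structure")
}

#' Maximum (tripeptide-context) SASA of a residue
#'
#' The reference exposure against which relative SASA is defined: the SASA
#' of the residue recomputed in a reduced structure containing only the
#' residue and its two sequence neighbours (index +/- 1 in the same chain),
#' all atoms kept at their original coordinates.  Terminal residues keep
#' their single neighbour.
#'
#' @param s A `surf_structure`.
#' @param chain Chain identifier.
#' @param index 0-based residue index within the chain.
#' @param params A [sasa_params()] object.
#' @return The residue's maximum SASA in square angstrom.
#' @export
max_sasa <- function(s, chain, index, params = sasa_params()) {
  stopifnot(inherits(s, "surf_structure"))
  rs <- residue_sequence(s)
  if (!any(rs$chain == chain & rs$index == index))
    stop("no residue ", index, " in chain ", chain)
  red <- subset_structure(s, chain, c(index - 1L, index, index + 1L))
  key <- paste(red$atoms$chain, red$atoms$res_index)
  areas <- atom_sasa(red, params)
  sum(areas[key == paste(chain, index)])
}

#' Surface profile: absolute, maximum and relative SASA per residue
#'
#' Computes per-residue absolute SASA in the full structure, the
#' tripeptide-context maximum SASA, their ratio (relative SASA), and the
#' surface flag `rel_sasa >= rel_cutoff` (inclusive).
#'
#' @param s A `surf_structure`.
#' @param params A [sasa_params()] object.
#' @return A data.frame of class `surface_profile` with one row per
#'   residue: `chain`, `index`, `resid`, `abs_sasa`, `max_sasa`,
#'   `rel_sasa`, `is_surface`.
#' @export
#' @examples
#' s <- make_structure("AEKLG", geometry = "helix")
#' surface_profile(s, sasa_params(n_sphere_points = 240))
surface_profile <- function(s, params = sasa_params()) {
  stopifnot(inherits(s, "surf_structure"))
  rs <- residue_sequence(s)
  abs_s <- residue_sasa(s, params)
  key <- paste(rs$chain, rs$index)
  max_s <- vapply(seq_len(nrow(rs)), function(i)
    max_sasa(s, rs$chain[i], rs$index[i], params), numeric(1))
  if (any(max_s <= 0))
    stop("degenerate geometry: zero maximum SASA for residue(s) ",
         paste(key[max_s <= 0], collapse = ", "), call. = FALSE)
  rel <- as.numeric(abs_s[key]) / max_s
  out <- data.frame(chain = rs$chain,
                    index = rs$index,
                    resid = rs$resid,
                    abs_sasa = as.numeric(abs_s[key]),
                    max_sasa = max_s,
                    rel_sasa = rel,
                    is_surface = rel >= params$rel_cutoff,
                    stringsAsFactors = FALSE)
  attr(out, "params") <- params
  class(out) <- c("surface_profile", "data.frame")
  out
}
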