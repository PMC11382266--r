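# internal geometry and seeding helpers

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) v / sqrt(sum(v^2))

# Natural-extension (NeRF) placement: position atom d so that |c-d| = bond,
# angle(b,c,d) = angle and torsion(a,b,c,d) = torsion (degrees, right-handed).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit3(c - b)
  ab <- b - a
  n <- ab - sum(ab * bc) * bc
  n <- unit3(n)
  m <- cross3(bc, n)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * (-n) + d2[3] * m
}

dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Deterministic derived seeds: one base seed expands to independent
# sub-stream seeds, all kept below 2^31 - 1.
derive_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(index) * 16807 + 1
  as.integer(s %% 2147483647)
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
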