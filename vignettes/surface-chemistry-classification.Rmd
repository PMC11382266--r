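---
title: "Classifying secreted and cytosolic proteins from surface chemistry"
author: "surfclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying secreted and cytosolic proteins from surface chemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfclass)
```

## The problem and the model

Extracellular (secreted) and intracellular (cytosolic) proteins operate in
chemically distinct fluids: different electrostatic potential, different
crowding, different membrane contact. Those pressures act on the protein
*surface*, so a classifier built on surface descriptors — rather than on
the full sequence — can both predict a protein's compartment and expose
which surface properties carry the signal.

`surfclass` implements that analysis as four stages:

1. surface-residue extraction by tripeptide-normalised relative SASA,
2. compositional surface descriptors,
3. a class-balanced repeated-split random-forest protocol,
4. decision-path interpretation yielding per-feature boundary values.

This vignette records the modelling choices, tunable parameters, and the
limits of what the shipped synthetic data can demonstrate.

## Stage 1: relative SASA and the surface mask

Solvent-accessible surface area is computed by Shrake–Rupley quadrature:
each atom's van der Waals sphere (default radii C 1.70, N 1.55, O 1.52,
S 1.80 Å, configurable) is inflated by the probe radius (default 1.4 Å, a
water molecule) and sampled with a deterministic golden-spiral point set
(default 960 points/atom); points inside any neighbouring inflated sphere
are occluded.

The *maximum* SASA of residue *i* is its SASA recomputed in a reduced
structure holding only residues *i −1, i, i+1* of the same chain at their
original coordinates — an in-place excision, not an idealised extended
tripeptide, so the normalisation reflects the local backbone geometry the
residue actually has. Terminal residues keep their single neighbour.
Relative SASA is the ratio, and residues with relative SASA **≥ 0.3**
(inclusive) are surface residues.

Numerical choices worth knowing:

* **Canonical frame.** Quadrature points are fixed in space, so a naive
  implementation gives slightly different areas when the same molecule is
  rotated in the file. `surfclass` first moves coordinates into a
  canonical principal-axes frame (eigenvectors of the coordinate
  covariance, signs fixed by the first atom's projections), which makes
  every area an exact function of internal geometry: rigid-body
  transforms change nothing, to machine precision.
* **Quadrature error.** At the 960-point default, per-residue areas carry
  ~1–2% quadrature error; halving stops mattering (<0.5% per doubling)
  around 8 000 points/atom. The default is kept at 960 because the
  surface decision is a threshold at 0.3 on a ratio of two areas with
  correlated errors — in practice the mask is insensitive to the
  quadrature level, while SASA cost dominates feature extraction.
* **Consequences of the two frames.** Absolute SASA is computed in the
  full structure's frame and maximum SASA in the reduced structure's
  frame, so relative SASA can exceed 1 by quadrature noise (the package
  tolerates 1 + ε; a residue whose context *is* the whole structure gets
  exactly 1). Likewise, deleting an atom re-canonicalises the frame, so
  SASA monotonicity under deletion holds exactly at fixed coordinates
  (the occlusion core is monotone by construction) but only to quadrature
  tolerance across the public API.
* **Degenerate input.** Two distinct atoms at identical coordinates are
  rejected; a residue with zero maximum SASA would be rejected too
  (geometrically impossible with sane radii).

## Stage 2: descriptors

All descriptors are percentages. The default registry has 34 entries: the
20 surface amino-acid compositions (summing to 100 by construction), five
surface residue-class compositions — positive (Arg, His, Lys), negative
(Asp, Glu), polar uncharged (Ser, Thr, Asn, Gln), hydrophobic (Ala, Ile,
Leu, Met, Phe, Trp, Tyr, Val) and hydrophilic (the union of the first
three, so hydrophilic = positive + negative + polar-uncharged holds
identically) — surface and overall helix and sheet compositions, the
surface-residue ratio, and four functional-group compositions (amide:
Asn/Gln; hydroxyl: Ser/Thr/Tyr; carboxyl: Asp/Glu; thiol: Cys). Gly, Pro
and Cys belong to none of the four residue classes, so class percentages
need not total 100. This registry is a documented reconstruction of the
descriptor families the analysis calls for (compositions, functional
groups, secondary structure, surface ratio); it is deliberately
config-shaped rather than a claim that these exact 34 columns are the
only reasonable set.

Secondary structure is assigned by a three-state Kabsch–Sander-style
procedure authored in the package: backbone amide hydrogens are placed
along the previous peptide's C=O direction, carbonyl oxygens are
reconstructed from N/CA/C geometry when missing, and a hydrogen bond is
an electrostatic energy below −0.5 kcal/mol. Two consecutive i → i+4
turns label residues i+1…i+4 as helix; parallel/antiparallel bridge
ladders (two or more consecutive bridge residues) label strands;
everything else is coil. Only the canonical α-pattern maps to H — 3₁₀/π
variants fall to coil — because the downstream descriptors only ever use
α-helix and β-sheet ratios; the mapping is isolated in `assign_ss()` and
swappable. On an ideal 15-residue poly-Ala helix this convention labels
residues 2–14 H (13 of 15); helix extent near termini is
convention-dependent, and the tests freeze this package's convention
against a direct H-bond-energy enumeration.

Correlation pruning removes, for every pair with |Pearson r| strictly
above 0.85 (processed in descending |r|, ties broken by name), the member
with the larger cumulative |r| against all other features. A pair at
exactly 0.85 survives. Zero-variance columns are removed first with a
warning, since their correlation is undefined. Group comparisons
(`group_report()`) use the Mann–Whitney U test — the comparison
distributions are visibly non-normal compositions, so a rank test is the
defensible default; the test's name is recorded in the output.

## Stage 3: the training protocol

Each iteration draws a class-balanced split: `round(0.7 · n)` training
rows, half per class, sampled without replacement from independent
per-class seeded streams (so e.g. 708 rows give 248 + 248 training and
212 test rows). On each split a probability random forest is fitted with
the four properties that motivate the model family: fully grown trees,
bootstrap resampling, √p random feature candidates per split, and
probability (vote) aggregation. Defaults beyond those properties — 500
trees, `mtry = floor(sqrt(p))`, minimum node size 1 — are exposed as
arguments. The protocol runs 150 iterations by default, records one
derived seed per iteration, selects the *best* model by test accuracy,
and averages normalised Gini importances over the top-7 runs.

Features with averaged importance strictly below 2% can be dropped
(`prune_by_importance()`, which always retains at least two features).
A caveat the synthetic experiments make explicit: raw Gini importance of
*completely uninformative* features does not go to zero on fully grown
trees. With 13 features and `mtry = 3`, about 42% of splits see no
informative candidate at all, and deep trees chase label noise; uniform
noise features then stabilise around 2.5–3% importance — *above* the 2%
floor. The floor therefore separates weak real descriptors from dominant
ones, but cannot be relied on to delete pure noise under these
conditions; the acceptance suite asserts the idealised behaviour and
documents its failure rather than silently tuning `mtry` or the tree
depth away from the stated model family.

`compare_algorithms()` reruns the same splits for logistic regression,
k-NN, an RBF support-vector machine and a single-hidden-layer neural
network (all standardised by training mean/SD; the forest sees raw
percentages) and returns per-algorithm accuracy samples and densities.

## Stage 4: interpretation

`decompose()` implements decision-path contribution attribution: every
node of every tree carries the in-bag training class distribution; a
sample walking root → leaf credits each split with the change in the
node's cytosol probability; contributions are averaged over trees and the
mean root probability is the bias. Conservation — bias + Σ contributions
= predicted probability — holds to machine precision by construction,
and is asserted at 1e-9 in the tests. Positive contributions point
toward the cytosol class (the orientation of contribution-vs-value
plots); Table-style output for the secreted class flips the sign.

`extract_threshold()` replaces reading a vertical line off a plot by an
explicit estimator: the boundary is the 1-D stump on the *sign* of the
contribution that maximises the fraction of samples whose sign matches
their side, reported as the midpoint of the two straddling values,
rounded to 0.1; the direction is the side whose mean contribution points
toward secreted, and the separation score (0.5–1) reports the achieved
sign purity. Features whose contributions never change sign yield a
warning and no boundary — they do not discriminate. At least 10 samples
with nonzero contributions are required.

## The synthetic data, and what the tests do and do not show

`make_structure()` builds polypeptides from ideal bond lengths/angles
with geometry-specific dihedrals (helix −57/−47, strand −139/+135,
extended 180/180, coil randomised) and Cβ stubs (full rotamers are out of
scope; burial and sequence identity, which the descriptors consume, are
captured). `make_strand_pair()` places a flipped copy of an ideal strand
at a registry where a genuine antiparallel hydrogen-bond ladder forms.
`make_planted_table()` generates feature tables whose labels follow a
known conjunction of one-sided thresholds — by default f1 < 9.0 ∧
f2 > 1.8 ∧ f3 > 5.8 for secreted, the structure of the boundary-value
analysis — with uniform windows (half-width 5 percentage points) around
each boundary, a 5% label-flip rate, 10 uninformative features, and
optionally a 20-column simplex block mimicking compositional closure.

Default generator conditions (n = 400 per class, 5% noise, 10 noise
features) are the study conditions for all recovery experiments. At
desk scale the protocol runs 8–20 iterations with 100–300 trees in the
tests and acceptance script; these sizes were chosen as the smallest at
which the protocol's averages stabilise, and all seeds derive from a
single master seed.

What passing tests demonstrate: the estimator machinery recovers planted
structure — rankings, directions, boundaries to ±0.5 percentage points —
under compositional, noisy conditions, and every numerical identity
(conservation, closure, pruning invariants) holds. What they cannot
demonstrate: performance on real proteomes. Real AlphaFold models bring
correlated descriptors, class imbalance, disordered low-confidence
regions (an optional `min_confidence` filter exists but defaults to off,
since the analysis itself states no such filter) and label noise that is
not independent Bernoulli. The published headline numbers for the real
708-protein dataset are therefore out of reach of this repository by
design; the package reproduces the *method*, and its acceptance suite
reproduces the method's internal arithmetic and recovery behaviour.

## Known limitations

* Quadrature SASA only; no analytic areas. Errors ~1% at the default
  point count, exactly rotation-invariant but only ε-monotone across the
  public API (see Stage 1).
* Secondary structure is 3-state and α-only for H; no 3₁₀/π, no
  torsion-based fallback beyond carbonyl-O reconstruction.
* The boundary estimator assumes an axis-aligned, single-threshold
  signal; genuinely interacting features produce a low separation score
  rather than a meaningful boundary.
* `both`-labelled proteins pass through the feature stage but the
  classifier protocol is strictly binary.
* NMR multi-model files: first model only; cross-chain sequence
  neighbours are never used for the tripeptide context.
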