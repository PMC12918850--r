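---
title: "Comparing amyloid filament folds and fitting fibrillization kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing amyloid filament folds and fitting fibrillization kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filamentr)
```

## The problem

Amyloid filaments — tau filaments among them — are stacks of identically
folded protein monomers ("rungs") spaced ~4.8 Å along a helical axis.
Different diseases, and different mutations, are associated with distinct
protofilament folds of the same protein, and a recurring analysis task is
to ask *where* two folds agree: two folds can be globally dissimilar yet
share a motif (a hairpin, a steric-zipper strand pair) whose internal
geometry is conserved even though its orientation relative to the rest of
the fold has rotated.

A single global superposition cannot see this. `filamentr` therefore
compares two folds by computing the backbone RMSD over **every contiguous
window** of aligned residues, with an **independent optimal superposition
per window**. A window containing a conserved motif scores low no matter
how the motif is oriented globally; the mean over all windows (the
*localized RMSD*) summarises overall similarity, and the full
(start × length) matrix renders as a triangular heat-map in which
conserved regions appear as low-RMSD patches.

## Residue correspondences

All tau filament depositions share the canonical numbering of the longest
(2N4R, 441-residue) isoform, so the default correspondence
(`correspond_by_numbering()`) simply pairs equal residue numbers. This has
two properties the analysis relies on:

* **Point mutants stay paired.** Position 305 is paired whether it carries
  Ser or Ile; a mutation is a coordinate difference, not an alignment gap.
* **Splicing forms are comparable.** A 3R fold lacks the R2 repeat
  (residues 275–305); those numbers are simply unpaired, and the
  correspondence splits into segments at the gap.

Windows are defined **within** correspondence segments — maximal runs in
which both residue numbers increase by exactly one — so no window ever
spans a splicing gap or chain break.

For chains whose numbering schemes differ, `correspond_by_sequence()`
falls back to global Needleman–Wunsch alignment (BLOSUM62, via
Biostrings). Gap penalties default high (`gap_open = 10`,
`gap_extend = 0.5`) relative to the worst substitution scores, so
block-sized gaps emerge rather than scattered single-residue gaps, and
mismatched (mutant) positions are matched rather than gapped. The penalty
values themselves are a package decision: numbering mode is the default
precisely because alignment is heuristic where numbering is unambiguous.

## Superposition

`kabsch_superpose()` computes the least-squares rigid superposition via
the SVD of the 3×3 cross-covariance matrix. Two numerical points matter:

* **Reflections are excluded.** The rotation determinant is forced to +1
  by sign-flipping the smallest singular direction. A mirror-image fold
  must never score as similar to its original.
* **Degenerate windows are fine.** For collinear or coincident points the
  minimal residual is still well defined (the rotation merely is not
  unique), so short or locally straight windows do not error.

The test suite checks every matrix entry against two independent routes: a
closed-form quaternion (Horn) solution and a brute-force quaternion grid
search with local refinement, and cross-checks against bio3d's fitting
routine.

## Windows, localized RMSD, and ranking

`window_rmsd_matrix()` evaluates every window of length ≥ `min_window`
inside every segment. The default `min_window = 3` is the smallest window
for which a rigid fit is non-trivial (1- and 2-point windows superpose to
zero residual identically); it is configurable. The localized RMSD is the
**unweighted arithmetic mean over all admissible windows** regardless of
length. Longer ranges contribute more windows, so extended conserved or
divergent regions naturally weigh more without an explicit length weight.

The default atom set is CA only; N, C and O are retained by the readers
and selectable (`atom_set = c("N","CA","C","O")`) for a denser backbone
comparison. `rank_folds()` applies the same machinery across a fold
library and orders ascending by localized RMSD, breaking ties by label and
reporting members that share no admissible window as incomparable rather
than dropping them.

Heat-maps (`render_heatmap()`) use window start residue on the horizontal
axis and window length on the vertical axis — the canonical triangular
layout — with a viridis colour scale fixed from 0 to the matrix maximum
(or a caller-supplied ceiling, for comparable panels across pairs), and
are written as both PNG and SVG.

## Synthetic filaments as ground truth

`build_filament()` turns one rung into an idealized filament: rung *k* is
the input rotated by *k*·twist about the z-axis through the rung centroid
and translated by *k*·rise along z. The geometry defaults follow the
cross-β architecture: rise 4.8 Å and left-handed twist, with the
crossover distance (the 180° repeat) related by
`crossover = 180 · rise / |twist|` — so 600 Å and 750 Å crossovers at
4.8 Å rise give −1.44 and −1.152 °/rung respectively.

The default rung (`serpentine_rung()`) is a 100-residue planar serpentine
CA trace (3.8 Å CA–CA spacing along strands, 4.8 Å strand offset) numbered
from 273, echoing the modelled core span of 4R tau depositions. It is
geometric, not stereochemical: bond angles, side chains and physical
packing are not modelled, which is irrelevant to the comparison machinery
(it only ever sees backbone coordinates) but means these fixtures say
nothing about, e.g., clash-driven fold preferences in real filaments.
Passing tests on synthetic filaments demonstrate the correctness of the
geometry and of the comparison operators — not that any particular real
fold pair scores any particular value.

`estimate_helical_params()` inverts the construction. The helical axis is
estimated as the first principal component of the **per-rung CA
centroids**: rung centroids trace the stacking direction exactly, whereas
the principal component of all atoms lies in the rung plane whenever a
short stack is wider than it is tall (a 100-residue rung spans ~70 Å;
five rungs stack only 19.2 Å), which would break both axis-based rung
selection and rise estimation. Rise is the mean centroid spacing along
this axis; twist is the mean adjacent-rung superposition angle, signed by
the sense of its rotation axis relative to the stacking direction.
Round-trips recover build parameters to 1e-6.

`perturb_region()` provides localization ground truth: residues in a
range are displaced along one seeded random direction by a `sin²` taper,
renormalised so the peak displacement equals the requested amplitude
exactly at the sampled residues; coordinates outside the range are
bit-identical. Comparison of a rung against its perturbed copy must show
elevation only in windows overlapping the range.

## ThT fibrillization kinetics

Thioflavin T fluorescence reports fibril mass, so a plate-reader time
course is a sigmoid. Each well is processed as:

1. **Background subtraction** — the mean of the first five raw readings
   is subtracted from every point (guarded against double application;
   the raw maximum is retained for QC).
2. **Gompertz fit** — `y(t) = A·exp(−exp(−(t − t_i)/B))`, minimised over
   `(A, t_i, B)` by Levenberg–Marquardt (minpack.lm). `A` is the
   amplitude (RFU), `t_i` the inflection time (h), and `B` a time
   constant (h) whose reciprocal `k_app = 1/B` is the apparent elongation
   rate. Starting values are `A₀ = max(rfu)`, `t_i₀` at the steepest
   observed rise, `B₀ = range(t)/10`; non-convergence is reported
   explicitly, never returned as a silent fit.
3. **Derived metrics** — the half-maximal time has the closed form
   `t½ = t_i − B·ln(ln 2)` (≈ `t_i + 0.3665·B`), and the aggregation
   propensity is `1/t½`. An interpolation mode instead takes the first
   half-maximum crossing of the observed curve; on clean data the two
   agree to within one sampling interval. The analytic, fit-derived
   value is the default because it is insensitive to single noisy points
   near the crossing.

**Quality control.** A well is discarded when its maximum *raw* RFU is
below 50 (too little signal to fit) **or** when its fit MSE exceeds one
standard deviation of the per-curve maximum signals within its condition
group. Two readings of this rule were genuinely open and are settled as
follows: the two clauses are combined with OR, because each alone marks a
defective (bubble-like) well and a high-signal bubble curve should not
survive on signal alone; and the MSE threshold is scoped per condition
group (configurable via `mse_sd_factor`), since plates mix constructs
with very different amplitudes. Note the threshold compares an MSE (RFU²)
against a spread of maxima (RFU); it behaves as intended on heterogeneous
real plates, where the spread of well maxima is large, but it is strict
on idealized homogeneous replicates — one more reason it is exposed as a
parameter. Group summaries report mean ± sd of `k_app` and propensity per
condition; inferential statistics between conditions are deliberately
left to dedicated statistics tools.

**Simulator.** `simulate_tht()` emulates the assay design — readings
every 5 minutes for 24 h (289 points) — adding seeded Gaussian noise and
giving each replicate a distinct sub-seed. At 2% amplitude noise the
median absolute relative error of recovered `k_app` across 100 seeded
wells is under 5%, which is the recovery bar the test suite enforces. The
simulator draws i.i.d. Gaussian noise only; real wells show drift,
correlated noise, and between-well amplitude variation that it does not
emulate.

## Problem sizes and runtime choices

The test suite and the acceptance script run on: 100-residue rungs (4,851
windows per comparison), 24–30-residue chains for oracle equivalence
(where the naive recomputation is affordable), 5–9-rung filaments for
geometry round-trips, and 100 seeded wells for the kinetics recovery
statistic. These sizes exercise every code path at full fidelity; all
operators scale to larger inputs without modification (the window count
grows quadratically in chain length).

## Known limitations

* Comparisons are single-rung: inter-rung packing and protofilament
  interfaces are out of scope, matching the per-fold cross-section view.
* No structure-guided realignment: the correspondence is fixed before any
  RMSD is computed.
* The deposited tau models this machinery is designed around are not
  shipped; comparisons of published folds require the user to supply the
  coordinate files.
* The synthetic rung is not stereochemically valid; do not use it as a
  modelling template.
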