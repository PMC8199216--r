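---
title: "Geometric interaction fingerprinting, occupancy statistics and assay math: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric interaction fingerprinting, occupancy statistics and assay math: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plifr)
```

This vignette is the package's own account of its methods: the
geometric criteria and their numerical treatment, the statistics built
on top of them, the assay mathematics, what the synthetic-data
generator does and does not emulate, and the design decisions taken
where more than one defensible convention exists.

## The detection model

An *interaction channel* names one candidate contact between declared
atoms (or rings) of a protein–ligand complex. On every trajectory
frame, a channel is either present (its geometric criteria hold) or
absent; the *occupancy* of a channel is the percent of frames in which
it is present. This frame-counting model deliberately ignores dynamics
within the trajectory — no lifetimes, no autocorrelation correction —
because the quantity of interest is the plain fraction of simulation
time an interaction is maintained.

The criteria, all cutoffs inclusive:

| channel | criterion | defaults |
|---|---|---|
| hydrogen bond | donor–acceptor distance ≤ d *and* donor–H–acceptor angle ≥ α | d = 3.0 Å, α = 135° |
| intramolecular H-bond | same, extended distance cutoff | d = 3.5 Å |
| salt bridge | min over declared O⁻/N⁺ pairs ≤ d | d = 4.0 Å |
| cation–pi | cation–centroid distance ≤ d *and* angle(ring normal, centroid→cation) ≤ α | d = 6.0 Å, α = 45° |
| pi–pi (face-to-face) | centroid distance ≤ d *and* interplanar angle ≤ α | d = 5.5 Å, α = 30° |

Assumptions worth making explicit:

- **Hydrogens are explicit.** The H-bond angle is the
  donor–hydrogen–acceptor angle (the CPPTRAJ-style convention; 180° is
  ideal, the cutoff is a minimum). No hydrogen positions are inferred;
  a donor–hydrogen distance above 1.5 Å draws a covalency warning
  because it usually means a mis-declared atom.
- **The H-bond angle convention** could in principle be
  donor–acceptor–H; we fix donor–H–acceptor, document it here, and
  record the cutoffs in every report so the convention travels with the
  numbers.
- **Salt bridges are group contacts.** Charged *groups*, not specific
  atoms, form the contact, so the criterion is the minimum over all
  declared oxygen–nitrogen pairs (both carboxylate oxygens × both
  amidine nitrogens).
- **Fused aromatics OR-reduce.** A tryptophan-like bicyclic is declared
  as two rings; a cation–pi or pi–pi channel on it is satisfied if
  *either* ring satisfies the criteria. This treats the residue as one
  interaction partner without privileging a ring.
- **The pi–pi rule is ours.** No standard criterion was inherited for
  pi–pi stacking, so the package supplies the conventional face-to-face
  rule (5.5 Å / 30°). Both thresholds are configurable, and reported
  pi–pi occupancies are rule-dependent in a way the other channels are
  not. T-shaped stacking is deliberately out of scope.
- **"Center of mass" of a single cation atom** is read as that atom's
  position.
- **Frames are taken as given**: imaged, aligned or not (detectors are
  rigid-motion invariant, so alignment does not matter), and the frame
  count is whatever the trajectory file contains — no stride is assumed
  or hard-coded.

## Geometric kernels and numerical choices

**Ring geometry.** The ring centroid is the unweighted atom mean. The
ring normal is the least-variance principal axis of the centered ring
coordinates (smallest eigenvector of the 3×3 covariance), not a
two-edge cross product, so puckered rings get a well-defined mean
plane; the RMS out-of-plane deviation is reported, and a declared
aromatic ring with planarity RMS > 0.3 Å draws a warning rather than an
error. The normal's sign is arbitrary, so it is canonicalized (largest
absolute component made positive, ties x before y before z) and all
angle computations fold by `|cos|` into [0°, 90°]; no detector result
ever depends on the sign.

**Cutoff comparisons.** All comparisons are inclusive, with a 1 × 10⁻⁹
(Å or degree) representability guard: a geometry constructed to sit
*exactly* at a cutoff evaluates through `sqrt`/`acos` with up to a few
ulps of error, and the guard absorbs that while anything 10⁻⁶ beyond
the cutoff still cleanly fails. This is a floating-point
representability tolerance, not a change to the cutoffs.

**Superposition and RMSD.** Superposition is the standard Kabsch
solution (SVD of the cross-covariance with determinant-sign correction,
always a proper rotation). `rmsd_coords()` is the plain
√(mean squared deviation) with no fitting, so fitted and unfitted RMSD
cannot be silently conflated. The RMSD trace protocol superposes each
frame onto the reference frame using protein backbone atoms
(N, CA, C, O) and reports ligand heavy atoms — the usual
ligand-stability trace — with both selections configurable because the
fitting selection is a genuine free choice.

**Degenerate inputs** are classed errors, not NaNs: collinear ring
atoms, zero-length angle vectors, mismatched point counts, empty
charged-atom sets, zero frames, flat dose-response data.

## Occupancy statistics

Occupancy is `100 × events / frames` computed from integer counts, so
it is exact; one-decimal formatting happens only at print time. The
heat-map matrix across compounds keeps a channel missing from a
compound's analysis as an empty cell (`NA`) rather than 0 %, because an
unmeasured interaction is not an absent one. Concatenating trajectories
combines occupancies by event-count weighting, which the tests assert
as an invariant.

## Assay mathematics

Polarization is `mP = 1000 (I_S − G·I_P)/(I_S + G·I_P)` with the
device G factor; blank correction is channel-wise subtraction with
negative results clamped to zero (with a warning — a blank brighter
than a sample well indicates a plate problem, not an arithmetic one).
Percent inhibition is `100 (1 − (P_I − P_neg)/(P_pos − P_neg))`,
reported as-is even outside [0, 100] so that over-ranged wells remain
visible.

IC50 fitting uses the four-parameter logistic with variable slope on
percent inhibition (not raw mP — fitting the normalized quantity is the
convention the inhibition-curve formulation implies, and it makes the
plateaus interpretable). The fit is Levenberg–Marquardt least squares
(via minpack.lm) with the IC50 parameterized as log₁₀ IC50, which keeps
it positive and well scaled. Initialization is deterministic: top and
bottom from the response range, IC50 from the concentration whose
response is nearest the plateau midpoint, Hill slope 1. Replicates are
fitted as individual points by default (averaging first discards
within-concentration variance; a flag averages if wanted). Standard
errors are asymptotic, the IC50's by the delta method from the log10
scale. Non-convergence returns a *flagged* result with a warning rather
than failing the batch; a response range below tolerance is a
degenerate-data error because no sigmoid is identified.

## Score discrimination

Group summaries are five-number box-plot statistics with type-7
(linear-interpolation) quartiles — box-plot conventions differ between
tools, so the method is fixed and recorded in the output — plus Tukey
whiskers and the between-group mean gap. The separation scan
exhaustively tries the midpoints between adjacent sorted scores (plus
thresholds outside the range), classifying the side holding the
active-group mean as active; ties between equally good thresholds break
toward the more negative threshold. Score kinds are ranked by
misclassification count, then gap. Activity labels are inputs (a
compound is active because its IC50 was determined), never inferred
from the scores being evaluated — inferring them would make the
discrimination analysis circular.

## The synthetic-data generator

`make_toy_complex()` builds a minimal stand-in for the pocket: one
aromatic six-ring for cation–pi (Phe-like), one for pi–pi (Trp-like,
six-membered ring only), a carboxylate oxygen pair (Asp-like), a
tyrosine-like hydroxyl acceptor, and a ligand carrying one dedicated
mobile unit per channel (cation, aromatic ring, amidine nitrogen pair,
and two donor–H triads). The five channel clusters are ~20 Å apart so
that moving one channel's atoms cannot affect another's criteria:
planted probabilities are independent by construction. Correlated
channels are deliberately out of scope.

`simulate_trajectory()` draws, per frame and channel, Bernoulli(p); ON
frames place the channel's mobile atoms uniformly inside the satisfying
region shrunk by a 0.3 Å / 5° margin, OFF frames push them beyond
cutoff-plus-margin, so OFF frames can never satisfy the criterion and
boundary ambiguity is kept out of all statistical tests (boundary
behavior is tested deterministically instead). A global rigid jitter
(rotation up to 2°, translation SD 0.3 Å) is applied last; being rigid
it cannot change any detector result, but it makes superposition in the
RMSD trace do real work. Each channel draws from its own random stream
keyed by (master seed, channel label), so results are bitwise
reproducible and independent of channel ordering.

The default plan plants 94 % (salt bridge), 54.1 % (cation–pi), 55.5 %
(protein–ligand H-bond), 31 % (intramolecular H-bond) and 2 % (pi–pi) —
occupancy levels spanning the range reported for inhibitor complexes of
this pocket family, from a firmly maintained salt bridge to a rarely
held stack. The score generator defaults to two Gaussians at
−76.3 / −60.35 kcal/mol (SD 4, n = 17/3), the composition of a
rescoring comparison between IC50-confirmed actives and inactives; the
assay generator defaults to a 12-point 1:3 dilution from 100 µM in
triplicate around a 182.6 nM IC50 with 2-point noise.

**What passing tests do and do not show.** The generator produces
piecewise-rigid, geometrically clean frames with independent channels
and exactly Bernoulli occupancy. Real MD frames have correlated
contacts, autocorrelated time series, thermal vibration of every atom,
near-cutoff dwelling, and occasional pathological geometry. Tests on
synthetic data therefore validate the *bookkeeping and the criteria* —
that detectors implement their definitions exactly, that occupancy
counts what it claims, that the pipeline is deterministic — not that
the cutoffs themselves are chemically optimal, nor how estimates
degrade under autocorrelation.

## Problem sizes and test design

The validation suite runs detector-vs-oracle comparisons on 1,000
random geometries per detector (the oracles are independent literal
transcriptions of the criteria, with cross-product ring normals on
planar rings), rigid-motion invariance over 200 random transforms of a
50-frame trajectory, planted-occupancy recovery on 10,000 frames
(within three binomial standard errors), IC50 recovery over 100 noisy
replicates, and simulate→analyze round trips at 3,000 frames — sizes at
which binomial bounds are tight enough to be meaningful while the whole
suite stays fast. Fixed seeds make every stochastic test reproducible.

## Known limitations

- No symmetry-corrected RMSD (equivalent-atom matching); declared atom
  order is trusted.
- No halogen bonds, water bridges, T-shaped stacking, or interaction
  energies; detection is purely geometric.
- Occupancies carry no error bars (no block averaging); they are exact
  frame counts of the given trajectory.
- The PDB dialect is the fixed-column MODEL/ENDMDL form; binary
  trajectory formats are out of scope.
- The 4PL fitter reports asymptotic standard errors only; profile or
  bootstrap intervals are left to the caller.
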