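# plifr

Protein–ligand interaction fingerprinting and assay analysis for MD
trajectories, in R.

## What this package is for

Structure-based studies of methyl-reader inhibitors (the motivating case
is a Tudor-domain protein whose aromatic cage binds a protonated
pyrrolidine, with an amidine salt bridge to a nearby aspartate) routinely
ask the same computational questions: *in what fraction of MD frames is
each key protein–ligand interaction actually present?* Is the pose
stable in RMSD terms? Do the scoring methods used to rank compounds
actually separate actives from inactives? And, on the experimental side,
what IC50 does a fluorescence-polarization (FP) displacement assay give?

`plifr` implements that analysis layer as tested, reusable components:

- **Geometric interaction detectors** over multi-model PDB trajectory
  frames, with inclusive cutoffs (defaults in parentheses):
  - hydrogen bond: donor–acceptor distance ≤ 3.0 Å and donor–H–acceptor
    angle ≥ 135°; the distance cutoff extends to 3.5 Å for ligand
    *intramolecular* hydrogen bonds;
  - salt bridge: minimum distance over the declared anionic-oxygen /
    cationic-nitrogen sets ≤ 4.0 Å;
  - cation–pi: cation-to-ring-centroid distance ≤ 6.0 Å *and* angle
    between the ring normal and the centroid→cation vector ≤ 45°;
  - pi–pi (face-to-face): centroid distance ≤ 5.5 Å and interplanar
    angle ≤ 30° (a conventional rule; configurable).
- **Occupancy statistics**: per-channel percent-of-frames occupancy
  (`100 × events / frames`, exact), compounds × channels heat-map
  matrices (missing channels stay empty, not 0), and Kabsch-superposed
  RMSD traces (fit on protein backbone, report ligand heavy atoms, both
  configurable).
- **FP assay mathematics**: `mP = 1000 (I_S − G·I_P)/(I_S + G·I_P)`,
  blank correction, percent inhibition
  `I = 100 (1 − (P_I − P_neg)/(P_pos − P_neg))`, and four-parameter
  logistic (variable-slope) IC50 fitting
  `y = bottom + (top − bottom)/(1 + 10^(hill·(log10 IC50 − log10 x)))`,
  returned as a classed fit object with `print`, `summary`, `coef`,
  `predict`, `plot`, `residuals` methods.
- **Score discrimination**: box-plot statistics per activity group, the
  between-group mean gap, and an exhaustive single-threshold separation
  scan, ranked across score kinds (e.g. docking scores vs MM-GBSA
  rescoring).
- **A synthetic-data generator** that builds a minimal aromatic-cage
  complex and plants each interaction with a chosen Bernoulli
  occupancy, so every statistic above can be validated against known
  ground truth. ON frames satisfy the criteria with ≥ 0.3 Å / 5°
  margin, OFF frames violate them with the same margin, and a global
  rigid jitter exercises the detectors' rigid-motion invariance.

## Worked example

```r
library(plifr)

tpl  <- make_toy_complex()                       # toy aromatic-cage complex
traj <- simulate_trajectory(tpl, channel_plan(), n_frames = 2000, seed = 42)
em   <- build_event_matrix(traj, tpl$channels, tpl$spec)
occupancy(em, compound = "toy-A366-like")
#> Interaction occupancies for toy-A366-like (2000 frames):
#>   ligand-Tyr170 H-bond           56.2 %  (1124/2000 frames)
#>   intramolecular H-bond          32.5 %  (650/2000 frames)
#>   amidine-Asp184 salt bridge     94.1 %  (1882/2000 frames)
#>   pyrrolidinium-Phe141 cation-pi   52.9 %  (1057/2000 frames)
#>   isoindoline-Trp151 pi-pi        2.2 %  (45/2000 frames)
```

The default plan plants 55.5 / 31 / 94 / 54.1 / 2 percent; the measured
occupancies differ only by binomial sampling noise. The ligand RMSD
trace and an FP dose–response fit:

```r
fit_sel <- resolve_selection(traj, "* * N,CA,C,O")
lig     <- which(traj$atoms$resname == "LIG" & traj$atoms$element != "H")
rmsd_trace(traj, fit_sel, lig)
#> RMSD trace: 2000 frames, mean 1.241 A, max 2.302 A

plate <- simulate_dose_response(seed = 42)       # planted IC50 182.6 nM
fit_4pl(plate$concentration, plate$inhibition)
#> Four-parameter logistic dose-response fit
#>   IC50:   1.7993e-07  (Hill slope 0.972)
#>   top:    100.777   bottom: -1.091
#>   converged, RSS 155.3 over 36 points
```

With 2-percentage-point noise on 12 concentrations × 3 replicates, the
fitted IC50 (180 nM here) sits within a few percent of the planted
182.6 nM.

Real trajectories enter through `read_multimodel_pdb()` plus a YAML/JSON
analysis config (`read_analysis_config()`) declaring the ligand, the
channels and any cutoff overrides. A thin command-line dispatcher over
the same functions is installed at
`system.file("cli", "plifr.R", package = "plifr")` with subcommands
`analyze`, `simulate`, `assay`, `discriminate`.

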