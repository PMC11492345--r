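---
title: "Beam complexity quantification and GPR prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beam complexity quantification and GPR prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmatqa)
```

## The problem

A VMAT beam is delivered as an ordered sequence of control points: at each
one the machine records the two MLC leaf banks, the collimator jaws, the
gantry angle and the cumulative meterset (MU) fraction. Patient-specific QA
measures how faithfully this sequence is delivered, summarized as a gamma
passing rate (GPR). Complexity metrics compress the control-point sequence
into scalars that correlate with QA outcome; `vmatqa` computes 27 of them,
correlates them with measured GPRs, derives pass/fail thresholds by ROC
analysis, and predicts GPR with tree ensembles.

All positions are millimeters at the isocenter plane in the IEC
beam-limiting-device frame. Leaf pairs are indexed from the most negative y
boundary; bank "left" closes from −x, bank "right" from +x.

## Meterset bookkeeping

Cumulative meterset weights must start at 0, end at 1, and never decrease.
Transition `k → k+1` carries `MU_k = MU · (w_{k+1} − w_k)`. Per-control-point
quantities use the *half-transition rule*: each control point receives half
of each adjacent transition's MU (the ends receive one half only). This
conserves MU exactly, reduces to the transition-pair averaging of the
VMAT-adapted modulation complexity score, and is how every "MU-weighted
mean" below is weighted. Internally the normalized weights are computed from
the cumulative weights alone, so every metric except TotalMU and PMU is
bitwise invariant under MU rescaling.

## Aperture geometry conventions

For each control point:

* a pair is **in field** when its y-span overlaps the jaw y-window with
  positive measure and its opening overlaps the jaw x-window;
* a pair is **open** when, additionally, its jaw-clipped gap exceeds
  `open_gap_tol` = 0.5 mm. 0.5 mm is the minimum dynamic gap of an HD-class
  MLC: smaller gaps are dosimetrically closed. Opposing leaves that overlap
  by ≤ 0.01 mm (file rounding) are clamped to their midpoint; larger
  overlaps are validation errors.
* areas, perimeters, spreads and midpoints all use jaw-clipped positions,
  so `area ≤ jaw_area` and `AAJA = area/jaw_area ∈ [0, 1]` by construction.

**Leaf-side perimeter.** `side_perimeter` sums, over pair boundaries
strictly inside the jaw y-window: `|Δleft| + |Δright|` where both adjacent
pairs are open, and the open pair's full clipped gap where an open pair
abuts a closed one (the whole end-to-end edge is exposed). Boundaries lying
on or outside a jaw edge are shielded by the jaw and contribute nothing —
this is what makes the static verification field score zero. The full-gap
rule at open/closed boundaries is a design choice (published illustrations
of the leaf-side perimeter cover only the open/open case); it is the unique
continuous extension as a neighbor's gap shrinks to zero.

**Full perimeter** (used by the irregularity metric BI) is the true boundary
length of the jaw-clipped open region: symmetric-difference edges at
interior boundaries, leaf-tip faces (2 × clipped width per open pair), and
jaw caps at the y-window edges.

**Rasters.** Union area uses a 0.5 mm pixel raster by default (pixel center
inside aperture), fluence maps 1 mm bixels, and test oracles 0.1 mm; all
configurable. The union raster agrees with analytic areas to < 0.5 % at
0.1 mm on random apertures (tested).

## The 27 metrics

In fixed CSV order: TotalMU, PMU, NumSegments, AvgLeafGap, AAJA, MAXJ,
JawTrackingPct, M, LSV, AAV, MCS, MCSv, LT, LTMCS, BA, BI, BM, EM, EAM, MAD,
UnionArea, SAS2, SAS5, SAS10, SAS20, APV, LAAM. Key conventions:

* **PMU** — plan MU normalized to a single 2 Gy fraction
  (`plan_MU · 2 / fraction_dose`); a plan-level value copied onto every beam
  of the plan.
* **AvgLeafGap** — plain (unweighted) mean of clipped gaps over all open
  pairs and control points; the only non-MU-weighted mean, because its name
  denotes a plain average. **SASx** — MU-weighted fraction of open pairs
  with gap strictly below x ∈ {2, 5, 10, 20} mm; control points with no open
  pair are skipped and the weights renormalized.
* **MAXJ** — the largest jaw opening, `max(x2−x1, y2−y1)`, over control
  points. **JawTrackingPct** — fraction of transitions in which any jaw
  coordinate moves by more than 0.1 mm.
* **LSV/AAV/MCS/MCSv** — the modulation complexity score family. LSV uses
  adjacent differences of open in-field leaf positions normalized by the
  bank spread (`pos_max`); a bank with < 2 open pairs or zero spread is a
  degenerate factor of 1. AAV divides each control point's summed opening by
  the per-pair maximum opening of the beam. MCS weights the per-CP product
  by CP meterset; MCSv averages the factors over transitions weighted by
  transition meterset.
* **LT** — mean total travel (mm) of active leaves (both leaves of every
  pair open at ≥ 1 control point), raw positions. **LTMCS** =
  `(1 − min(LT, 1000)/1000) · MCSv`. Masi's LTMCS construction leaves the
  travel normalizer implicit; 1000 mm is the round value consistent with
  LTMCS magnitudes quoted for clinical VMAT cohorts, and it is configurable.
* **BA** (cm²), **BI** (`perimeter²/(4π·area)`, ≥ 1), **BM**
  (`1 − weighted_area/UnionArea`). **UnionArea** defaults to the geometric
  raster union, the literal reading of "union area of all apertures";
  `union_mode = "summed"` returns the summed per-CP areas instead, because
  union-area magnitudes quoted for clinical cohorts are often consistent
  with summed areas. Both modes are exposed and BM follows the chosen mode.
* **EM** — `(c2·side + c1·tip)/area` with defaults `c1 = 0, c2 = 1` (1/mm);
  **EAM** — percentage of aperture area within 2 mm (Chebyshev distance) of
  the aperture boundary. EAM is computed by *exact* erosion: the aperture's
  row structure makes the Chebyshev-eroded region piecewise rectangular, so
  the erosion is evaluated on y-segments instead of a raster (verified
  against a raster-erosion oracle). EM/EAM constants vary across published
  implementations, so these metrics are behavior-tested (closed forms,
  monotonicity); their absolute magnitudes are convention-dependent.
* **M** — fluence modulation index: accumulate the MU fluence map, take σ
  over footprint bixels, and integrate over f ∈ [0, 1] (step 0.01,
  trapezoid) the fraction of adjacent same-row bixel pairs differing by more
  than f·σ. Uniform fluence gives 0; rescaling MU leaves M unchanged.
* **MAD** — MU-weighted mean over open pairs of |aperture midpoint x|
  (x-offsets only; translation-equivariant).
* **APV** — `1 − side_perimeter/((N_open − 1)(spread_L + spread_R))` per
  control point, MU-weighted. `P_max = spread_L + spread_R` is the reading
  that keeps APV in [0, 1] for contiguous apertures (the side-perimeter
  bound); degenerate states (≤ 1 open pair or zero spreads) score 1, and
  values are clamped to [0, 1] because hand-built *non-contiguous* apertures
  can exceed the bound.
* **LAAM** — the composite score described in the README: transition-MU
  weighted product of a leaf-travel factor (clamped at `LT_max` = 30 mm),
  the AAJA average and the APV average of the transition's endpoints.
  Zero-MU transitions are included with weight 0.

## QA statistics

* Spearman `r_s` is the Pearson correlation of mid-ranks (average ranks on
  ties). The two-tailed p-value uses exact permutation enumeration for
  n ≤ 8 and the t approximation `t = r_s√((n−2)/(1−r_s²))` above
  (exhaustive enumeration beyond 8! = 40320 permutations buys no practical
  precision at its cost). No multiple-testing correction.
* Pass/fail labels use GPR ≥ 95 % (≥ on the boundary); "pass" is the
  positive class. ROC analysis orients each metric so that larger oriented
  scores predict passing (AUC ≥ 0.5 by construction), computes AUC as the
  Mann–Whitney rank statistic with half-credit ties (equal to the
  trapezoidal ROC integral, tested to 1e−12), and picks the operating
  threshold by Youden's J, breaking ties toward the positive-class median.
  Neither the positive-class convention nor the threshold rule is
  standardized in the QA literature; Youden's J is the common default and
  both are configurable.

## GPR regression

Random forest (150 trees, depth 10, min-split 5, min-leaf 1) and
least-squares gradient boosting (180 trees, depth 12, min-split 10,
min-leaf 4, learning rate 0.01) are implemented as Rcpp CART ensembles
(no suitable R package is available offline): exact greedy splits on all 27
features, midpoint thresholds, first-best tie-breaking, bootstrap resampling
from R's RNG so a seed fixes the fit bit-for-bit. Importances are normalized
total SSE reductions per feature. Predictions are clipped to [0, 100] %.
"Prediction accuracy" is defined as `100 − MAPE` (mean absolute percentage
error), the definition consistent with accuracy/MAE pairs quoted for GPR
regressors operating near GPR ≈ 97 %. Evaluation reports both 5-fold
cross-validation (shuffled folds by seed) and an 80/20 holdout
(`round(0.8n)` training rows), since quoted performance figures often do
not distinguish the two. No feature scaling — trees are scale-invariant.

## The synthetic cohort: what it emulates, and what it does not

The generator produces jaw-tracked arcs of 50–180 control points on the
HD-120 geometry (32 central 2.5 mm pairs, 28 outer 5 mm pairs): a
superellipse target outline with lateral drift and size breathing, a
smoothed uniform leaf staircase of configurable amplitude, and per-control-
point jaw tracking. The cohort is a mixture of **conformal arcs**
(rectangular profile, zero staircase — low complexity, LAAM near 1) and
**modulated arcs** (superellipse exponent 5–14, staircase 0.5–6 mm), 60/40
by default, across five sites with different target-size ranges. GPR is
*assigned*, not computed: `GPR = clip(78 + 20·LAAM + N(0, 1), 0, 100)`.

The intercept/slope/noise are fixed package defaults; given them, the
target cohort shape (mean GPR in [95, 99], SD in [1.5, 4], LAAM AUC ≥ 0.9)
dictates a cohort dominated by low-modulation beams. The
mixture parameters were chosen once, by measuring mean/SD/rank-correlation/
AUC on three seeds, and then frozen; they are a stated world, not a tuning
knob, and the acceptance tests run against the frozen defaults at seed 42.

A green synthetic-cohort test therefore establishes that the *pipeline*
(metric extraction → correlation → ROC → regression → importance ranking)
recovers a known monotone complexity–GPR link through the package's own
computations. It does **not** establish dosimetric realism: there is no dose
calculation, the GPR link is linear by construction, the complexity
distribution is much milder than clinically measured stereotactic cohorts,
and measured-cohort statistics are neither reproduced nor asserted.

## Numerical and degenerate-input conventions

* Closed-pair tolerance 0.5 mm; overlap clamp 0.01 mm; jaw-move tolerance
  0.1 mm; cumulative weights validated to 1e−9 at the ends and 1e−12
  monotonicity slack.
* Empty apertures: a control point with no open pair contributes AAV 0,
  LSV 1 (degenerate), MAD 0 and is skipped by SAS renormalization; a beam
  with no open pair anywhere is an error (`empty beam`).
* σ = 0 fluence (or footprint < 2 bixels) gives M = 0; UnionArea = 0 gives
  BM = 0.
* DICOM support is deliberately narrow: RT Plan Storage, explicit VR little
  endian, MLCX + ASYMX/ASYMY devices, carry-forward of positions omitted at
  later control points; setup beams are skipped. Anything else raises
  `unsupported plan`. The JSON dialect is the canonical text fixture format.
* All artifact writes are atomic (temp file + rename) and carry a manifest
  with config hash, seed and input MD5 digests. Config files are JSON (no
  YAML parser is available in the supported environment).

## Known limitations

* No rounded-leaf-end, tongue-and-groove or transmission modeling; the
  collimator angle is assumed 0 in the beam's-eye view accumulation.
* EM/EAM/M constants follow the configurable defaults above, not any
  specific institution's implementation; absolute magnitudes of these three
  metrics are convention-dependent.
* The exact-erosion EAM assumes one interval per leaf pair (true for MLC
  apertures, not for arbitrary masks).
* The DICOM codec does not read implicit-VR or compressed transfer
  syntaxes.
* Tree ensembles use exact greedy splitting on all features; sklearn's
  random tie-breaking among equal-gain splits is replaced by deterministic
  first-best, so fitted trees can differ from sklearn's in degenerate cases
  even at identical hyperparameters.
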