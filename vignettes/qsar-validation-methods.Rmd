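---
title: "Models, validation criteria, and numerical choices in qsarpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, validation criteria, and numerical choices in qsarpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarpipe)
```

qsarpipe implements the statistical core of a small-series
inhibitor-discovery campaign: a multiple-linear-regression QSAR model with
its full validation battery, a small neural-network counterpart,
early-recognition metrics for ranked virtual screens, MM/GBSA component
bookkeeping, trajectory statistics, and rule-based drug-likeness filters.
This vignette explains the models and their assumptions, the tunable
parameters, what the synthetic generators do and do not emulate, and the
numerical decisions taken where the design was genuinely open.

## The regression model and its assumptions

Activities are pIC50 values, `9 − log10(IC50[nM])`; the conversion assumes
IC50 inputs in nanomolar and callers must convert other units first. The
model is ordinary least squares with intercept,
`y = a0 + Σ a_j x_j + ε`, solved by QR factorization of the
intercept-augmented design. With ~23 training compounds and mildly
correlated descriptors, forming and inverting X'X would lose roughly twice
the digits of the QR route, so no explicit inverse is ever formed (the
applicability-domain leverages likewise use triangular solves against the
QR factor R).

`fit_metrics()` reports R², adjusted R² = ((n−1)R² − p)/(n−1−p), MSE (SSE/n),
RMSE, MAE, the ANOVA F = (SSR/SSE)(n−p−1)/p, the residual standard
deviation s = sqrt(SSE/(n−p−1)), and a Bayesian information criterion.
BIC is computed under the Gaussian likelihood as
`n·ln(SSE/n) + (p+1)·ln(n)`; the criterion is named in the modelling
literature this package follows without a formula, so the standard
Gaussian-likelihood form was adopted. A perfect fit reports `F = +Inf`
rather than erroring, since downstream code treats F as a quality score.

Descriptor *selection* is deliberately out of scope: models are fit on
caller-specified columns. How four descriptors might be chosen from
thousands is a separate, procedure-dependent question that the upstream
sources do not specify.

## The validation battery

**Internal (LOOCV).** `loocv_q2()` refits the model n times, predicting
each held-out compound, and reports
`Q² = 1 − PRESS / Σ(y_i − ȳ)²` with ȳ the full-training mean, flagged
against the conventional Q² > 0.5 bar. The refits are an explicit loop —
not the hat-matrix shortcut — so the identical code path supports any
model through the `fit_fun`/`predict_fun` hooks (the ANN reuses it). The
closed-form identity `y_i − ŷ_loo,i = e_i/(1 − h_ii)` is used as an
independent oracle in the test-suite, where the two routes must agree to
1e−10.

**External (Golbraikh–Tropsha).** The battery needs a definition of the
through-origin determination coefficients r0² and r0′², which the source
table names without formulas. The literature-standard forms are used:
with through-origin slopes `k = Σyŷ/Σŷ²` and `k′ = Σyŷ/Σy²`,
`r0² = 1 − Σ(y − kŷ)²/Σ(y − ȳ)²` and the converse for r0′². Thresholds are
fixed: Q²ext > 0.5, R² > 0.6, |r0² − r0′²| < 0.3, both normalized deltas
< 0.1, and 0.85 < k, k′ < 1.15. When R² = 0 the delta criteria are
reported as `NA` (undefined) rather than thrown, since a hopeless model
should still produce a readable report.

**Y-randomization.** The activity vector is permuted (default 10 runs,
matching common practice), the model refit, and
`cRp² = R·sqrt(R² − mean R²rand)` compared against 0.5 with the additional
requirement that every permuted R² fall below the original. The printed
source formula for cRp² is typographically corrupted; the standard form
above was adopted. When the radicand is negative — possible for weak
original models — cRp² is clamped to 0 and flagged (`crp2_clamped`),
never returned as NaN.

**Applicability domain.** Leverages are diagonal elements of the hat
matrix on the *intercept-augmented* design, so training leverages sum to
k+1 and the warning leverage `h* = 3(k+1)/n` is consistent with the
augmented column count (with k = 4 descriptors and n = 24 this gives the
familiar 0.625). Standardized residuals use s from the training fit; the
outlier cutoff ±3 is the Williams-plot convention. Note the arithmetic of
h\* = 0.625 implies n = 24 while a 23-compound training set would give
0.652 — both appear in the motivating literature; the package simply
computes h\* from the supplied design and lets the caller override it.

## The neural-network model

`train_mlp()` trains a p–h–1 feed-forward network (sigmoid hidden layer,
identity output; default h = 3, so a 4–3–1 net has 19 parameters). Inputs
and target are z-scored on training statistics — the sources are silent on
scaling, and without it conjugate-gradient training on raw descriptor
scales (spanning 0.005 to 150 here) stalls. Weights start from a seeded
uniform [−0.5, 0.5] draw; training minimizes MSE by conjugate gradients
with analytic backpropagated gradients. The named training algorithm in
the motivating literature is the scaled-conjugate-gradient method; plain
conjugate gradients with line search is the documented substitute, which
reaches the same minima on these problem sizes. The default width is 3
per the running text of that literature; a figure caption there says 2, so
the width is a parameter rather than a constant.

One stated invariance deserves honesty: predictions after
standardize→train→predict are invariant to affine rescaling of an input
column *in exact arithmetic*, and bitwise invariant when the rescaling is
a power of two (standardization then reproduces the identical floating
design). For general affine maps the z-scored design changes at the last
ulp, and an iterative nonconvex optimizer amplifies that along near-flat
directions of the loss — measured divergence is ~1e−2 after tens of
thousands of iterations regardless of polish. The tests therefore assert
exact invariance for power-of-two rescaling and approximate invariance
(0.05 on predictions) for general affine maps, rather than pretending to
a 1e−6 guarantee no implementation of this trainer can give.

## Screening enrichment metrics

A `ranked_screen()` sorts ligands best-first by score with a stable sort
(ties keep input order; ROC credits score ties 0.5 via midranks, the
Mann–Whitney convention). RIE and BEDROC follow Truchon & Bayly: with
active ranks r_i among N ligands and Ra = n/N,

RIE = Σ exp(−α r_i/N) / [Ra (1 − e^{−α})/(e^{α/N} − 1)],

and BEDROC is the min–max normalization of RIE onto [0, 1], exactly 1 for
a perfect ranking. The default α = 160.9 concentrates the weight on
roughly the top 1% of the list. A useful identity: for a perfect ranking
at large α, RIE → N/n, which is 28/22 = 1.27 for a 22-active, 28-ligand
screen.

“Actives recovered in the top x% of decoys” is read ROC-style: find the
rank at which ⌈x · n_decoys⌉ decoys have been seen and report the percent
of actives at or above it. This reading reproduces the worked values
7/22 = 31.8% and 2/16 = 12.5% that anchor the definition; the alternative
(“top x% of the whole database”) cannot. EF(f) counts actives in the top
⌈f·N⌉ entries; because of that ceiling the exact upper bound is
⌈f·N⌉/(n·f), which slightly exceeds the idealized min(1/f, N/n) on small
lists.

## MM/GBSA bookkeeping

`binding_totals()` enforces the identities ΔG_gas = ΔvdW + ΔEEL,
ΔG_solv = ΔEGB + ΔESURF, Δtotal = ΔG_gas + ΔG_solv as exact sums, in
kcal/mol (AMBER convention; no unit conversion is attempted).
`aggregate_frames()` reports component-wise mean ± sample sd; since the
totals are linear, totals-of-means equal means-of-totals, which the tests
assert. Whether a published table of this kind holds single-snapshot
values or trajectory means is often unstated — the aggregator supports
both readings. Published tables also occasionally carry ±0.01 rounding
inconsistencies between components and totals; comparisons against such
tables are made at the printed 2-decimal scale and internally inconsistent
columns are excluded from exact checks.

## Trajectory statistics

Superposition is the weighted Kabsch fit: SVD of the weighted
cross-covariance with the sign of the smallest singular direction flipped
when needed so the rotation is proper (det = +1). Degenerate (collinear)
point sets are rejected — the rotation is not identifiable. RMSD is
mass-weighted by default and computed after the fit; RMSF aligns frames
onto an iteratively refined mean structure (two passes: align to the first
frame, average, re-align to the average) before averaging per-atom squared
deviations over time — whether published RMSF curves aligned to the mean
or the first frame is typically unstated, and the two-pass mean is the
common default of trajectory-analysis libraries, against which this
implementation is tested to 1e−6.

Hydrogen bonds follow the stated criterion literally: hydrogen–acceptor
distance < 3.5 Å and D–H…A angle within 150–210°, implemented as
|angle − 180°| ≤ 30° since three-point angles fold at 180°. The 3.5 Å
figure is conventionally a *donor*–acceptor cutoff, so a
`distance_mode = "DA"` switch provides the conventional reading; the
literal H…A default is documented prominently because the two differ by
roughly one covalent bond length.

SASA is Shrake–Rupley with a deterministic golden-spiral lattice (default
960 points, probe 1.4 Å, Bondi radii), so results are exactly reproducible
and converge as the point count grows; agreement with an independent
implementation is within 0.6% on a 30-atom test cluster. Coordinate PCA
operates on aligned, mean-centered frames; eigenvalues are sorted
descending and their sum equals the total coordinate variance (trace
identity, asserted to 1e−8). Free-energy landscapes bin two order
parameters into a 2-D histogram and report
ΔG = −kB·T·(ln P − ln Pmax) in kcal/mol (kB = 0.0019872041 kcal/mol/K,
default T = 310 K, the usual physiological simulation temperature):
the most populated bin is exactly 0 and empty bins are `NA`, masked rather
than −kB·T·ln 0.

## The synthetic-data generators: a stated world

The generators exist so every stage is testable offline; their defaults
are a fixed statement of the world being emulated, not dials to tune.

* `gen_qsar_dataset()`: 28 compounds, 4 descriptors, linear signal with
  coefficients (intercept 6.2; −0.002, 52, 0.43, 0.28) and Gaussian noise
  sd 0.15 pIC50 units — the coefficient magnitudes and residual scale of a
  strong small-series model. Descriptor means/scales (1000 ± 150,
  0.03 ± 0.005, 1 ± 0.7, 2 ± 1.2) were chosen once so each descriptor
  contributes roughly 0.3 pIC50 units of spread — giving training R²
  around 0.95 at n = 23 — and activities land in the realistic 5–8 pIC50
  range. The target correlation matrix (max |r| ≈ 0.58) reproduces the
  mild multicollinearity typical of topological/autocorrelation descriptor
  sets, via a Cholesky transform of i.i.d. normals.
* `gen_ranked_screen()`: active scores N(separation, 1), decoys N(0, 1);
  separation 0 is the calibrated null (mean AUC 0.5), large separations
  approach the perfect ranking.
* `gen_trajectory()`: a random reference geometry plus i.i.d. Gaussian
  jitter, optionally split into two offset basins. This exercises the
  estimators (closed-form RMSF = σ√3, two-minimum landscapes) but is *not*
  dynamics: no bonds, no correlated motion, no solvent, no periodic box.
* `gen_mmgbsa_frames()`: i.i.d. normal components at kinase-complex
  magnitudes.

A green test on synthetic data therefore establishes that the estimators
compute their definitions correctly and calibrate at the null — not that
any real system behaves this way. Every generator threads one seeded RNG,
restores the caller's RNG state, and returns ground truth separately from
observations so recovery tests never peek.

## Degenerate inputs and tie-breaks

* Missing CSV cells are rejected, never imputed; schema errors name the
  offending column; duplicate ids are errors.
* Rank-deficient designs name the collinear columns; LOOCV refits that go
  singular name the fold.
* Activity labelling is strict (`pIC50 > threshold`): a compound exactly
  at 6.5 is inactive, per the "exceeding" reading.
* Drug-likeness boundaries are inclusive (TPSA exactly 131.6 passes the
  Egan rule); Lipinski accepts up to one violation by default — the
  original rule-of-five convention — configurable to strict.
* Score ties in screens: stable sort, secondary key input order, 0.5 ROC
  credit.

## Known limitations

* The ANN trainer is plain conjugate gradients, adequate at these sizes
  but slow near flat minima; no hyperparameter search is provided.
* Trajectory I/O is text-only (multi-frame XYZ, multi-model PDB); binary
  MD formats are out of scope.
* SASA is O(atoms² · points) without spatial hashing — fine for ligands
  and test systems, not for large proteins.
* The Williams-plot and other figures are exported as data (CSV/JSON);
  no plotting is bundled.
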