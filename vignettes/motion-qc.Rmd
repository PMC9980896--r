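---
title: "Evaluating head-motion effects on neonatal functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating head-motion effects on neonatal functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neomotion)
```

## The problem

Newborns move in the scanner: long quiet stretches of sleep are broken by
sudden surges of head motion. Motion corrupts resting-state BOLD signals in
two ways that matter for connectivity analysis — it injects shared artifact
signal into many regions at once (inflating or deflating correlations,
depending on how each region's signal responds), and it destroys signal in
the affected frames (lowering temporal SNR). `neomotion` implements the
full evaluation chain used to quantify these effects and to test how well
frame censoring ("scrubbing") removes them, together with a synthetic
cohort generator whose ground truth is known exactly, so that every stage
can be validated end to end.

## Frame-wise displacement

Head position per frame is summarized by six rigid-body parameters:
translations $d_x, d_y, d_z$ in mm and rotations $\phi, \theta, \psi$
(roll, pitch, yaw) in radians. Rotations are converted to millimetres on a
sphere of radius $r = 30$ mm — a neonatal head, about 60% of the adult
radius used by the original displacement index. The per-frame displacement
is the *mean* of the six absolute backward differences:

$$\mathrm{FD}_i = \tfrac{1}{6}\left(|\Delta d_x| + |\Delta d_y| +
  |\Delta d_z| + r|\Delta\phi| + r|\Delta\theta| + r|\Delta\psi|\right),
  \qquad \mathrm{FD}_0 = 0.$$

Two conventions deserve attention. First, the widely cited adult index
*sums* the six terms; the mean used here is exactly one sixth of that, so
thresholds are not interchangeable between the two conventions.
`compute_fd()` implements the mean form. Second, absolute values are
applied to each term — without them displacement terms of opposite sign
would cancel and FD could be negative, contradicting its definition as a
displacement magnitude. The sign convention of the difference
(previous − current vs current − previous) is immaterial under the
absolute value.

## Censoring plans

`make_censor_plan()` applies two optional stages: every frame with FD above
a threshold (0.5 mm "lenient" and 0.2 mm "strict" are the conventional
choices) is dropped — frame 0, whose FD is 0 by definition, is never
dropped on FD grounds — and the scan is then capped at a fixed length
(default 240 s, i.e. 120 frames at TR 2 s) by keeping the *earliest*
surviving frames. The cap equalizes the number of frames entering every
censoring condition, so that conditions differ in *which* frames survive,
not in how much data they have; otherwise stricter thresholds would be
penalized by higher sampling noise. Keeping the earliest frames (rather
than a random subset) preserves temporal order and determinism; which
frames to keep is not prescribed by the index itself, so this is an
implementation decision. Mean FD after censoring is the mean of the
original per-frame FD over the survivors; it is *not* recomputed between
now-adjacent frames.

## Cleaning: simultaneous nuisance regression and band-pass

Nuisance regression and band-pass filtering interact: regressing unfiltered
nuisance signals after filtering reintroduces out-of-band variance.
`clean_timeseries()` therefore performs both in a single least-squares
projection: the design contains an intercept, a linear drift, the
requested nuisance columns (24 motion regressors — the six parameters,
their backward differences, and the squares of both; a white-matter mean;
principal components of the CSF signal; optionally the gray-matter global
signal), plus sine/cosine regressors at every discrete Fourier frequency
outside the passband (default 0.009–0.08 Hz). The residuals are orthogonal
to every removed column by construction, and the projection is idempotent.
Whether tissue regressors should be filtered before regression is moot
under this design — the joint projection spans both subspaces. Band edges
are inclusive on the retained side. A rank-deficient combined design
triggers a warning and a projection onto the column space (no error):
duplicated regressors are common in automated designs and harmless for
residualization.

One practical consequence of a joint projection: with a TR of 2 s, roughly
85 frequency regressors plus a 26-column motion design require comfortably
more than ~115 frames. Scans shorter than that cannot support the full
design and are rejected with a validation error rather than silently
producing empty residuals.

Temporal SNR (`compute_tsnr()`) is computed on the *raw* series, before any
regression — after residualization the mean is zero and the ratio is
meaningless. The SD uses denominator $n-1$; zero-variance units are
excluded from the summary and counted.

## Connectivity

`fc_matrix()` computes Pearson correlations over the surviving frames and
applies the Fisher z transform ($\operatorname{atanh}$), which makes
correlation values approximately variance-stabilized for averaging and
group statistics. Perfect correlations ($|r| \ge 1 - 10^{-12}$) are
clamped to $\operatorname{atanh}(1 - 10^{-12})$ and flagged; zero-variance
regions produce `NA` entries and are reported, never silently zeroed.
Homotopic (left–right mirror-pair) strengths are read from an explicit
partner mapping in the ROI table rather than inferred from label parity —
atlas numbering conventions differ, and a silent parity assumption is a
classic source of wrong-pair errors. Seed maps average bilateral seed
regions into one series before correlating. Group-average maps average the
z-transformed values (transform first, then average).

## Association statistics

The cohort-level battery mirrors the three questions a motion-evaluation
study asks:

* **Is connectivity coupled to motion?** Pearson correlation between
  per-scan mean FD and network strength (`fd_fc_association()`), per edge
  over the whole connectome (`edgewise_fd_association()`), and between
  cohort-mean edge strength and inter-ROI Euclidean distance
  (`distance_dependence()`).
* **Does motion bias group maps?** A quartile split by mean FD
  (`split_by_motion()`; group size $\lfloor 0.25 n \rfloor$, ties broken by
  scan id so the split is deterministic; groups re-derived per censoring
  condition), per-unit two-sample t tests in the high > low direction with
  Benjamini–Hochberg FDR (`group_contrast()`), and a one-way ANOVA with
  post hoc t tests comparing the group difference across censoring
  conditions (`strength_comparison()`). Student's pooled-variance t is the
  default with Welch behind a flag, since the classical map-contrast
  literature does not specify the variant.
* **Does motion mask developmental effects?** Bootstrap comparison of the
  simple PMA–strength correlation against the first-order partial
  correlation controlling mean FD (`pma_association()`; partial correlation
  via double residualization — residualize both variables on FD, then
  correlate). Each of the 5000 default replicates draws 50% of scans
  *without* replacement (the resampling scheme is subsampling, not the
  classic bootstrap; a flag switches). One-sample t tests on the replicate
  distributions assess each correlation; a paired t test assesses the
  partial-minus-simple increment.

## The synthetic cohort

Real neonatal scans cannot be redistributed, so validation rests on a
generator whose ground truth is exact. Its defaults are the study
conditions the package is designed around: 149 scans × 200 frames at TR
2 s, 90 ROIs, PMA 37.7–47.7 weeks.

**Geometry.** Half the ROI centroids are drawn in the right hemisphere
(x between 20 and 60 mm — mirrored partners are then at least 40 mm apart,
as real homotopic cortical pairs are) and mirrored across the midline; the
partner mapping is recorded explicitly.

**Ground-truth covariance.** $\Sigma = h P + (1-h) K$, where
$K = \exp(-d/\lambda)$ is a distance-decay kernel ($\lambda$ = 40 mm) and
$P$ the block matrix of homotopic pair factors. Both terms are positive
semidefinite with unit diagonal, so $\Sigma$ is a valid correlation matrix
by construction for any pair-factor weight $h \in (-1, 1)$; the naive
alternative — overwriting homotopic entries of the kernel — is not
positive definite at realistic sizes. The realized homotopic correlation is
$h + (1-h)K_{ij}$ and is recorded exactly in the `GroundTruth` object; all
recovery tests compare against that recorded matrix. The weight $h$ shifts
with postmenstrual age on the z scale (`pma_slope`, default 0.02/week about
the range midpoint), emulating connectivity growth.

**Motion.** Each parameter follows a small random walk (step SD 0.06 mm)
plus sparse single-frame surges: per frame, with scan-specific probability,
a total displacement drawn half-normal (scale 2.2 mm × a scan-level
log-normal multiplier, SD 0.8) is split across a random parameter subset.
Scan-level heterogeneity is deliberately split between *rate* (log-normal,
SD 1.2, capped at twice the nominal rate) and *amplitude*: a purely
rate-driven model cannot reproduce the empirical pattern of neonatal
cohorts, where the most extreme scans reach mean FD near 1 mm while losing
only a modest fraction of frames to censoring — extreme movers move
*bigger*, not proportionally more often. The rate cap also guarantees every
scan retains a full 4-minute window at the strict threshold, so censoring
conditions never differ in frame count across scans. At the defaults a
149-scan cohort has mean FD ≈ 0.11 ± 0.11 mm (maximum ≈ 1 mm), dropping to
≈ 0.065 and ≈ 0.05 mm after 0.5 and 0.2 mm censoring.

**Artifact and noise coupling.** At frame $i$ every ROI receives a shared
artifact $g_a \mathrm{FD}_i^2 w$, with fixed signed per-ROI weights $w$,
and white noise with SD $g_d \mathrm{FD}_i$. The quadratic FD dependence
makes the artifact excursion-dominated: sub-threshold frames carry little,
which is what gives censoring its leverage. (A linear coupling spreads
artifact into quiet frames that survive even strict censoring, and the
residual coupling then floors at the strict threshold instead of
shrinking.) The default gain $g_a = 16$ was set by a power analysis of the
recovery design — it is the weakest of the surveyed values at which the
censoring-recovery ordering (below) is reliably detectable at 60 scans —
not an estimate of any real artifact magnitude, which is unknown. The
named networks carry fixed weights: the motor pair $(+1, +1)$ (shared
artifact inflates its homotopic correlation), the auditory pair $(+1, -1)$
(deflates it), the visual pair $(0, 0)$ (artifact-free), remaining ROIs
mild random weights. This reproduces the empirical observation that the
direction of the FD–FC association differs across networks.

**Age covariate.** PMA is drawn uniformly from the master seed,
independently of every motion draw, so FD–PMA correlations are null by
construction. Per-scan seeds are `master seed + scan index`, making any
single scan regenerable.

**What the generator does not emulate.** No respiratory or cardiac
waveforms, no spin-history or EPI-distortion physics, no spatial structure
within ROIs (the optional NIfTI writer gives each ROI a two-voxel block
purely to exercise the image path), and noise attenuation acts on all
pairs — so the "visual" network is artifact-free but not attenuation-free,
and its FD–FC association is weakly negative rather than exactly zero in
strongly-moving cohorts. Passing recovery tests therefore demonstrate that
the pipeline removes the couplings the generator injects; they cannot
certify performance against physiological artifact classes the generator
does not model.

## Validation properties

The test suite asserts, among others:

* FD equals an independent straight-loop implementation of the formula on
  1000 random traces (1e−12); FD is offset-invariant and ignores rotations
  at radius 0.
* A 0.15 Hz sinusoid is attenuated to ≤ 1% and a 0.03 Hz sinusoid retained
  ≥ 95% by the joint projection (empty nuisance set); residuals are
  orthogonal to all design columns (1e−8 relative).
* With artifact couplings switched off, `fd_fc_association()` rejects at
  5% ± 3 SE and the group contrast at 1% ± 3 SE (200 cohorts of 40 scans,
  10 ROIs, 120 frames).
* With couplings on (20 cohorts of 60 scans), tSNR falls with motion,
  |r(FD, FC)| decreases monotonically across none → 0.5 mm → 0.2 mm, and
  the Frobenius error of the cohort-mean FC matrix against the recorded
  ground truth shrinks after strict censoring — each in ≥ 90% of cohorts.
* The BH step-up mask matches a hand-computed oracle exactly, and the
  empirical false-discovery proportion stays at or below the nominal level
  on signal + independent-null mixtures.

Cohort sizes in the test suite (40–60 scans, 8–20 ROIs, 120–200 frames)
are chosen so the whole battery, including the 200-cohort calibration,
completes in about a minute while keeping every Monte-Carlo band at 3
standard errors.

## Numerical and design choices

* Perfect correlations clamped at $1 - 10^{-12}$ before `atanh`; clamped
  entries flagged.
* CSF principal components are sign-fixed (largest-magnitude loading
  positive) so designs are reproducible across platforms; columns centred,
  not variance-scaled.
* Backward differences use first-row 0.
* Cleaning runs on the full series; frames are dropped only afterwards for
  connectivity. No interpolation of censored frames.
* Motion-file dialects (degree-valued rotations, rotation-first column
  order) are handled only behind explicit reader flags — never guessed.
* All cohort randomness funnels through one master seed; every pipeline
  manifest records the full configuration and seed, which is sufficient to
  reproduce a run exactly.

## Limitations

The analysis operates at ROI scale (seed maps accept any "unit" grid, so
voxel-level maps work where memory allows, but no spatial smoothing or
cluster-extent inference is provided). Slice-timing, distortion and
registration corrections are upstream of this package. The ANOVA across
censoring conditions compares per-unit group differences over a common
unit set selected in the uncensored condition; with few significant units
its power is limited. Motion-parameter interpolation, DVARS, and
ICA-based denoising are out of scope.
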