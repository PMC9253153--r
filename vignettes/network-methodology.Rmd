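---
title: "Estimating the fear-of-movement / neck-kinematics network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the fear-of-movement / neck-kinematics network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(necknet)
```

## The scientific problem

Neck pain is multifactorial: fear of movement (kinesiophobia, measured by the
Tampa Scale for Kinesiophobia, TSK) coexists with reduced range of motion
(ROM), slower and less smooth movement, impaired proprioception, and reduced
muscle strength. Simple pairwise correlations between one physical measure
and fear confound shared associations among the kinematic measures
themselves. `necknet` implements the alternative: a Gaussian graphical model
(GGM) over six participant-level features — TSK, joint position error (JPE),
ROM, movement velocity, movement smoothness (SPARC), and neck strength — in
which an edge is the *partial* correlation between two features after
conditioning on all others.

## From raw signals to the feature table

Each participant performs ten cycles of neck movement per plane
(flexion–extension, rotation, lateral flexion) recorded as joint angles at
100 Hz. Processing follows the standard cervical-kinematics chain:

1. **Filtering** — zero-phase (forward–backward) Butterworth low-pass, 10th
   order per pass, 10 Hz cutoff. We add odd-reflection padding before
   `signal::filtfilt`, because without it start-up transients of a 10th-order
   filter corrupt several hundred milliseconds at each end (a constant input
   came back with errors of ~12°; with padding, `< 1e-6`°).
2. **Neutral reference** — the median angle over the first 0.5 s of the
   recording. This assumes recordings begin at rest, which the synthetic
   generator honours with a 1 s lead-in.
3. **Differentiation** — central differences (one-sided at the ends).
4. **Cycle detection** — angle extrema at zero crossings of the velocity,
   subject to a prominence of 30 % of the maximal excursion; a movement is
   one extremum-to-extremum transition.
5. **Movement segmentation** — each movement is trimmed to where its speed
   exceeds 5 % of that movement's peak speed.
6. **Features per movement** — ROM (maximal absolute excursion from
   neutral), mean absolute velocity over the trimmed segment, and SPARC.

**SPARC** (spectral arc length) measures smoothness as the negated arc
length of the normalized magnitude spectrum of the speed profile: with
$\hat V(f) = V(f)/V(0)$ from a zero-padded FFT, an adaptive cutoff
$f_c = \min(20\,\mathrm{Hz},\ \max\{f : \hat V(f) \ge 0.05\})$, and

$$\mathrm{SPARC} = -\int_0^{f_c}\sqrt{\left(\tfrac{1}{f_c}\right)^2 +
\left(\tfrac{d\hat V}{df}\right)^2}\,df .$$

Parameters (20 Hz maximal cutoff, 0.05 amplitude threshold, 4 levels of zero
padding) are the established defaults of the metric. SPARC is invariant to
amplitude scaling and strictly decreases as oscillatory contamination grows.

Whether ROM should be peak-from-neutral or peak-to-peak, and whether SPARC
should be computed per half-cycle or per full cycle, is underdetermined; we
use peak-from-neutral and per directional half-cycle, mirroring the six
directional entries that are averaged into each kinematic node.

Proprioception (JPE) is the mean absolute repositioning error over six
marked head-relocation trials; strength is the mean of the flexion and
extension MVC peak forces; TSK is a questionnaire total (17–68). Kinematic
nodes are unweighted means over the six movement directions.

## Network estimation

Features are first Gaussianized with the **nonparanormal transformation**:
column-wise empirical CDF (average ranks over $n$), truncated to
$[\delta_n, 1-\delta_n]$ with $\delta_n = 1/(4 n^{1/4}\sqrt{\pi\log n})$,
mapped through $\Phi^{-1}$, and rescaled to unit SD. Ranks are preserved;
only the truncation can merge the most extreme ranks into a tie, so Spearman
correlations are preserved to ~1e-3, not exactly.

The GGM is estimated by the **graphical lasso**: maximize
$\log\det\Omega - \mathrm{tr}(S\Omega) - \lambda\sum_{i\neq j}|\Omega_{ij}|$
over positive-definite precision matrices (diagonal unpenalized), via block
coordinate descent written in C++ for speed (a full 100-point path on six
nodes takes ~3 ms, which makes the bootstraps cheap). The penalty path has
100 log-spaced values from $\lambda_{max}$ (the largest absolute
off-diagonal correlation, where the graph is empty) down to
$0.01\,\lambda_{max}$, and the model minimizing the **EBIC**
$-2L + E\log n + 4\gamma E\log p$ is selected, ties going to the sparser
model. Edge weights are the partial correlations
$w_{ij} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$, with $|w| \le 10^{-8}$
treated as zero.

### The hyperparameter $\gamma$, and reproducing the published network

$\gamma = 0.5$ is the conventional conservative default and is what
`select_network()` uses unless told otherwise. The published analysis of
this cohort, however, was explicitly exploratory. On the printed correlation
matrix (`neck_pain_cor()`, $n = 100$) the two settings differ sharply:

```{r}
select_network(neck_pain_cor(), n = 100, gamma = 0.5)$edge_count
neck_pain_network()  # gamma = 0, the exploratory selection
```

$\gamma = 0$ (plain BIC) retains 12 of 15 edges and matches the published
weights to printed rounding (ROM–Velocity 0.36 vs 0.39, Velocity–SPARC 0.57
vs 0.58); $\gamma = 0.5$ prunes the network to the two strongest kinematic
edges. `neck_pain_network()` therefore defaults to $\gamma = 0$: it is the
setting under which the published numbers are recoverable from the printed
matrix. Note the reproduction is approximate by construction — the original
analysis transformed the raw data before correlating, while only the raw-data
Pearson matrix is printed; the largest residual discrepancy is the TSK–JPE
edge (0.17 here vs 0.10 published).

A by-product of the partial-correlation structure is a Simpson's-paradox
reversal: the marginal ROM–SPARC correlation is +0.14, but the edge is
negative once velocity is conditioned on. `simpson_decomposition()` shows
the same reversal non-parametrically by stratifying participants into
velocity tertiles.

## Centrality and stability

Node **strength** is the sum of absolute incident weights; **closeness** and
**betweenness** use shortest paths with edge length $1/|w|$ (Dijkstra /
Brandes via igraph, with equal fractional credit among tied shortest paths).
Raw coefficients are reported; z-standardization is a flag.

`bootstrap_edges()` re-runs the entire pipeline (transform, correlate,
select) on participant resamples and reports percentile 2.5 %/97.5 % bounds
per edge. `casedrop_bootstrap()` drops growing proportions of cases
(0.05–0.75 in steps of 0.05, a grid fine enough to resolve values such as
0.52) and correlates subsample centralities with the original; the **CS
coefficient** is the largest proportion at which at least 95 % of subsample
correlations stay at or above 0.7, cumulatively from the smallest
proportion. Resampling is always at the participant level, and all
procedures are bit-reproducible for a fixed seed. `sample_size_simulation()`
treats a fitted network as ground truth and reports sensitivity,
specificity, and weight recovery across candidate sample sizes.

## The synthetic cohort

No raw data accompany the study, so `cohort_spec()` defines a synthetic
cohort matching everything the analysis assumes: the six marginal means/SDs
of the neck-pain history group (e.g. velocity 61.6 ± 20.3 °/s, SPARC
−1.68 ± 0.11, TSK 35.0 ± 6.4), the printed 6×6 Pearson structure, and
realistic non-Gaussian marginals (right-skewed shifted-exponential JPE;
integer TSK clamped to 17–68) applied *after* Cholesky-based correlation so
ranks are preserved. Positive physical quantities are floored at 0.1 (a
~0.1 % tail event for velocity). A two-group version (85 with / 15 without
pain history) is available by building two specs, but the analysis pools
participants.

`generate_cohort_recordings()` expands a feature table into raw material:
per-plane cyclic waveforms driven by each participant's ROM and velocity,
relocation trials whose mean absolute error equals the participant's JPE
exactly, and flexion/extension peak forces averaging to the strength value.
Waveforms are raised-cosine half-cycles between the ±ROM end-ranges (period
$T = 4\,\mathrm{ROM}/\bar v$, so the noise-free mean speed equals the target)
with a 1 s neutral lead-in and smooth onset — a recording that started
mid-motion would defeat the neutral-reference rule. Self-paced timing
variability is a 5 % CV on cycle periods (the study reports no
within-participant variances; this is our choice). Reduced smoothness is
emulated with band-limited 8–15 Hz angular noise; its default RMS amplitude
(0.2°) was calibrated once so that standard extraction of the default
profile yields SPARC ≈ −1.69, matching the cohort's −1.68 ± 0.11, and a
fixed piecewise-linear curve inverts the (approximately monotone)
noise-to-SPARC response per participant. The generator emulates the
statistical structure of the cohort, not its physiology: no trunk
compensation, sensor drift, or direction-specific asymmetries, so passing
tests demonstrate correctness of the pipeline, not validity on real IMU
recordings.

## Numerical choices and degenerate inputs

* glasso convergence: elementwise change of the working covariance below
  1e-8 per sweep (1e-10 for single fits, giving $\lambda = 0$ agreement with
  direct inversion to ~1e-7); non-convergence raises an error.
* Correlation inputs are validated (symmetry 1e-10, exact unit diagonal,
  eigenvalues ≥ −1e-8); constant columns are rejected everywhere; resamples
  with constant columns are redrawn; case-dropping proportions whose
  subsample would fall below $p + 2$ cases are skipped with a warning.
* Centrality correlations that are undefined (constant centrality vector,
  e.g. an empty subsample network) are recorded as `NA` and count as
  failures toward the CS criterion.
* Movements whose segmentation fails are dropped with a warning; cycles are
  only counted at extrema exceeding 30 % of the maximal excursion.

## Problem sizes used in validation

The test suite validates the machinery at deliberately modest sizes chosen
for tight Monte-Carlo control: marginal/correlation convergence at
n = 100 000 draws; support recovery at n = 5000 with 20 replicates;
bootstrap CI behaviour over 200 replicate cohorts of n = 500 with 200
resamples each; case-dropping at n = 1000 with 40 subsamples per
proportion.

## Known limitations

* Edge bootstrap intervals inherit the shrinkage of the regularized
  estimator: they are centred on shrunken weights and **undercover** the
  true partial correlation (we measure ~88–89 % for a strong edge at
  n = 500 against a nominal 95 %). They rank edge variability well but must
  not be read as significance tests — a caveat the network-bootstrap
  literature itself emphasizes.
* EBIC-glasso retains occasional numerically tiny spurious edges even at
  n = 5000 (|w| < 0.05, at most a couple per fit); exact support recovery is
  not a property of the estimator at these sizes.
* TSK is treated as continuous after transformation; no mixed
  discrete–continuous graphical model is attempted, and the undirected
  network supports no causal claims.
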