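---
title: "Simulating and analysing small-world fNIRS neurofeedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing small-world fNIRS neurofeedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swnf)
```

## The problem

Closed-loop neurofeedback experiments that target a *global* network
property — here, the small-worldness of the frontal functional network
measured with fNIRS — involve a long computational chain: optical
intensities become hemoglobin concentrations, sliding windows of the
OxyHb series become correlation matrices, thresholding turns them into
binary graphs, graph metrics are normalized against degree-preserving
random nulls, and a baseline-anchored score is fed back to the
participant several times per second. Every stage has parameters, and
human datasets of this kind are rarely deposited. `swnf` implements the
full chain together with a synthetic-data generator whose ground truth is
known, so each stage — and the pipeline end to end — can be tested.

## The score and the metrics

For a window of the 35-channel OxyHb series, pairwise Pearson
correlations $r_{ij}$ are Fisher-transformed,
$Z_{ij} = \tfrac12 \ln\!\big((1+r_{ij})/(1-r_{ij})\big)$, ranked by
$|Z|$, and the top fraction $s$ of the $n(n-1)/2$ node pairs (the
*sparsity*, working value $0.3$, i.e. 178 of 595 pairs) become edges of
an undirected binary graph. With $C$ the node-averaged clustering
coefficient and $L$ the characteristic path length (mean over finite
pairs), the small-world indices are

$$\gamma = C/\langle C_{\mathrm{null}}\rangle, \qquad
  \lambda = L/\langle L_{\mathrm{null}}\rangle, \qquad
  \sigma = \gamma/\lambda,$$

where the null ensemble holds 30 Maslov–Sneppen degree-preserving
rewirings of the same graph. During training, each block provides its own
baseline: $\sigma$ is computed over the 15 s continuous-subtraction span
(mean $\sigma_{base}$, standard deviation $SD$), and every regulation
update is scored as

$$\mathrm{Score}_i = 50\,\frac{\sigma_i + 3SD - \sigma_{base}}{3SD},
  \qquad 0 \le \mathrm{Score}_i \le 100 .$$

Baseline performance maps to 50 and $\pm 3SD$ to the clamp bounds; the
session statistic reported by `session_summary()` is the mean regulation
score minus 50, i.e. baseline-relative feedback points. We adopt this
baseline-relative reading because group learning curves in this paradigm
are of order $\pm 3$ points, not 0–100; the raw mean is recoverable by
adding 50.

```{r score}
bs <- baseline_stats(c(0.95, 1.02, 1.08, 0.99, 1.06))
feedback_score(c(bs$sigma_base, bs$sigma_base + 3 * bs$sd), bs)
```

## What the generator emulates

`make_ws_graph()` builds the latent truth: a Watts–Strogatz graph on 35
nodes (one per channel) with lattice degree $k = 10$, chosen so the
lattice's density $175/595 \approx 0.29$ matches the working sparsity
0.3 — comparable edge budgets between truth and estimate. The rewiring
probability $p$ spans the regular ($p=0$) to random ($p=1$) continuum.

`gen_oxyhb()` draws channels from a zero-mean multivariate normal with
covariance $I + c\,A$ ($A$ the latent adjacency, coupling $c = 0.6$ by
default, eigenvalue-clipped to stay positive definite). This is the
simplest construction that makes connected pairs more correlated; it is
documented as not unique. On top of the neural component it layers what
contaminates real recordings: cardiac (1.2 Hz), respiratory (0.25 Hz)
and Mayer-wave (0.1 Hz) sinusoids with per-channel phases, $1/f$ pink
noise, per-channel linear drift, and sparse spike artifacts — all
configurable through `signal_gen_config()`.

`gen_session()` lays out the training protocol at 25.6 Hz: 120 s rest,
then 18 blocks of 15 s baseline, a 2 s stimulus gap (51 samples after
flooring the non-integer 51.2; the gap is excluded from every statistic)
and 25 s regulation. Rest and baseline samples follow the subject's
baseline graph ($p = 0.4$, a mid-continuum working state); regulation
samples follow a covariance blend toward the day's schedule graph. The
default schedules move the UP group toward the lattice
($p: 0.40 \to 0.15$ across the five days) and the DOWN group weakly
toward randomness ($0.40 \to 0.50$), with per-subject regulation-strength
multipliers drawn from $N(1, 0.15)$ and centred within the cohort.

The behavioral generator works at the level of per-subject condition
means (the group statistics of interest are subject-level summaries), with an
optional trial-level expansion into pseudorandom 18-block × 5-trial
tables. Post-minus-pre Stroop changes are drawn directly from the
configured group distributions (UP posttest $-60 \pm 45$ ms, DOWN
$9 \pm 77$ ms), follow-up accuracy changes likewise
($+2.48 \pm 4.69$ percentage points for UP), and the neutral condition
carries a shared practice-effect decrease. Pretest accuracy defaults to
$85 \pm 4\%$, deliberately away from the 100% ceiling so that the
$[0, 100]$ truncation cannot bias change scores by more than ~0.05
points.

What the generator does **not** emulate: hemodynamic response functions
and neurovascular coupling dynamics (the neural component is white in
time), scalp versus cortical signal layering (the emulated recordings had
no short channels), non-stationary strategy changes within a block, and
any spatial structure tied to real channel geometry. Tests passing on
this generator therefore demonstrate the correctness and sensitivity of
the *analysis chain*, not the physiological faithfulness of fNIRS
forward models.

## Calibration of the session-score target

The latent covariance contrast between baseline and a day-5 UP graph is
strong, while realistic group session scores are a few feedback points —
small relative to the within-block baseline SD. The generator therefore
exposes a calibration hook: the regulation covariance is
$\Sigma_{base} + v\,(\Sigma_{day} - \Sigma_{base})$, and
`calibrate_session_drift()` finds the global multiplier on $v$ at which
the *measured* group-mean session score of the full online pipeline hits
a target. The search is a secant iteration under common random numbers
(every evaluation reuses the same derived seeds), which makes the
measured mean a smooth, nearly linear function of the multiplier;
convergence takes two to four pipeline evaluations. The reported value is
always the pipeline's measured mean, never the target itself.

## Numerical choices

* **Fisher transform.** $|r|$ is clamped to $1 - 10^{-7}$ before
  $\operatorname{atanh}$ so duplicated channels stay finite; matrix
  diagonals are zeroed (self-correlations are excluded downstream).
* **Thresholding.** Edge count is $\lfloor s \cdot n(n-1)/2 \rfloor$
  (never exceeding the stated sparsity); ties at the boundary are broken
  by ascending (row, column) index for bit-reproducibility. Because only
  the rank order of $|Z|$ matters, ranking by $|r|$ or $|Z|$ yields the
  same graph — a property the tests assert.
* **Band-pass.** The 5th-order Butterworth band-pass (0.01–0.2 Hz at
  25.6 Hz sampling) is realized as a cascade of a 5th-order high-pass
  and a 5th-order low-pass: the single transfer-function band-pass is
  numerically unstable at a passband this narrow relative to the
  sampling rate. Offline filtering is zero-phase (forward–backward);
  the online variant is strictly causal, as a real-time system requires.
* **Disconnected graphs.** Path length uses the finite-pairs rule
  (disconnected pairs excluded from numerator and denominator), applied
  identically to observed and null graphs so $\lambda$ stays comparable;
  an edgeless graph is an error.
* **Nulls.** Maslov–Sneppen double-edge swaps, at least 10 successful
  swaps per edge, connectivity not enforced; $\gamma$ and $\lambda$ use
  ensemble means. Swap saturation degrades to a warning carrying the
  achieved count.
* **Online refresh.** The nominal 3 Hz refresh is an 8-sample step at
  25.6 Hz (3.2 Hz), the closest integer step; scaled-down simulations
  thin it by an integer stride.
* **Degenerate statistics.** Zero-variance samples with zero effect are
  reported as $t = 0$, $p = 1$ (nothing to detect); a degenerate score
  baseline ($SD = 0$) is a refusal, since the score divides by it.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script keep simulation sizes modest by
design: behavioral recovery uses 500 cohorts of 17 subjects;
the end-to-end session reproduction uses one 17-subject day with every
4th refresh and 10 nulls per window (the full-rate, 30-null engine is
exercised on single blocks); rewiring-probability reference curves use
30–100 graphs per grid point. These sizes hold Monte-Carlo error
comfortably inside the tolerances asserted alongside them.

## Open choices resolved

* The clustering coefficient is the node-averaged Watts–Strogatz
  definition (the first of the two conventions common in brain-network
  toolboxes).
* The absolute-value sign convention for thresholding is applied to both
  the online and offline paths.
* Whether the online training data were motion-corrected is unstated;
  the online chain defaults to filter-only, with correction available
  behind a flag.
* The fixation cross is treated as per-trial (0.5 s before every word),
  which reproduces the printed 9-minute total with the mean 19 s rest;
  per-block fixation remains available as a schedule option.
* Edge-wise group tests operate on per-subject mean Fisher-z values
  (binary-presence mode is a flag); selection for drawing uses
  unadjusted $p < 0.01$, with BH adjustment available.
* The repeated-measures correlation of the power computation defaults to
  $\rho = 0.5$ and sphericity to $\varepsilon = 1$ (the conventions of
  the a-priori computation being reproduced).

## Limitations

Recovered rewiring probabilities are family-relative: they place an
observed $(C, L)$ pair within a simulated Watts–Strogatz family of
matched $(n, k)$ and should not be read as biophysical parameters.
The score simulation reproduces group-level session statistics; it makes
no claim about individual learning dynamics. And because the generator's
neural component is temporally white, absolute correlation magnitudes —
and hence absolute $\sigma$ levels at short windows — should be compared
between conditions, not to human data.
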