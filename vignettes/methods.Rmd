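---
title: "Models and methods behind lhbaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lhbaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lhbaxis)
```

`lhbaxis` implements two linked analysis pipelines for the lateral
hypothalamus (LHA) to lateral habenula (LHb) projection system: (i) a
classification of projection neurons into electrophysiological types from
ex vivo patch-clamp recordings, and (ii) a quantification of aversive-state
signals in prefrontal (mPFC) population recordings acquired during a
four-block head-fixed protocol (tone; tone + optogenetic activation of the
pathway; tone; novel sound + air puff). Because the real recordings are not
required here, a synthetic-data module generates every input with known
ground truth, which is what all calibration and recovery tests run on.

## The sweep simulator

Whole-cell responses are generated by an adaptive exponential
integrate-and-fire (AdEx) neuron,

$$C\dot V = -g_L(V-E_L) + g_L\Delta_T e^{(V-V_T)/\Delta_T} - w + I,\qquad
\tau_w\dot w = a(V-E_L) - w,$$

with reset $V\to V_r$, $w \to w + b$ at a spike, integrated by forward
Euler (compiled) with a 2 ms refractory clamp. The six archetypes (FA-Bk,
Burst, RS-N, LS-N, LS-W, RS-W) use the classical AdEx regimes: strong
spike-triggered adaptation for the fast-adapting type, a depolarised reset
with large $b$ for the burst type (doublet onsets), plain tonic parameters
for regular spiking, and negative subthreshold coupling $a<0$ for the
late-spiking types, which delays the first spike of a depolarising step.
Because a bare integrate-and-fire trace carries no spike shape, a
stereotyped action-potential waveform (sinusoidal rise, cosine fall, an
exponentially recovering afterhyperpolarisation, optionally an
afterdepolarisation hump) is added at every spike as a deviation that
decays back onto the subthreshold trajectory; its parameters are per
archetype, so half-width, up/downstroke and afterpotential features are
measurable and type-specific. Spontaneous cell-attached traces are
gamma-renewal spike trains (shape 4, i.e. fairly regular) rendered as
biphasic waveforms on unit-variance noise; every archetype fires tonically.

Per-neuron variability is a single jitter knob: multiplicative log-normal
jitter (default CV 0.1, a typical within-type spread for intrinsic
parameters) on conductances, capacitance, time constants and waveform
widths, and additive jitter (1 mV at the default) on voltage parameters.
All draws come from one seeded generator per call; identical seed and
configuration give bit-identical output.

The default protocol holds the cell at -70 mV (the holding current is
computed analytically from the steady state), applies 1-s steps at -40,
-20, +20 pA and a +40..+560 pA ladder in 20 pA increments at 20 kHz, and
records 100 ms before and 150 ms after the step. The ladder top was chosen
so that twice the rheobase of every archetype falls inside it. Small white
current noise (2 pA s.d.) is on by default; the integration is verified
against an independent Euler reference at ten-fold finer time step with
noise off.

## Intrinsic-feature extraction

The extractor reproduces the standard definitions: input resistance is the
least-squares slope of steady-state deflection (mean of the last 100 ms of
the step; by then the transient has decayed for any plausible membrane
time constant) against the two +/-20 pA currents; the membrane time
constant is a single-exponential fit (Levenberg-Marquardt) to the averaged
onset of up to twenty -40 pA responses; AP threshold is the voltage where
the upstroke first reaches 10 mV/ms, found by walking back from the peak;
rise time is threshold-to-peak; half-width is measured at half amplitude
with linear interpolation at the crossings; up/downstroke are the extrema
of the central-difference derivative. Afterpotentials are classified from
the capped (20 ms) post-spike segment — ADPs are fast events, and a wider
window would misread the partial recovery of a deep fast AHP under slow
adaptation as an ADP-plus-concave-AHP complex: a single trough with no rebound of
at least 0.5 mV is a convex AHP (amplitude measured from AP threshold to
the trough — the reference point is a package convention, as is measuring
the concave AHP from the ADP peak); a trough followed by a rebound hump
and a later trough is an ADP + concave AHP. Firing-pattern features come
from the rheobase sweep (counts split at the step midpoint), the sweep
closest to twice rheobase (first/second ISI as instantaneous frequencies,
adaptation ratios oriented last ISI over first and last over second — the
orientation is configurable since either reading of "ratio of the last two
ISI relative to the first" is defensible) and the maximal-frequency sweep
(post-step voltage deviation over 150 ms). Missing features are `NA`, never
silently zero; a separate `impute_features()` step encodes structural
absences (e.g. no ADP) as explicit zeros before clustering.

## Consensus cell typing

Feature matrices are normalised in four steps (shift positive by the
column minimum; divide by the column sum and scale by 10,000; `log1p`;
z-score), reduced to four principal components, and clustered twice: Ward
hierarchical clustering cut at six clusters, and Louvain communities on a
shared-nearest-neighbour graph (k = 20, Jaccard edge weights pruned at
1/15, resolution 1.5). The two labelings are aligned by maximum-overlap
assignment (exhaustive over permutations up to eight clusters); cells on
which they disagree are discarded. Accuracy against a reference labelling
is the percentage assigned to the matched cluster; its chance level is the
mean accuracy over 10,000 random shuffles of the aligned labels, which for
fixed marginals has expectation $\sum_i p_i q_i$ — the closed form the
tests check against. The 2-D embedding is an exact (dense-gradient) t-SNE
of the four PCs, written in the package because the datasets are small
(hundreds of cells) and determinism under a seed matters more than speed;
perplexity is reduced automatically when the sample cannot support 30.
Soma profiles are scored as E = X/Y and T = Ymajor/Yminor with the 1.8 and
1.2 thresholds.

On the default synthetic conditions (40 neurons per archetype, CV 0.1
jitter) the consensus labels recover the generative archetypes with
adjusted Rand index above 0.9 over repeated seeds — the headline recovery
property in `tests/testthat/test-acceptance.R`. Passing it shows the
pipeline separates types whose differences survive feature extraction; it
does not show that real LHA-LHb neurons are this separable, since the
generator draws independent jitter and has no recording artefacts,
electrode drift or cell-health gradients.

## The population generator

In vivo datasets are inhomogeneous Poisson spike trains with
piecewise-constant rates: per-unit baseline (log-normal, median 5 Hz)
times a per-block multiplier, times an event gain inside each
event-response window (200 ms for sounds, 500 ms for the optogenetic
train and the air puff — the same windows the GLM uses). Blocks default to
the protocol's 50/100/50/50 trials. Two deliberate departures from a bare
Poisson process: a 2 ms absolute refractory period is enforced by
dead-time thinning, because a pure Poisson train at 5 Hz would violate the
pipeline's own ISI-violation QC rule; and each trial is extended by a
uniform multiple of 100 ms up to 1 s (seeded), because a perfectly
periodic event schedule would let circular shifts by whole trials map
event windows onto themselves and degenerate the surrogate null. Both
choices mimic properties any real session has (refractoriness, jittered
inter-trial timing). Ground-truth gains are stored for recovery tests.

## Single-unit tuning

After QC (rate > 0.1 Hz, ISI violations < 1% at a 2 ms bound) and linear
clock-drift correction, each unit's session is binned at 100 ms and fitted
with a Poisson log-link GLM on four binary regressors (tone, optogenetic
stimulation, novel sound, air puff) plus intercept. The standard design is
a partition (binary, mutually non-overlapping), for which the Poisson MLE
has the closed form $\beta_j = \log \bar c_j - \log \bar c_0$ (group mean
counts over baseline); the package uses it and falls back to `stats::glm`
otherwise, and a test asserts the two agree to 1e-8. The surrogate null
rotates the binned count vector by a uniform random offset (1,000
surrogates; rotation preserves the counts exactly) and refits — for the
partition design that is a set of group sums evaluated by direct indexing,
identical to the explicit refit and cheap enough to calibrate on thousands
of units. Tuning scores are z-statistics against the null; significance
uses the 99.9th/0.01st null percentiles estimated with the $(n+1)p$
order-statistic convention, under which the positive rule has its nominal
0.1% tail mass at 1,000 surrogates (the interpolating default would roughly
double it). Primary/secondary tunings rank absolute scores; a unit is
comodulated when they are the optogenetic and air-puff regressors, both
significant.

Conditioned units run four paired Wilcoxon signed-rank tests (tone and
opto in block 2 on the even-indexed 50 of its 100 trials; novel sound and
air puff in block 4) comparing 500 ms pre-sound baseline with 500 ms
post-event rates at a Bonferroni-corrected alpha of 0.001/4, requiring
both of a block's tests to pass. Optotagging requires a response in more
than 10% of pulses within the 10 ms post-pulse bin, a waveform correlation
above 0.9 when waveforms are available, and a latency test: the mean
first-spike latency after the pulses (censored at 100 ms) compared with
199 circularly shifted pulse trains, add-one permutation p, strict
p < 1%. The stimulus-associated latency test used with these recordings is
external software; this permutation construction is the package's own and
is required (and verified) to keep its false-positive rate at or below 1%
on 2,000 laser-independent units.

## Population dynamics

Trial-averaged activity matrices are built per block on a 10 ms grid over
(-0.1, 3) s (310 bins per block) or coarser grids as each analysis
requires; Gaussian smoothing is explicit discrete convolution
(zero-padded) and is tested against a double-loop oracle at 1e-12. Two
conventions coexist and are explicit arguments: z-score then smooth
(sigma 2 bins) for PC trajectories, smooth (sigma 0.8) then z-score
across blocks for activity clustering. Activity clustering drops units
with fewer than 200 active (>= 0.5 Hz) bins — the package reads the
protocol's "active" as at-or-above that rate, since the printed inequality
as written would count silent bins as active — takes the top 20 PC scores
per unit, applies Ward linkage, and cuts the tree into a configured number
of flat clusters (default 15, matching the reported cluster count; a
literal "depth of ten children" rule is ambiguous between tree depth and
split count, so the parameterised cut is the implementation and this note
the record of the alternative). Clusters are named by their units'
dominant primary tuning, or "state" when baseline activity shifts
significantly between the first and last block.

Activity modes are linear-SVM weight vectors (hinge loss, cost 1,
class-balanced, no kernel — no hyperparameters are given, so the plainest
linear machine is used) for three contrasts on mean-subtracted 50 ms
activity: sound (200 ms before vs after onset), an aversive contrast, and
state (1 s pre-sound baseline, block 1 vs block 4). The aversive contrast
has two readings and both are provided: "opto OR air puff" discriminates
the pooled aversive epochs from the matching epochs of the control blocks,
"opto AND air puff" discriminates the optogenetic from the air-puff
epochs. The three vectors are orthogonalised by QR (signs aligned with the
raw vectors); projections are $W^\top X$ per block, with group-restricted
projections using the corresponding rows of W only.

Decoding bins the (-2.1, -0.1) s pre-trial baseline at 100 ms, z-scores
within unit, drops units without baseline spikes, and classifies single
time bins by block with an L2-regularised logistic regression (ridge,
fixed penalty 0.01 — small enough to be near-unregularised, large enough
to keep separable subsets stable), over 50 repeats of stratified twofold
cross-validation at subset sizes from 5 units up to the population size.
With balanced blocks and identical baselines the mean accuracy stays
within the binomial confidence band of 50% at every subset size; this is
the first acceptance quantity. The paper's block 2 has twice the trials of
block 1, which would move the no-information rate of bin-wise
classification to 2/3, so chance-level checks here use equal-sized blocks.

PC trajectories project pooled per-block activity (time bins as
observations, units as variables) onto three common components and then
restrict the loadings per genotype; a stability test checks that two
random unit subsets give trajectories differing by less than 10% of the
trajectory extent.

## Estimation statistics

`bootstrap_mean_difference()` resamples each group with replacement
(default 5,000 resamples), reports the percentile 95% CI of the mean
difference, and a two-sided permutation p-value: the proportion of
shuffled-group comparisons at least as extreme as the observed difference,
with add-one correction. (A literal "proportion outside the CI" rule is
degenerate for strong effects — every null comparison lies outside a CI
centred on a large effect — so the package computes the standard
permutation test that the estimation-graphics software it emulates uses.)
Coverage of the CI is approximately 95% on Gaussian simulations at n = 20
per group — slightly under, as percentile intervals are at small n — and
is the second acceptance quantity. The stress index is the equal-weight
mean of the three behavioural z-scores (marble burying, looming aversive
time, forced-swim immobility) against a reference cohort; the formula is
not specified by the protocol, so the z-composite (weights configurable,
normalisation cohort explicit — within-sex or pooled is the caller's
choice) is this package's definition and is flagged as such in the
function documentation.

## Problem sizes and numerical choices

The test-suite defaults are desk-scale: 240 simulated neurons (40 per
archetype) for typing over five seeds; 40-500 units per simulated session
for tuning and decoding; 2,000 units for the two calibration studies;
1,000 simulations for bootstrap coverage. Tie-breaks are deterministic
throughout (nearest-neighbour ties by index order, PCA signs by the
largest-magnitude loading, label matching by exhaustive assignment);
degenerate inputs (constant feature columns, zero-s.d. nulls, silent
units, truncated afterpotential windows) produce explicit zeros, `NA`
flags or errors rather than silent values. Known limitations: the
generator's archetypes are caricatures constrained only by qualitative
phenotypes and tonic-rate ranges, the Poisson units carry no slow
non-stationarities beyond block gains, and the soma generator produces
idealised ellipse/triangle profiles; calibration results transfer to real
recordings only to the extent those simplifications hold.
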