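---
title: "Population analysis of representational maps under targeted microablation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population analysis of representational maps under targeted microablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftmap)
```

## The problem

Layer 2/3 of mouse auditory cortex encodes the relationships between sounds
in a *representational map*: the pattern of pairwise similarities between
population responses to different stimuli. Individual neurons drift — they
gain and lose sound responsiveness and reshape their tuning from day to day —
yet the population-level map is remarkably stable. Targeted two-photon
microablation of a few tens of selected neurons perturbs this equilibrium,
and the way the map degrades and recovers over the following days reveals
which single-neuron changes carry the disturbance and which carry the
recovery.

`driftmap` implements the full analysis chain for such longitudinal
imaging-plus-microablation experiments: event extraction from raw traces,
per-neuron responsiveness classification, tuning statistics, similarity
matrices and their summaries, microablation target selection with the
spared-network exclusion rules, and the permutation machinery used for
inference. A synthetic cohort generator with exportable ground truth stands
in for raw imaging data, so every stage has a parameter-recovery test.

## Experimental design assumed by the pipeline

* 34 stimuli: 19 pure tones of 50 ms covering 2–45 kHz in quarter-octave
  steps and 15 complex sounds of 70 ms; 10 trials per stimulus per session
  (`build_stimulus_set()`).
* Seven imaging sessions per field of view (FOV) on days 1, 3, 5, 7, 9, 11
  and 15; the (sham) microablation happens on day 6. Days 1–5 are baseline.
* FOVs of 367 × 367 µm containing roughly 140–180 tracked neurons, ~10–14%
  of them significantly sound responsive on a given day, ~10% inhibitory.
* Four cohorts: `responsive_ablation`, `nonresponsive_ablation`,
  `inhibitory_ablation` and `control` (sham). Mice are the independent
  observations in all cohort-level statistics.

## From traces to trial amplitudes

When raw fluorescence is the input, `compute_dff()` subtracts the neuropil
trace scaled by a contamination ratio and divides by a running baseline F0 —
the 30th percentile of the 200 surrounding frames (100 before, 100 after; at
the trace edges the available window is used rather than dropping frames).
Frames with non-positive F0 are masked, not propagated. `extract_amplitudes()`
then computes each trial's evoked amplitude as the mean ΔF/F over the two
frames 200–400 ms after stimulus onset minus the mean over the two frames
−200–0 ms (exactly two frames each at the 5 Hz frame rate). Trials whose
windows leave the trace are masked and logged. The synthetic generator
produces these amplitudes directly.

## Responsiveness classification

For every neuron × stimulus cell, the ten trial amplitudes are compared with
ten paired pre-stimulus values by a Wilcoxon signed-rank test
(`signed_rank_pq()`). Zero differences are discarded before ranking — the
dominant convention, which also changes the attainable minimal p-value (with
all ten differences of one sign the exact two-sided p is 2/2^10 ≈ 0.00195).
The exact null distribution is used up to n = 15 tie-free differences;
beyond that, the normal approximation with continuity and tie correction.
The protocol this pipeline follows does not pin down the test's sidedness;
we default to two-sided with a configurable alternative. Benjamini–Hochberg adjustment runs across the 34
stimuli within each neuron; a neuron is *responsive* when any adjusted value
falls below 0.05. A consequence worth knowing: a single minimally-attaining
stimulus (q = 0.00195 × 34 ≈ 0.066) is not sufficient for responsiveness;
at least two near-minimal stimuli are needed.

The best stimulus is the one with maximal trial-mean amplitude *among the
significant stimuli only*, and the best amplitude feeds the four standard
categories (0–15, 15–25, 25–55, 55–1000 %ΔF/F; left-closed, right-open;
values above 1000 clamp into bin 4 with a warning).

Cells with fewer than five usable pairs are excluded from the BH family.
Under a global null the per-neuron family-wise error of this procedure is
approximately the nominal 0.05, which the test suite verifies on null
simulations.

## Tuning statistics

*Split-half reliability and cross-day tuning correlation*
(`split_half_tuning_correlation()`): trials are split 5 + 5 per stimulus —
stratified, so both half tuning curves cover all stimuli, a choice the
source protocol leaves open — and the Pearson correlation of the half-mean
curves is averaged over ten random splits. Same-day halves measure response
reliability; one half from day 5 and one from another day measures tuning
retention. For half-means of five trials the expected same-day correlation
is the attenuation σ_s²/(σ_s² + σ_n²/5), which the acceptance suite checks
against simulation. Because the same attenuation multiplies cross-day
correlations, the ratio cross/same estimates the pure per-lag tuning
retention — the basis of `estimate_drift_rho()`.

*Tuning width* (`tuning_width_profile()`): each responsive neuron's curve is
sorted descending and normalized to its peak; the width statistic is the
normalized amplitude at sorted index 15 (0 for one-hot tuning, 1 for flat).

*Signal correlations* (`signal_correlations()`): Pearson correlations of
trial-averaged tuning curves over all unordered within-FOV pairs of
responsive neurons (pairs never span FOVs); a pair's amplitude category is
the bin of the mean of the two best amplitudes, and the headline readout is
the fraction of pairs with r > 0.7.

*Reference-tuning profiles* (`reference_correlation_profile()`): every
spared neuron is correlated with the day-5 tuning of the high-category
reference neurons, pooling each spared × reference pair. Neurons split into
group R5 (responsive on day 5) and group G (unresponsive on day 5,
responsive on some other day). Correlations are binned from −0.6 to 1.0 in
steps of 0.2 (below-range values are clamped into the first bin) and
baseline-subtracted (mean of days 1 and 3). The Methods text restricts the
profile to neurons responsive on the profiled day while the Results compute
it for all spared neurons; we follow the Results by default and expose
`responsive_on_day = TRUE` for the Methods-conformant variant.

## Representational maps

`similarity_matrix()` correlates population response vectors across
stimuli. In `single_trial` mode, element (s1, s2) averages the Pearson
correlations of all trial-vector pairs — same-trial pairings are excluded on
the diagonal, leaving C(10,2) = 45 pairs per diagonal element and 100 per
off-diagonal — so the diagonal measures trial-to-trial population
reliability. In `trial_averaged` mode vectors are averaged first and the
diagonal is exactly 1, isolating tuning structure from reliability.
`summarize_map()` grand-averages matrices across FOVs per day and reports
diagonal and off-diagonal means, raw and normalized to the baseline-day mean
(days 1–5 by default; configurable because ablation analyses sometimes
normalize to other pre-ablation sets). Off-diagonal averages count each
unordered stimulus pair once. `mds_embed()` applies classical (Torgerson)
MDS to 1 − r; coordinates are defined up to rotation and reflection, and
eigenvalues are returned so non-Euclidean inputs are visible.
`pairwise_decode()` trains a linear SVM per stimulus pair with stratified
five-fold cross-validation (every trial tested exactly once); the
regularization constant is fixed at C = 1, which the source does not state.
For cross-day decoding we keep the fold structure — train on the training
day's folds, test on the held-out fold of the test day — and share the
neuron mask between days so dimensionality matches.

## Microablation design

`select_targets()` implements the three targeting modes from the two
baseline sessions (days 3 and 5). For responsive targeting, each day's
responsive neurons are ranked by their mean amplitude over significant
stimuli, the two days' distributions are merged, sorted and deduplicated
keeping the higher-ranked entry; targets come from the top. The amplitude
key for a neuron appearing on both days is ambiguous in the source; we keep
the larger of the two day amplitudes (that is what "higher rank" in a merged
amplitude-sorted list implies) and expose `dedup_key` to switch.
Nonresponsive targeting ranks neurons responsive on neither day by absolute
amplitude per day, averages the two ranks and takes the smallest. Inhibitory
targeting applies the responsive criterion within interneurons and fills up
with the largest-amplitude nonsignificant ("apparent sound-responsive")
interneurons. Ineligible neurons (occluded nuclei and the like) carry an
`eligible = FALSE` flag the simulator can set.

`assign_categories()` defines the digital-exclusion sets that equalize
cohorts: the five highest-amplitude responsive neurons per FOV
(high-category) and the five minimum-|amplitude| nonresponsive neurons
(low-category). Ties break deterministically by neuron id.
`build_spared_mask()` excludes all targeted neurons (successful or not),
every neuron within 15 µm (3-d Euclidean, boundary inclusive — "within a
sphere of radius 15 µm") of a successfully ablated neuron, and the cohort's
applicable category sets.

## Inference machinery

`permutation_group_test()` permutes cohort labels of mouse-level values
(200 permutations by default), with the difference of cohort means as the
statistic and two-sided extremity by absolute value; p-values use add-one
smoothing. `fov_shuffle_similarity_null()` reassigns neurons to pseudo-FOVs
of the original sizes (500 draws by default), rebuilds trial-averaged
similarity matrices and reports the observed across-FOV off-diagonal mean
against the 2.5/97.5 percentile envelope; each draw preserves every
single-neuron tuning curve exactly. Percentiles use the (n+1)p order
statistic convention (type-6 quantiles), which keeps the envelope's
two-sided coverage at its nominal level. The shuffle operates on
trial-averaged curves; whether the original procedure shuffled trial-level
data is ambiguous and trial-averaged is the reading we implement.

`width_scaling_similarity_sim()` asks how much of an off-diagonal change is
attributable to tuning-width change alone: every neuron's sorted curve is
divided by its bin's baseline sorted-normalized profile and multiplied by a
target profile, preserving stimulus order and peak amplitude, and the
trial-averaged matrix is rebuilt. Scaling by the baseline profile itself is
an exact identity; a narrower target lowers the off-diagonal mean, a flat
profile raises it toward 1.

`stability_overlap()` measures responsiveness stability across consecutive
sessions. The denominator is not pinned down by the source; the default is
the union of the two responsive sets (so identical sets give 1 and disjoint
sets 0), with `"first"` and `"total"` as alternatives.
`spatial_effect_profile()` bins per-neuron effects by distance to the
nearest ablated neuron; empty bins are missing, never zero. `ei_balance()`
computes per mouse and day the excitatory share of "total response"
(responsive fraction × mean best amplitude per class).

## The synthetic cohort generator

`simulate_cohort()` produces a full dataset with the statistical structure
the analyses assume, and `export_truth()` exposes the ground truth. Design
choices, each with one knob:

* **Tuning latents.** Each neuron's 34-dimensional tuning latent is a
  weighted mixture of (i) a component with a fixed stimulus-similarity
  covariance — tonotopically smooth across the tone ladder with a common
  complex-sound block (`stimulus_similarity_kernel()`, weight
  `stim_structure_weight` = 0.35) — which makes the population-level map
  reproducible across days, FOVs and neuron subsets; (ii) `k_latent` = 5
  FOV-shared factors with nonnegative stimulus loadings and neuron loadings
  of mean `latent_loading_mean` = 0.5 (weight `latent_weight` = 0.25), giving
  each FOV a regional tuning bias so that local co-tuning exceeds what
  FOV-shuffling preserves; and (iii) private noise. The curve is a positive
  affine map of the latent (peak = the neuron's amplitude scale), so Pearson
  correlations between days equal latent correlations exactly — this is what
  makes drift estimation unbiased.
* **Drift.** All latent components evolve as a stationary AR(1) with
  per-2-day retention `drift_rho` = 0.85 (the 4-day gap before day 15 uses
  ρ²). Cross-day tuning correlations therefore decline gradually and
  symmetrically in the day gap.
* **Responsiveness turnover.** A drop/gain Markov chain started at its
  stationary distribution (p = 0.12, drop rate 0.25 per session, gain rate
  matched to stationarity), so day summaries are trend-free without
  ablation.
* **Amplitudes.** Per-neuron log-normal scale with meanlog = log(25) and
  sdlog = 0.963. The printed bin cut points (15/25/55) cannot be exact
  quartiles of any log-normal — the log-spacing is asymmetric around the
  median — so we average the two one-sided fits; the resulting occupancies
  (≈ 30/20/29/21%) sit within the reported ≈ 25 ± 7% spread.
* **Trial noise.** Additive Gaussian on amplitude (σ = 8 %ΔF/F);
  pre-stimulus baselines are zero-mean noise of the same scale. Raw-trace
  simulation is deliberately not part of the generator; `trace_bundle()`
  inputs are exercised with purpose-built traces in the tests.
* **Geometry.** Positions uniform in a 367 × 367 × 200 µm slab, so the
  15-µm exclusion sphere and distance profiles are exercised.
* **Inhibitory neurons** (10%) get a broader tuning offset (factor 1.5),
  giving the moderately broader tuning the data show.
* **Reproducibility.** One seed; every mouse/FOV/day/procedure draws from a
  named hash-derived sub-stream, so regenerating any subset is stable.

`inject_ablation()` adds ground-truth ablation effects on top, scaled per
neuron by exp(−d/`spatial_scale`) with d the distance to the nearest
successfully ablated neuron: a transient fractional SNR drop
(`reliability_dip`, recovery time constant `recovery_tau`), persistent
compression of below-peak tuning of pre-ablation-responsive neurons
(`narrowing_factor`), an increased gain rate (`gain_boost`), alignment of
newly responsive neurons' tuning with the ablated targets' mean tuning
(`gain_alignment`), and a transient excitatory/inhibitory amplitude
asymmetry (`ei_shift`). All effects vanish at their defaults, in which case
the spared-network data are returned bit-identical. Effect magnitudes are
not reported quantitatively by the source (figures are normalized), so the
values used in tests are chosen for testability and are not claims about
the data.

### What the generator does and does not emulate

It reproduces the counts, rates, drift structure, local correlation excess
and ablation phenomenology the analyses consume. It does not model calcium
indicator kinetics, spikes, noise correlations, spontaneous activity, or
imaging artifacts, and "nonresponsive" neurons carry no subthreshold
tuning. Passing tests therefore demonstrate that the pipeline measures what
it claims on data with known structure — not that the biological findings
are reproduced from raw data.

## Numerical choices and degenerate inputs

* Exact signed-rank null up to n = 15; zeros discarded; ties switch the
  affected cell to the corrected normal approximation.
* Correlations of zero-variance vectors are undefined: the pair is excluded
  from the statistic and counted, never silently zeroed.
* Amplitude bins are left-closed right-open; >1000 clamps with a warning.
* The 15-µm exclusion boundary is inclusive (a neuron at exactly 15 µm is
  excluded).
* Selection sorts are stable with neuron-id tie-breaks, so target selection
  is deterministic and input-order invariant.
* Similarity-matrix off-diagonal summaries count each unordered pair once.
* Heavy-tailed per-neuron effect ratios are winsorized at the 1/99th
  percentiles before spatial decay fitting (`estimate_spatial_scale()`).
* `estimate_drift_rho()` fits log(cross/same) ~ lag through the origin,
  weighting lags by the number of contributing FOVs and dropping
  non-positive ratios.

## Problem sizes used by the test and acceptance suites

The suites exercise the pipeline at the following sizes, chosen as the
smallest that make the statistical checks sharp: classification and oracle
checks on single FOVs of 40–300 neurons; the split-half attenuation check on
10,000 simulated neurons; null calibrations with 250–500 replicate
simulations; drift recovery on a 2-mouse default cohort; spatial-scale
recovery on an 8-mouse cohort (the per-neuron amplitude-ratio effect is
noisy, so this fit needs the larger cohort); and the ablation phenocopy at
the study's own scale (10 ablation vs 9 control mice, 7 FOVs each). The
phenocopy comparison uses the ±2 s.e.m. band of the control day course — the
envelope the day-course figures shade — rather than the min/max across
mice, which is unstable at cohort sizes this small.

## Known limitations

* The high-/low-category exclusion is conditioned on days 3 and 5, which
  systematically depresses baseline-day population statistics relative to
  later days (the excluded neurons are exactly the ones that dominated the
  baseline sessions). The same conditioning exists in the real design; in
  the generator it is more visible because "nonresponsive" neurons carry no
  subthreshold tuning mass. Cohort comparisons are unaffected — both cohorts
  share the artifact — but absolute normalized day courses should be read
  with this in mind.
* FOV inclusion reads "more than ten" responsive neurons strictly: exactly
  ten fails. The bound is configurable.
* Cross-day decoding assumes matched trial counts between the two days.
* The pipeline treats neuron identity across days as given; ROI tracking is
  upstream and out of scope.
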