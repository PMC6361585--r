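---
title: "Methods: valence-coding analysis of spike trains, calcium traces, and place conditioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: valence-coding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valencephys)
```

This vignette documents the statistical model behind `valencephys`, the
choices made where the analysis conventions of the field leave room, and
what the synthetic-data validation does and does not establish about real
recordings.

## The analysis problem

Midbrain valence-coding studies record extracellular units (e.g. in the
RMTg, a GABAergic afferent to dopamine neurons, or in the VTA) while
animals experience appetitive cues and aversive stimuli at two
timescales: phasic events lasting milliseconds to seconds (reward cues,
footshock, siren, bright light) and sustained states lasting minutes
(LiCl, restraint stress, cocaine).  The scientific claims rest on
per-neuron response classification — which units are inhibited by reward
cues, excited by aversive stimuli, biphasic across a sustained
stimulus's onset and offset — and on population summaries of those
labels.  The package implements that chain end to end, plus the matched
calcium-imaging and place-conditioning analyses.

## Unit acceptance

Two rules are applied before any response analysis.

*Refractory rule.*  The violation fraction is the number of spikes whose
preceding interspike interval is in `[0, 1 ms)` divided by the total
spike count; a unit passes iff the fraction is strictly below 0.002.
Both bounds are taken literally; the interval is half-open and the
threshold strict.

*Drift rule.*  No specific trend statistic is canonical for "significant
drift", so the package uses the Spearman rank correlation of per-window
baseline rate against window index (two-sided, α = 0.05, 20 equal
windows by default).  It is distribution-free, which matches the overall
preference for rank statistics on spike-count data, and it calibrates
correctly on homogeneous Poisson trains (null flag rate ≈ 5%, verified
over 1000 simulated units in the test suite).  The same mechanism serves
for cross-session baseline decline by passing session-level baselines as
the windows.

*Shock blanking.*  The first 10 ms after each footshock onset is removed
— the shock itself lasts 10 ms and contaminates the electrode.  Blanked
intervals are carried on the train and subtracted from effective bin
durations downstream, so a half-blanked 50 ms bin contributes a rate
over 40 ms rather than a spuriously low rate over 50 ms.  Blanking is
idempotent and merges overlapping windows.

## PSTHs and normalization

`align_and_bin()` counts spikes in half-open bins `[edge, edge + w)`
relative to event onset; a spike exactly on an edge belongs to the
right-hand bin (enforced against floating-point division error by a
1 ns-scale epsilon).  The phasic convention is 50 ms bins with a 1 s
pre-stimulus baseline; the sustained convention is 5 min bins with a
15 min baseline.  Both run through the same code path — the test suite
exercises the 5-min-bin variant explicitly.

The baseline "normalization" is not fully pinned down by convention, so
two dialects are provided and recorded in the output:

* **z-score** (default): each bin's trial-mean rate minus the mean of
  the baseline-bin rates, over their SD floored at 0.1 Hz.  The floor
  keeps silent and near-silent units finite; a unit with no baseline
  spikes yields an all-zero trace and a `zero_baseline` flag rather than
  an error.
* **fold-change**: bin rate over baseline mean (same floor).

Latency is the left edge of the *first* bin attaining the window maximum
(excited) or minimum (inhibited); ties therefore resolve to the earliest
bin, and a flat window returns the first bin with a `flat` flag.

## The per-neuron test

Per trial, the mean rate in the response window is paired with the mean
rate in a pre-stimulus baseline segment and the two are compared with a
two-sided Wilcoxon signed-rank test at α = 0.05.

One calibration detail matters.  If a 100 ms response window is paired
with the full 1 s baseline, the null paired difference of two Poisson
rates with very different supports is markedly skewed, and the
signed-rank test's symmetry assumption fails: measured null rejection is
≈ 7.8% at nominal 5%.  The default baseline segment therefore has the
*same duration* as the response window, ending at onset (the full
baseline is used when the response window is longer, where both rates
are near-Gaussian and calibration is unaffected).  With this pairing,
measured null rejection is 5.0–5.4% across every analysis window used
(200–400, 0–100, 0–200, 100–500, 200–2000 ms), verified on 200-unit
null populations in the acceptance tests.  The explicit
`baseline_window` argument overrides the default.

Direction and magnitude are both taken from the window-mean normalized
rate, so `sign(magnitude)` always agrees with the reported direction —
an invariant asserted exactly in the tests.  (Taking direction from the
median paired difference instead can disagree with the mean-based
magnitude on skewed count data; a single source of truth avoids
self-contradictory rows in the output tables.)

## Classification rules

* **Valence encoding**: reward-cue direction `inhibited` (200–400 ms
  window) *and* footshock direction `excited` (0–100 ms window).
* **Cell typing** (VTA): pDA = excited 0–200 ms after the reward cue;
  ramping = excited 200–2000 ms and not pDA; reward-inhibited =
  inhibited 0–200 ms.  Precedence pDA > ramping > reward-inhibited
  resolves units significant in both windows: the pDA definition is
  applied first.
* **Aversive inhibition typing** (pDA units): the inhibition window is
  100–500 ms.  The early-excitation window that separates *delayed* from
  *immediate* inhibition is not independently specified anywhere, so the
  package uses 0–100 ms, mirroring the fast aversive excitation window —
  the initial pDA excitation precedes the 100–500 ms inhibition on
  exactly that timescale.
* **Sustained (opponent) responses**: there is no trial structure at the
  minutes timescale, so each phase is tested by a two-sided rank-sum of
  per-minute rates in the phase window against the 15 per-minute
  baseline rates.  A unit is *biphasic* iff both phases are significant;
  phase directions are recorded independently.  Default phase windows:
  LiCl 0–10 and 20–30 min, restraint 0–3 and 9–12 min, cocaine 0–10 and
  20–30 min.  For cocaine the rebound window is reported inconsistently
  between 20–30 and 15–25 min in the source literature conventions; the
  package defaults to 20–30 min and the window is an argument.

## Bursts

A burst opens at the first spike of any pair with interspike interval
strictly below 80 ms, continues while successive intervals are at most
160 ms (inclusive — termination requires *more than* 160 ms), and
scanning resumes after the closing spike, giving non-overlapping maximal
bursts.  Many toolboxes use other conventions at exactly 80/160 ms, so
the boundary behavior is asserted bin-exactly in the tests, and the
scanner is verified identical to an independent segment-based
enumeration on 1000 random Poisson and cluster-process trains.  Note
that under this rule a homogeneous 10 Hz Poisson train already places
most spikes in "bursts" (P(ISI < 80 ms) ≈ 0.55); the informative
quantity is the comparison against rate-matched controls, which the
cluster-process generator provides.

## Population statistics

Correlations of per-unit response magnitudes use Pearson's r with a
two-sided t-based p-value; magnitudes are window-mean normalized rates,
and subset filters (e.g. units significantly excited by footshock) are
explicit arguments.  Proportion contrasts use the chi-square test of
independence *without* continuity correction, matching the reporting
conventions for group sizes in this literature; the test suite checks it
against a binomial-resampling oracle under the pooled null.  Group time
courses use repeated-measures one-way ANOVA (`aov` with an
`Error(unit)` stratum) with Holm–Šidák-adjusted paired contrasts of each
window against baseline only — not all pairwise contrasts.  The
normality gate is the D'Agostino–Pearson K² omnibus (implemented from
the standard skewness/kurtosis transforms and verified against an
independent implementation to 6 decimals); samples failing it at
p < 0.05 are replaced by mid-ranks before parametric testing, and the
gate is idempotent on ranks.

## Calcium analysis

Trials are 20 s windows centered on onset (100 samples at 5 Hz).  The
baseline segment within the window is not standardized; the package uses
the entire pre-onset half (10 s) and subtracts its per-trial mean — the
minimal reading of "normalized to baseline", robust for dF/F inputs —
with the segment overridable.  Smoothing is a centered 0.6 s moving
average (3 samples at 5 Hz) whose window shrinks at trial edges.  The
per-cell test is a two-sided paired t-test of per-trial response-window
means (default 0–2 s, the cue duration) against baseline means.  The
whole chain is invariant to positive rescaling of dF/F, asserted
exactly.

## Place conditioning

Occupancy logs must partition the session, alternate chambers, and route
side-to-side transitions through the center — malformed logs are
rejected at the first offending interval.  The preference score is
seconds in (or entries into) the paired minus the unpaired chamber; the
shift is post minus pre.  An *entry* is a transition into a chamber from
the center; because real trajectories include sub-second center
traversals, center entries are debounced at 1 s dwell (a documented
choice — no debounce rule is standard), with the debounce exposed as an
argument.  Group analysis offers the two-way ANOVA (lesion × stimulus)
contract with Bonferroni per-stimulus contrasts plus a one-sample test
of shifts against zero, since the intended primary test is ambiguous in
the field's reporting.

## The synthetic-data generator

The generator is the package's test surface: every classifier is
validated against data whose true labels are known.

* **Spiking** is an inhomogeneous Poisson process sampled by per-segment
  thinning: the rate function — baseline × product of active kernel
  gains, piecewise-linear once drift is added — is cut at kernel-phase
  boundaries, candidates are drawn at each segment's maximum rate and
  accepted with probability rate/max.  This is exact for the
  piecewise-constant and linear segments used.
* **Dead time.**  A clean Poisson train at 10 Hz has ≈ 1% of intervals
  under 1 ms and would fail the refractory acceptance rule, which real,
  well-isolated units do not.  Clean units therefore carry a 1 ms
  absolute dead time, with the driving intensity compensated as
  r′ = r/(1 − r·τ) so the realized rate equals the configured rate
  (verified: 100-seed mean counts match rate × duration within the
  Poisson 99% band).  Injected refractory violations (+0.5 ms
  duplicates) and event-onset artifact spikes are added *after* this
  step, so only configured defects produce sub-millisecond intervals.
* **Bursts** are a Neyman–Scott cluster process (Poisson cluster
  centers, ≥ 1 spikes per cluster with exponential within-cluster
  intervals) superimposed on the baseline process, giving the burst
  module a non-Poisson positive control.
* **Calcium** is the spike train convolved with a peak-normalized
  difference of exponentials (0.1 s rise, 0.8 s decay — a
  fast-indicator-like shape at 20 Hz acquisition, downsampled 4× to the
  5 Hz analysis rate) plus Gaussian noise.
* **Behavior** is a center-mediated Markov walk: exponential dwells,
  paired-side probability `bias_paired` at each center departure,
  photobeam counts of two breaks per transition plus Poisson background,
  and occupancy truncated to partition the session exactly.

Reference conditions follow the study design the package targets: 50
reward trials and 50 trials per aversive stimulus at 30 s intervals,
10 Hz baseline units, excitation gain 3 and inhibition gain 0.2,
15 min pre-stimulus baselines for sustained stimuli, 15 min
place-conditioning sessions.  Where the design leaves a count open (the
per-stimulus aversive trial count) the generator defaults to a typical
value (30; the validation suites use 50 to match the reward block).

**What passing tests show — and don't.**  The generator's spikes are
(dead-time-corrected) Poisson with multiplicative box/ramp kernels; real
units have slow excitability fluctuations, correlated trial-to-trial
variability, and non-multiplicative interactions between stimuli.
Calibration results (type-I error ≈ 5%) transfer to real data only to
the extent that per-trial window rates are exchangeable with baseline
rates under the null; the recovery sensitivities (≥ 90% at gain 3 / 0.2,
50 trials) are statements about these planted effect sizes, not about
effect sizes in tissue.  The behavior model has no within-chamber
kinematics, so photobeam counts validate bookkeeping, not locomotor
inference.

## Problem sizes and numerical choices

The validation suites use: 1000 trains for the burst oracle, 200-unit
null populations (50 trials) for classifier calibration with binomial
99% acceptance bands, 100-unit planted populations for recovery, 1000
repetitions for the calibration of each population statistic, and
50-unit groups for the sham/lesion structural contrast — sizes at which
the binomial bands are tight enough to be informative while the full
suite runs in well under a minute on one core.  Wilcoxon tests use the
normal approximation with continuity correction (`exact = FALSE`):
spike-count data are tie-rich, where R's exact method is unavailable
anyway; all-zero difference vectors return p = 1 and direction `none`
rather than an error.  Chi-square contrasts reject tables with a zero
expected count.  Seeds propagate from a single master seed via derived
child seeds, and identical configurations reproduce byte-identical
outputs — asserted for spike trains, populations, pipeline reports, and
behavior sessions.

## Known limitations

* Spike sorting, CNMF-E source extraction, and motion correction are out
  of scope; inputs are sorted spike times and extracted dF/F.
* No spike-density (kernel-smoothed) PSTH estimation — plain binning
  only, by design.
* No hierarchical modeling across animals/sessions; units are pooled as
  in the analyses the package mirrors.
* The drift screen and the per-neuron sustained-phase test are this
  package's documented stand-ins where the field's descriptions are
  procedural rather than statistical; both are exposed with their
  parameters and calibrated on nulls, but they are conventions, not
  canon.
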