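# valencephys

Analysis toolkit for studies of motivational valence coding in midbrain
circuits: extracellular spike trains recorded around phasic (sub-second)
and sustained (multi-minute) appetitive/aversive stimuli, miniscope
calcium traces from projection-defined populations, and three-chamber
conditioned place preference/aversion behavior.  It is written for
systems-neuroscience labs that record RMTg (rostromedial tegmental
nucleus) or VTA (ventral tegmental area) units in freely moving animals
and need the full chain from unit acceptance to population statistics in
one reproducible, tested pipeline.

## What it computes

**Unit quality control.** A unit is accepted when fewer than 0.2% of its
spikes follow a preceding spike by less than 1 ms (strict inequality),
and when its baseline firing rate shows no significant rank trend across
the session (Spearman correlation of per-window rate vs. window index,
two-sided, α = 0.05).  The first 10 ms after each footshock is blanked
and treated as excluded time, not as silence.

**Event-aligned responses.** Peri-stimulus time histograms use 50 ms bins
normalized to the 1 s pre-stimulus baseline for phasic stimuli, and 5 min
bins normalized to a 15 min baseline for sustained stimuli — one code
path, two timescales.  The normalized rate is the z-score
*z<sub>b</sub>* = (*r<sub>b</sub>* − *μ*<sub>base</sub>) / max(*σ*<sub>base</sub>, 0.1 Hz);
a fold-change dialect is selectable.  Response latency is the left edge
of the first bin attaining the window's peak (excited) or trough
(inhibited).

**Per-neuron classification.** Each unit × stimulus is tested with a
two-sided Wilcoxon signed-rank test of per-trial window rate against a
duration-matched pre-stimulus baseline rate, at p < 0.05:

| label | rule |
|---|---|
| valence-encoding | inhibited by reward cue (200–400 ms) **and** excited by footshock (0–100 ms) |
| pDA (putative dopamine) | excited 0–200 ms after reward cue |
| ramping | excited 200–2000 ms after reward cue, not pDA |
| immediate / delayed inhibition | pDA inhibited 100–500 ms after an aversive stimulus, without / with a brief 0–100 ms excitation |
| biphasic (opponent) | significant in both the initial and rebound phase of a sustained stimulus (rank-sum of per-minute rates vs. 15 baseline minutes) |

**Bursts.** The interspike-interval rule: a burst opens at any pair of
spikes less than 80 ms apart and runs until the next spike is more than
160 ms away; the package reports burst intervals and the percentage of
spikes in bursts.

**Population statistics.** Pearson correlations of per-unit response
magnitudes (r², two-sided p, fitted line), chi-square contrasts of
category proportions (no continuity correction), repeated-measures
one-way ANOVA over phase windows with Holm–Šidák-corrected
window-vs-baseline contrasts, and a D'Agostino–Pearson normality gate
that rank-transforms non-normal samples before parametric tests.

**Calcium and behavior.** Trial tensors from 20 s onset-centered dF/F
windows (5 Hz), baseline subtraction, 0.6 s moving average, paired
t-tests per cell, and projection contrasts (VTA- vs. DRN-projecting).
Place-preference scores are seconds-in (or entries-into) the
stimulus-paired minus unpaired chamber; the conditioning effect is the
post-minus-pre shift.

**Synthetic data with planted truth.** Every stage is validated against a
generator that plants known structure: inhomogeneous-Poisson spiking
(piecewise thinning, 1 ms absolute dead time), multiplicative
stimulus-locked rate kernels at both timescales, Neyman–Scott burst
clusters, injectable QC defects (drift, refractory violations, shock
artifacts), kernel-convolved calcium transients, and a Markov
chamber-transition model with controllable side bias.

## Worked example

A single synthetic RMTg-like unit with the reference valence-encoding
kernels (10 Hz baseline, reward-cue gain 0.2 at 200–400 ms, footshock
gain 3 at 0–100 ms), analyzed exactly like a recorded unit:

```r
library(valencephys)

sched <- phasic_schedule(n_reward = 50, n_per_stimulus = 50,
                         stimuli = "footshock", iti = 30)
cfg <- archetype_config("valence", unit_id = "rmtg_07")
st  <- generate_spike_train(cfg, sched, max(sched$onset) + 30, seed = 11)
st  <- blank_shock_artifact(st, schedule_events(sched, "footshock")$onset)

reward <- align_and_bin(st, sched, "reward_cue", c(-1, 0.5), 0.05)
shock  <- align_and_bin(st, sched, "footshock",  c(-1, 0.5), 0.05)
profiles <- list(
  reward_cue = window_response_test(reward, c(0.2, 0.4)),
  footshock  = window_response_test(shock,  c(0, 0.1)))
do.call(rbind, profiles)
#>            unit_id   stimulus win_start win_end direction  p_value magnitude latency
#> reward_cue rmtg_07 reward_cue       0.2     0.4 inhibited 9.90e-08      -4.0     0.2
#> footshock  rmtg_07  footshock       0.0     0.1   excited 1.09e-06      13.6     0.0

classify_rmtg_profile(profiles)$valence_encoding
#> [1] TRUE
```

The unit is significantly inhibited by the reward cue (mean normalized
rate −4.0 baseline SDs in the 200–400 ms window, latency 200 ms) and
excited by footshock (+13.6 SDs at 0–100 ms), so it carries the
valence-encoding label.  The whole-population version of this analysis —
generation, QC, classification, proportion tables, and magnitude
correlations — is one call:

```r
report <- run_pipeline(analysis_config(
  population = list(list(archetype = "valence", count = 40),
                    list(archetype = "none",    count = 60)),
  seed = 1, vta_typing = FALSE))
report$proportions$reward_cue
```

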