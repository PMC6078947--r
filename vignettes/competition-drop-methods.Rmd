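---
title: "Tracking retrieval competition with transferred EEG classifiers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking retrieval competition with transferred EEG classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compdrop)
```

## The scientific problem

Repeated testing produces better long-term retention than repeated study.
One mechanistic account holds that each successful retrieval weakens the
competing memories activated by the cue, and that the *amount* by which
competition declines across retrieval-practice attempts should predict
whether the practiced item survives a long delay. `compdrop` implements
the full analysis chain needed to evaluate that account with EEG:

1. **Competition localizer.** A within-subject sliding-window classifier
   learns to separate epochs of high-competition cued recall (retrieve
   one exemplar from a category cue) from low-competition recall
   (retrieve the category from an exemplar cue).
2. **Cross-session transfer.** Classifiers trained at each discriminative
   localizer timepoint are applied to every post-onset timepoint of the
   vocabulary-learning session, producing, per item and practice round, a
   grid of *competition probabilities* over (training time, testing time).
3. **Competition drop.** Per item and grid square, the competition
   probability at the first correctly-answered round minus the
   probability at the final round. Items never answered correctly, or
   answered incorrectly in the final round, are excluded.
4. **Inference.** A pooled one-tailed t-test grid comparing drops for
   subsequently-remembered vs -forgotten items, thresholded at p < 0.10,
   corrected family-wise by a max-cluster-size permutation test
   (4-connectivity, 1000 label permutations, alpha 0.05), with a
   subject-level bootstrap quantifying population reliability.

Because real multi-session EEG recordings are not shipped with the
package, a synthetic-data module generates multi-subject datasets with
planted ground truth; recovery and error-rate control on those datasets
are the package's validation surface.

## The generative model

`simulation_config()` fixes both the experimental design and the planted
structure. Defaults mirror the paradigm the analysis targets: 40
subjects, 64 channels at 512 Hz, a localizer with 19 categories x 8
exemplars x 2 conditions (304 trials per subject, balanced and randomly
interleaved), and 60 vocabulary items practiced over 4 study+test rounds
with a delayed test one week later.

**Session 1 epochs.** The two classes differ only by a mean pattern
`±(effect_size/2) · topography ⊗ envelope`, where the topography is a
smooth unit-norm bump over channels and the envelope is a raised cosine
supported exactly on `signal_window` (default 100–500 ms). Outside that
window the class-conditional mean difference is identically zero, which
gives the localizer-recovery tests a sharp target. Noise is Gaussian
with exponential inter-channel correlation (length scale 8 channel
indices) and AR(1) temporal autocorrelation (lag-1 coefficient 0.3) —
the minimal structure under which whitening matters and the Haufe
weight-to-pattern transform differs visibly from the raw weights.

**Latent competition.** Each item starts at a latent competition level
drawn uniformly from [0.55, 0.95] and loses a truncated-normal decrement
(mean 0.08, SD 0.05) per round, clamped to [0.02, 0.98]: decline is
monotone in expectation with genuine across-item variance in the total
drop, which the analysis requires. Retrieval epochs for item *i*, round
*r* carry the amplitude `effect_size · (latent_ir − 0.5)`; study-block
epochs carry the neutral amplitude (latent pinned at 0.5), so the
study-trial control analysis is null by construction.

**Behavior.** Per-round correctness follows a logistic learning curve
(defaults 0.30/0.50/0.65/0.78) shifted by a per-item ability offset
(SD 1 log-odds). Delayed recall is drawn with log-odds
`α + β·(drop − 0.15) + 0.8·ability`, where `β = drop_memory_coupling`
and drop is the latent drop from the first-correct round (first round if
never correct) to the final round. The centering constant 0.15
approximates the expected planted drop, so the default intercept yields
the near-50% marginal delayed recall this paradigm shows; the ability
term reproduces the strong dependence of delayed recall on learning
accuracy that makes response configurations predictive (with the default
coupling, the 40-subject behavioral classifier lands in the mid-60%
accuracy range). Reaction times are log-normal on top of the enforced
2 s response delay, with the item random effect (SD 0.6 log units)
dominating a weak per-round trend (−0.05 log units/round), emulating
item-level RT variance that is large relative to round differences.

**What the generator does not emulate.** No volume conduction from a
forward head model, no eye-blink or EMG artifacts, no non-stationarity
across blocks, no 1/f spectral shape, and a single fixed topography for
the competition signal rather than the early/late representational
change real data show. Passing recovery tests therefore demonstrate that
the *pipeline* is correct and calibrated, not that real recordings will
yield any particular result.

## Numerical and procedural choices

- **Filtering** is zero-phase (forward–backward) cascaded Butterworth:
  high-pass at 2 Hz and low-pass at 200 Hz (order 4 per section) plus a
  4 Hz-wide order-2 band-stop at 60 Hz. Cascaded IIR sections stay
  stable where a single high-order band-pass at a 2/256 normalized edge
  would not, and they reach the documented ≥ 20 dB notch attenuation on
  ~1 s epochs where an equally selective FIR filter would be longer than
  the epoch. Theta power band-passes 4–8 Hz the same way and takes the
  squared magnitude of the FFT-constructed analytic signal (a
  `magnitude` option exists); no baseline correction on this path.
- **Windowing**: 50 ms windows every 20 ms; membership is half-open
  `[t, t+50)` on the sample grid, and windows that do not fit inside the
  epoch are excluded with a count. The default epoch span (−100 to
  +1000 ms) and baseline window (−100 to 0 ms) are package choices,
  exposed in the configuration.
- **Classifier**: L2-penalized logistic regression via `glmnet`
  (`alpha = 0`, single `lambda = 1/(nC)`, default `C = 1`), no feature
  standardization by default since window means share one voltage scale;
  both are configuration-exposed. Folds are stratified and seeded.
- **Permutation p values** use the add-one estimator
  `(1 + #{perm ≥ obs})/(n_perm + 1)`, so p is never 0. Before the
  inverse-normal group transform, within-subject p values are clipped to
  the resolution of the permutation count (`1/101` for 100 permutations)
  to keep z finite; the group test is a one-sided one-sample t-test of
  the z values against zero, Bonferroni-corrected at `0.001/T`.
- **Window selection** requires group significance *and* accuracy more
  than one across-subject SD above chance, bridging internal dips
  shorter than `bridge_ms` (default 120 ms) instead of splitting the
  window; among disjoint surviving runs the longest (earliest on ties)
  is kept. The bridge rule formalizes a narratively-described practice.
- **Transfer**: one model per selected training timepoint, fit on all
  Session 1 trials; output probabilities are clipped to
  `[1e−6, 1 − 1e−6]`.
- **Cluster inference**: Student (pooled-variance) t by default (Welch
  behind a flag); cluster statistic is *size* (square count) under
  4-connectivity; permutations shuffle outcome labels over the pooled
  item set (a within-subject-stratified variant exists behind a flag);
  the null records the maximum cluster size of the right-tailed mask
  only, because the hypothesis is directional — the left-tailed map is
  reported descriptively. The Kolmogorov–Smirnov normality check is a
  reported diagnostic, never a gate.
- **Z-scoring** of drops within subject uses the n−1 SD; subjects with
  fewer than two retained items or zero variance at any square are
  excluded with a logged count.
- **RT drop** takes the final round (not the last *correct* round) as
  its second term, mirroring the competition-drop definition.
- All randomness flows through named integer seeds; a dataset, a fold
  assignment, a permutation run, and a full pipeline run are each
  bit-reproducible given their seed.

## Validation strategy and problem sizes

The package validates itself at reduced scale, chosen so the suite runs
comfortably on one CPU while keeping every statistical property intact:

- *Oracle equivalence*: window means vs explicit index enumeration;
  cluster labeling vs a recursive flood fill on random 10×10 masks; the
  t grid vs a from-scratch formula and `stats::t.test`; the RDM vs hand
  arithmetic.
- *Error-rate control*: 200 replicate null datasets (8 subjects, 30
  items, 8 channels at 64 Hz, 200 permutations, zero drop–memory
  coupling) for the family-wise cluster rate, and 200 behavior-only
  replicates for the permutation test's type-I error; both must sit
  inside the binomial 95% band around 0.05.
- *Recovery at high SNR* (effect size 8, coupling 10): localizer
  significance concentrates inside the planted window; a family-wise
  significant cluster overlapping the planted window appears in ≥ 90% of
  20 replicates; averaged Haufe patterns correlate r > 0.9 with the
  planted topography.
- *Controls*: the study-trial grid stays null in ≥ 90% of the same
  replicates; RT-drop does not predict delayed recall when RTs are
  generated without a round trend. (With the default weak negative round
  trend, RT drop inherits a slight coupling to the first-correct round
  and is not a pure null — the control criterion therefore switches the
  trend off.)

## Known limitations

- The discriminative-window rule assumes a single dominant run of
  significant timepoints; pathologically fragmented masks return only
  the longest run.
- The pooled (fixed-effects) t grid is anticonservative on its own, as
  expected; only cluster-corrected p values should be interpreted.
- The subject bootstrap reruns the full permutation test per draw and is
  the most expensive stage; reduced permutation counts per draw trade
  tail resolution for time.
- `read_dataset`/`write_dataset` use an RDS + TSV directory layout; no
  interchange with BDF/EEGLAB file formats is provided.
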