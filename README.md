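# compdrop

EEG decoding of memory-retrieval competition and its decline across
retrieval practice.

`compdrop` is for cognitive-neuroscience researchers who want to test a
mechanistic account of the testing effect: that repeated successful
retrieval strengthens long-term retention by *reducing competition* from
related memories. The package implements the complete analysis chain as
reusable, tested R functions, together with a synthetic multi-subject
EEG + behavior generator with planted ground truth so that every stage
can be validated by parameter recovery and error-rate control.

## The method

1. **Competition localizer.** From Session 1 epochs (balanced
   high-competition vs low-competition cued recall), per-channel means
   over 50 ms sliding windows (20 ms steps) feed a within-subject
   L2-penalized logistic regression at every timepoint, scored by
   stratified 5-fold cross-validation. Within-subject significance uses
   a 100-permutation test; subjects are combined via the inverse-normal
   transform, z = Φ⁻¹(1 − p), and a one-sided one-sample t-test, with
   Bonferroni correction 0.001/T over the T timepoints. The
   discriminative window is the run of timepoints that are significant
   and > 1 SD above chance (short dips bridged).
2. **Transfer.** For each training timepoint in that window, a
   classifier fit on *all* Session 1 trials is applied to every
   post-onset timepoint of the Session 2 vocabulary-learning epochs.
   The logistic output is read as the **competition probability**
   P(high-competition state), giving a per-item, per-round grid over
   (training time, testing time).
3. **Competition drop.** Per item and grid square:
   P(first correctly-answered round) − P(final round). Items never
   correct, or incorrect in the final round, are excluded.
4. **Inference.** A pooled one-tailed t-test grid (remembered vs
   forgotten on the delayed test), thresholded at p < 0.10; family-wise
   correction by a max-cluster-size permutation null (4-connectivity,
   1000 label shuffles, α = 0.05); a subject bootstrap reports how
   often each square falls in a significant cluster.

Diagnostics include cosine-distance RDMs over the learned weight
vectors, Haufe weight-to-pattern transforms (a = Σ_X w), study-trial and
reaction-time-drop control analyses, and response-configuration
(e.g. `0011`, `0111`) behavioral decoding of delayed recall.

## Worked example

A reduced-scale end-to-end run (6 subjects, 8 channels at 64 Hz, 30
items, planted signal at 100–300 ms, high SNR):

```r
library(compdrop)

cfg <- simulation_config(
  n_subjects = 6, n_channels = 8, sampling_rate = 64,
  epoch_span = c(-100, 500), n_categories = 5, n_exemplars_per_category = 6,
  n_items_s2 = 30, signal_window = c(100, 300), effect_size = 8,
  drop_memory_coupling = 10, seed = 3)

params <- pipeline_params(step_ms = 40, n_perm_localizer = 100,
                          n_perm_cluster = 500, n_perm_behavior = 500,
                          n_boot = 50, n_perm_boot = 200, seed = 4)

run_pipeline(cfg, "run1", params)
cat(make_report("run1"), sep = "\n")
```

Output for this configuration (seed 1 throughout):

```
Competition-drop analysis report
================================
features: voltage

Localizer decoding:
  4 of 14 timepoints group-significant
  peak group accuracy 1.000
  selected window: 100..220 ms

Retained items: 130
Clusters (retrieval trials):
  label size        fw_p significant
1     1   18 0.005988024        TRUE
2     2    1 0.818363273       FALSE
Clusters (study-trial control):
  label size      fw_p significant
1     1    1 0.8483034       FALSE
Bootstrap: 50 valid draws, max inclusion 0.88

Behavioral prediction:
  configuration-based accuracy 0.689 (p = 0.001996)
```

Reading the numbers: the localizer finds the planted 100–300 ms signal
(windows starting 100–220 ms cover it); 130 of 180 pooled items satisfy
the retention rule; the competition-drop grid yields one family-wise
significant cluster (p = 0.006) on retrieval trials while the
study-trial control — whose epochs carry no round-dependent signal —
stays null; and the 4-bit response configurations predict delayed recall
well above the 50% chance level.

## Package layout

- `R/simulate.R` — synthetic-data generator (design, planted signal,
  latent competition trajectories, behavior, reaction times)
- `R/preprocess.R` — zero-phase band-pass/notch filtering, average
  re-reference, epoching + baseline, theta-band Hilbert power
- `R/localizer.R` — sliding-window features, CV decoding, permutation
  and group tests, window selection
- `R/patterns.R` — weight RDMs, Haufe transform, pattern averaging
- `R/transfer.R` — full-data training, cross-session competition grids
- `R/drop.R` — drop scores, configuration filters, within-subject
  z-scoring, RT drop
- `R/cluster.R` — grid t-tests, KS diagnostics, 4-connected clusters,
  permutation correction, subject bootstrap
- `R/behavior.R` — response configurations, behavioral decoding,
  round summaries
- `R/pipeline.R` — end-to-end orchestration and reporting

See `vignettes/competition-drop-methods.Rmd` for the model, the
numerical choices, and what the synthetic validation does and does not
establish about real recordings.
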