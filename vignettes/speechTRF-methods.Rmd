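---
title: "Modeling neural tracking of speech and lexical surprisal with speechTRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling neural tracking of speech and lexical surprisal with speechTRF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechTRF)
```

## The problem

When a listener follows continuous speech, low-frequency cortical activity
tracks the acoustic envelope of the signal, and — beyond acoustics — the
*predictability* of each word modulates a slower, centro-parietal negative
response akin to the classical N400. speechTRF implements the full analysis
chain needed to measure both phenomena from multichannel EEG recorded during
audiobook listening:

1. **Lexical surprisal** of each word, $S(w_k) = -\log_2 p(w_k \mid
   w_{k-4},\dots,w_{k-1})$, from a backoff n-gram language model
   (`train_ngram()`, `surprisal_of()`, `annotate_tokens()`).
2. **Stimulus regressors**: the broadband temporal envelope (magnitude of the
   analytic signal), a binary word-onset step function, and a surprisal-scaled
   step function (`compute_envelope()`, `step_regressor()`).
3. **Temporal response functions (TRFs)**: linear kernels $w(f, \tau)$ mapping
   each stimulus feature $f$ at lags $\tau \in [-100, 1000]$ ms to each EEG
   channel, estimated by Tikhonov-regularized (ridge) regression on a lagged
   design matrix with leave-one-trial-out cross-validation of the
   regularization strength $\lambda \in \{2^{-5}, \dots, 2^{15}\}$
   (`fit_tikhonov()`, `cross_validate_lambda()`, `condition_trf()`).
4. **Model comparison**: the added predictive value of surprisal, measured as
   the difference in cross-validated prediction accuracy (Pearson *r*,
   averaged over channels) between the *acoustic* model (envelope + onset) and
   the *full* model (+ surprisal), tested across participants with a one-sided
   Wilcoxon signed-rank test (`added_value()`).
5. **Cluster-based permutation statistics** on TRF weights over channels and
   lags, with channel adjacency defined by a 4 cm neighborhood
   (`build_adjacency()`, `cluster_perm_test()`).
6. **Component extraction**: TRF-N1 (minimum, 50–150 ms) and TRF-P2 (maximum,
   150–250 ms) of the envelope kernel over a frontal-central ROI; the TRF-N400
   as the minimum (200–1000 ms) of the altered-minus-control difference of the
   surprisal kernel over a parietal ROI, with amplitude averaged over a
   ±10 ms window around the peak (`extract_sensory_peaks()`,
   `extract_n400()`).
7. **Behavioral scoring and group statistics**: listening-span recall and
   sentence-judgment accuracy, SSQ domain means, Welch *t*, exact Wilcoxon,
   mixed repeated-measures ANOVA, Spearman correlations with
   Benjamini–Hochberg FDR, chi-square, and a noncentral-*t* sensitivity
   analysis (`score_listening_span()`, `welch_t()`, `mixed_anova()`,
   `spearman_fdr()`, `min_detectable_effect()`).

Because suitable public recordings do not exist, the package ships a
first-class synthetic-data generator (`gen_story()`, `simulate_recording()`,
`simulate_cohort()`) whose forward model is exactly the linear TRF framework
the estimator inverts, plus controlled departures from it. Every stage of the
pipeline is validated against this known ground truth.

## The estimator

For one trial with regressor matrix $X \in \mathbb{R}^{n \times F}$ and EEG
$Y \in \mathbb{R}^{n \times C}$, the lagged design $D$ contains each feature
delayed by every lag in the window (out-of-range samples zero-padded) plus an
unpenalized intercept. The TRF solves

$$ (D^\top D + \lambda M)\, w = D^\top y $$

per channel, with $M$ the identity on all non-intercept coefficients
(classical ridge; a per-feature second-difference smoothness matrix is
available via `penalty = "derivative"`). Two implementation details matter:

* **Sufficient statistics instead of the explicit design.** $D^\top D$ has a
  block-Toeplitz structure: within a feature pair, entries along a diagonal
  differ only by a few boundary samples. The package computes each lag block
  from one FFT cross-correlation per feature pair plus short head/tail
  corrections, and $D^\top y$ from FFT cross-correlations, in
  $O(n \log n + L^2)$ per pair instead of $O(n L^2)$. A dedicated test
  verifies exact agreement (to $10^{-8}$) with `crossprod()` on the explicit
  design.
* **Intercept by block elimination.** Leaving the intercept unpenalized is
  equivalent to ridge on the column-centered Gram matrix (a rank-one update),
  which makes the problem symmetric again, so a *single* eigendecomposition
  per cross-validation fold serves the entire $\lambda$ grid, and held-out
  accuracy is evaluated analytically from the test trial's sufficient
  statistics without forming predictions.

Cross-validation never scores a trial used for fitting (the fold bookkeeping
is asserted in tests), ties on the accuracy curve resolve to the smallest
$\lambda$, and the per-condition TRF is the average of per-epoch fits at the
chosen $\lambda$, baseline-corrected by subtracting the mean over
$[-100, -4]$ ms.

## The synthetic forward model

`simulate_recording()` builds EEG as

$$ Y = \sum_f t_f \, (x_f * k_f)^\top \; + \; \text{noise}, $$

where $k_f$ are sums of Gaussians in lag space (closed-form window means make
peak-extraction tests analytic): a biphasic envelope kernel (N1 at 100 ms,
amplitude −1; P2 at 200 ms, amplitude +1.2; SD 25 ms), a small onset kernel
(120 ms, +0.4), and a negative surprisal kernel (N400) centered at 427.2 ms
(SD 60 ms, −0.08 per bit) for the normal-hearing preset and 554.3 ms for the
implant-like preset, whose sensory components are additionally delayed by
40 ms. Topographies $t_f$ are smooth Gaussian weightings on the bundled
10–20/10–10 montage — frontal-central for envelope/onset, central-parietal
for surprisal — mirroring the analysis ROIs. Noise is $1/f$ (exponent 1) plus
white noise (relative SD 0.5), scaled so that RMS(signal)/RMS(noise) matches
the configured SNR (default 0 dB) over the whole recording.

Two deliberate super-linearities make the generator more than a tautology for
the estimator:

* **Incongruity response.** Altered (out-of-context, >20-bit) words drive
  `(1 + incongruity_gain)` times the linear surprisal response
  (default gain 2). A strictly linear-in-surprisal brain would produce
  *identical* surprisal TRFs in the altered and control stories (the TRF is
  per-bit) and an exactly zero difference wave; the incongruity term is what
  gives the altered-story condition its N400 difference, matching the logic
  of the altered-story design itself.
* **Behavioral link.** Each subject's sentence-judgment accuracy is a
  logistic function of their (jittered) surprisal-kernel gain plus binomial
  trial noise, emulating a brain–behavior correlation of configurable
  strength.

Stories are stitched from sampled sentences of a packaged ~100-sentence
corpus, so most words are predictable in context (mean surprisal ≈ 2.5 bits)
while replacement words — drawn from out-of-vocabulary nouns and verified
against the model — exceed the 20-bit floor (mean ≈ 29 bits). The default
study conditions are 15-minute stories at 170 words/min with one altered word
roughly every 45 s (greedy placement guarantees ≥45 s spacing and yields 20
altered words per 15-minute story), EEG at 250 Hz, 60-s epochs.

What the generator does **not** emulate: real speech acoustics (the envelope
is rectified $1/f$ noise, band-limited only by its own spectrum), eye/muscle/
implant artifacts (artifact removal is out of scope), volume conduction from
realistic sources, non-stationary noise, and latency/amplitude variability
beyond Gaussian jitter. Passing the recovery tests therefore demonstrates
correctness of the estimation and inference machinery, not robustness to all
properties of real recordings.

## Preprocessing order and numerical choices

The pipeline follows a fixed stage order: broadband 0.1–40 Hz band-pass
(second-order zero-phase Butterworth) → audio/EEG alignment by
cross-covariance → resampling to 250 Hz (8th-order anti-alias low-pass at
0.4× the target rate, nearest-sample decimation) → 1–20 Hz analysis band-pass
→ joint z-scoring → 60-s epochs. Key numerical decisions:

* **Joint standardization across runs.** EEG channels and regressors are
  z-scored with statistics pooled over a participant's concatenated runs
  (`standardize_runs()`), not per run. Per-run scaling would give the
  surprisal regressor different per-bit units in the altered versus control
  condition (its SD is ~4× larger when >20-bit words are present) and largely
  cancel the condition difference the analysis targets.
* **Zero-padding interaction.** Centering regressors makes the padded edges
  of each trial's lagged design correspond to the raw mean rather than zero —
  a small, inherent model misfit (~2% of samples at 60-s trials) shared by
  all TRF pipelines that z-score. Noiseless-inversion tests therefore run on
  unstandardized data, where forward and inverse match to machine precision;
  all noisy-recovery tests include standardization.
* **Onset/surprisal steps** span each word's onset→offset interval;
  contiguous words merge into one continuous step and pauses leave gaps.
  (Holding values to the next word's onset would make the onset channel a
  constant over continuous speech, i.e. a zero-variance regressor.)
* **Sample mapping** of word times uses nearest-sample rounding (half away
  from zero); peak searches break ties toward the earlier lag; flat search
  windows report the window start with amplitude 0.
* **The regularization curve is flat near its top** on realistic data: with
  z-scored inputs, accuracy typically rises by <1% from $2^{-5}$ to the
  chosen $\lambda$, and the CV optimum often sits at the top of the grid,
  where shrinkage acts mainly as smoothing (Pearson *r* is scale-free).
  The group-level $\lambda$ (accuracy curves averaged across participants
  before the argmax, `choose_group_lambda()`) is the pipeline default.

## Validation studies and their problem sizes

The packaged studies (also exercised by `scripts/acceptance.R`) were sized to
keep full Monte-Carlo validation practical on a single CPU; each size is a
deliberate down-scaling of the study conditions along dimensions that do not
change what the check measures:

* `kernel_recovery_study()`: one subject, 10 × 60-s trials (5 per condition)
  at 250 Hz and 0 dB SNR; envelope-kernel correlation (topography-weighted
  average) ≥ 0.95 and N400 latency within one sample (4 ms).
* `added_value_study()`: 20 subjects at 64 Hz analysis rate, 4 × 30-s trials
  per condition; the detection concerns accuracies, not latencies, so the
  rate can be low.
* `null_added_value_calibration()`: 200 cohorts of 12 subjects at 32 Hz with
  the surprisal kernel and incongruity gain set to zero. Stories and design
  Grams are fixed per subject across repeats; only the noise is redrawn. Its
  result is a *negative* finding worth stating plainly: the per-subject
  accuracy difference $\Delta r$ is systematically below zero under the null
  (mean ≈ −0.003, about −5 SD), because adding a useless regressor can only
  cost held-out accuracy. The one-sided Wilcoxon on $\Delta r$ is therefore
  conservative — its null rejection rate is ≈ 0, not the nominal 5% — which
  is the safe direction for the detection claim but means $\Delta r$ should
  never be interpreted as a calibrated test statistic. An estimator with a
  centered null would require fitting the extra regressor's coefficients on
  independent data.
* `cluster_null_fwer()` / `cluster_planted_power()`: 500 null and 100
  planted-effect datasets (16 subjects, 12 channels, 250 time points, 200
  permutations; effect: +1 SD on 4 adjacent channels × 200 ms). Family-wise
  error sits near the nominal 5% and the planted effect is detected in
  >90% of repeats.
* `latency_shift_study()`: 20 subjects/group, 2 × 240-s runs each at 250 Hz,
  12 channels; the configured 127.1-ms between-group difference in N400
  latency is recovered from grand-average difference waveforms within the
  inter-subject-jitter and sampling tolerance (±8 ms). Per-subject peak
  latencies are far too noisy at this SNR (SD > 190 ms); the grand average is
  the appropriate estimator. Subject latency jitter defaults to 10 ms SD so
  cohort-level checks measure pipeline bias rather than sampling noise of
  subject variability; real cohorts vary much more.

## Known limitations

* The n-gram model's smoothing (interpolated add-k, Kneser–Ney optional) is
  not the scheme of any specific external toolkit, so absolute surprisal
  values — e.g. story-level averages — are not comparable across toolkits,
  only orderings and threshold-crossings.
* EDF input is not supported; BrainVision (plus a JSON positions sidecar)
  doubles as the exchange format. ICA/SOBI artifact removal and
  spherical-spline interpolation are out of scope; bad channels are excluded,
  not interpolated.
* The cluster test assumes exchangeability within the permutation scheme
  (sign-flips for paired, label shuffles for independent designs); its
  calibration is verified only under the simulated i.i.d. null.
* `mixed_anova()` requires complete balanced designs (as in the simulated
  cohorts); it does not handle missing cells.

## A minimal end-to-end run

```{r example, eval = FALSE}
cfg_sim <- sim_config(n_per_group = 5, rate = 64, duration_s = 120,
                      channels = c("Fz", "FCz", "Cz", "CP1", "CP2",
                                   "CPz", "Pz", "POz"),
                      seed = 77)
cohort <- simulate_cohort(cfg_sim, trial_s = 30)
res <- run_pipeline(cohort,
                    pipeline_config(rate = 64, trial_s = 30,
                                    n_perm = 200, adjacency_radius = 0.08,
                                    seed = 5),
                    out_dir = "results")
res$added_value$test$p      # added value of surprisal
res$n400                    # per-subject N400 latency/amplitude + behavior
res$clusters$NH             # within-group cluster test
```
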