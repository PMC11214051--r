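---
title: "Time-resolved RSA of voice EEG: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved RSA of voice EEG: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(voicersa)
```

## The scientific question and the analysis it requires

When we hear a short voice recording we spontaneously form impressions
of the speaker — their gender and age, but also how trustworthy,
dominant, healthy or educated they sound.  `voicersa` implements a
time-resolved representational similarity analysis (RSA) that asks
*when* such person characteristics become decodable from the EEG
response to a voice, and how much of that apparent decoding is really
driven by low-level acoustics rather than by perceived characteristics.

RSA sidesteps the impossibility of regressing ratings directly on
single-trial EEG by comparing *geometries*: for a set of voice stimuli,
every data modality is summarized as a representational dissimilarity
matrix (RDM) over stimulus pairs, and modalities are related by
correlating their RDMs.  Three RDM families are built:

* **Neural RDMs**, one per participant and per time point: the
  cross-validated accuracy of a linear SVM classifying each stimulus
  pair from the channel pattern at that time point (chance = 50%;
  higher accuracy = more distinct neural patterns).
* **Behavioral RDMs**, one per person characteristic: the absolute
  difference of the stimuli's mean ratings on a 1–9 scale.
* **Acoustic RDMs**: the cosine dissimilarity of long-term average
  spectra (LTAS), and absolute score differences on the principal
  components of 13 perceptually salient acoustic measures (F0, formant
  frequencies and dispersion, harmonic source shape, cepstral peak
  prominence, energy, harmonics-to-noise ratio).

The link statistic is the **partial Spearman rank correlation** between
the neural RDM at time *t* and a characteristic's behavioral RDM,
computed on the vectorized lower triangles.  Three nested models
control acoustics to increasing degree:

* **Model 1** partials out the LTAS RDM;
* **Model 2** additionally partials out the acoustic
  principal-component RDMs;
* **Model 3** additionally partials out the behavioral RDMs of all
  other retained characteristics, isolating each characteristic's
  unique contribution.

Group-level significance over participants uses permutation-based
cluster-size inference: per time point a one-sample *t* against zero is
converted to a *z* value through the *t* CDF, contiguous runs of
*z* > 1.64 (one-sided; 1.96 two-sided for model comparisons) form
clusters scored by length, and the null distribution of the maximum
cluster size is built by sign-flipping participant time courses.

## The decoding dissimilarity in detail

Trials of each stimulus are randomly assigned to 5 splits and averaged
into pseudo-trials (subaveraging raises the signal-to-noise ratio of
the patterns that enter the classifier).  Cross-validation holds out
one split per stimulus: a linear SVM (C = 1) is trained on the
remaining 4 pseudo-trials per stimulus and scored on the 2 held-out
pseudo-trials, and the fold accuracies are averaged.  The whole
procedure is repeated for several random split assignments
("permutations"; 50 at full scale) and averaged, which shrinks the
assignment noise roughly in proportion to the number of draws.

Before classification, **multivariate noise normalization** (the
"epoch method") whitens the channel dimension: residuals of the
training pseudo-trials around their stimulus means are pooled over time
points into a channel covariance, shrunk toward a scaled identity with
an analytic Ledoit–Wolf-style intensity, and inverted via the symmetric
inverse square root.  The normalizer is fitted within each training
fold only, so no test information leaks into it.  On spatially
correlated noise this step reliably improves decoding; the test suite
checks `W %*% Sigma %*% W = I` algebraically at zero shrinkage.

Two interpretation points are worth recording.  First, the feature
vector at each time point is the vector of channel amplitudes at that
single sample; averaging across electrodes instead would leave a single
feature and make multivariate classification meaningless.  Second,
decoding accuracy is a *dissimilarity with a floor*: once two stimuli
are perfectly separable the entry saturates at 1.0, so at very high
signal-to-noise the neural RDM flattens and rank correlations with
graded behavioral RDMs *decrease*.  The synthetic default amplitudes
are chosen below this saturation regime (see below); users simulating
their own conditions should watch for it.

## The synthetic ground-truth model

The generator builds every input the pipeline consumes:

* **Design**: speakers × vowels stimulus sets, repetitions spread over
  blocks, vigilance probe trials (50/50 identical/different pairs,
  never first in a block, never consecutive), onset asynchronies
  jittered in 800–1000 ms.
* **Latent trait space**: speakers receive standardized scores on a
  small number of latent dimensions; the eight characteristics are
  linear combinations (a loading matrix) plus unique residuals, so the
  characteristic intercorrelation matrix ("halo" structure) is
  available in closed form.  Ratings map latent-driven values affinely
  to the 1–9 scale (mean 5, SD 1.5), add per-response rater noise, and
  round and clip.  A ninth scale is generated as pure noise: it fails
  the inter-rater agreement screen (ICC(2,k) near 0) and is dropped,
  exercising the same screening path a real low-agreement scale would
  take.
* **Acoustics**: 13 measures on realistic scales, driven by a small
  number of latent acoustic dimensions through four measure families
  (pitch, formants, harmonic source shape, noise/periodicity).  A
  mixing matrix controls how strongly the latent *traits* leak into the
  acoustic dimensions — the handle for simulating acoustic confounds.
  The LTAS is shaped by vowel identity and speaker gender only, so the
  LTAS covariate stays separable from the feature-PCA covariates.
* **EEG**: each trial is the sum over latent dimensions of
  (speaker latent score × unit-RMS scalp pattern × temporal kernel),
  plus an optional acoustic-confound term, plus stationary Gaussian
  noise with first-order spatial correlation (~0.6 between neighboring
  electrodes) and a 1/f-shaped temporal spectrum.  `snr` is the
  amplitude of a unit-score effect relative to the per-sample noise SD.

**Temporal kernel.**  Effects are windowed with a Tukey
(tapered-cosine) kernel, flat over the central half of the window with
cosine tapers at the edges (`taper = 1` recovers the fully tapered
raised-cosine window).  The flat top is deliberate: a kernel that
decays to zero at the window edges makes the *nominal* window
unrecoverable in principle — no detector can flag time points where
the effect amplitude vanishes — whereas recovery checks are stated in
terms of the nominal window.

## What the recovery scenario encodes, and why it is shaped this way

`recovery_scenario_config()` freezes one fully specified study in which
every downstream claim of the pipeline can be checked against ground
truth: an early physical-like characteristic (age, own latent,
100–300 ms), a late trait-like characteristic (trustworthiness, own
latent, 520–700 ms), a shared "halo" latent carried by the remaining
valenced characteristics (300–520 ms), an emergent characteristic
(attractiveness) defined as the average of two collinear parents, and
an early acoustic confound (0–140 ms) correlated with the age latent.

Three numerical findings from developing this scenario are themselves
methodological results and constrain the design:

1. **Shared stimulus-set noise is not averaged away by participants.**
   All participants are correlated with the *same* mean ratings, so any
   chance or measurement-error overlap between a behavioral RDM and the
   stimulus set's latent geometry is identical for every participant.
   Its magnitude scales with the number of independent *speaker* pairs
   — not stimulus pairs, because latent traits are speaker-level.  The
   scenario therefore uses 24 speakers with a single vowel each: for a
   fixed decoding budget, spending stimuli on more speakers rather than
   more vowels is what shrinks these shared residuals.
2. **Absolute-difference RDMs of latent mixtures carry genuinely novel
   rank information.**  If a characteristic mixes two *independent*
   latents, its distance structure |0.5Δa + 0.5Δb| is not linearly
   spanned (in ranks) by |Δa| and |Δb|; Model 3 then legitimately finds
   a unique contribution for it.  An "emergent" characteristic is only
   fully explained away by its parents when the parents measure the
   same latent direction — hence attractiveness is built as the average
   of two collinear parents (health and dominance, both near-pure
   measures of the halo latent).
3. **Saturation inflates consistency.**  When a window's amplitude
   drives all pairwise accuracies to 1.0, the between-participant
   variance of the RSA correlation collapses and even tiny shared
   residuals become nominally highly significant.  The confound gain
   (1.2 × snr) and the scenario snr (0.45) sit below this regime.

The scenario's amplitude is the documented snr threshold in the sense
that the recovery properties (window coverage ≥ 80%, Model 1 vs
Model 2 confound difference, emergent-characteristic behavior, early
vs late Model 3 ordering) hold in at least 8 of 10 seeds at snr 0.45
under these conditions; lower amplitudes progressively lose the window
edges first, higher amplitudes approach saturation.

## Scales, defaults, and the parameters that matter

Two presets bundle the pipeline parameters:

* `pipeline_config("full")`: 32 speakers × 3 vowels = 96 stimuli, 40
  repetitions, 24 vigilance stimuli × 16 repetitions over 6 blocks,
  1 kHz epochs from −100 to 700 ms, 5 splits, 50 subaveraging
  permutations, 10,000 inference iterations, thresholds 1.64/1.96,
  preprocessing with 0.1–30 Hz zero-phase Butterworth (order 4),
  150 µV peak-to-peak rejection, Tp9/Tp10 re-reference.
* `pipeline_config("desk")`: 8 speakers × 2 vowels = 16 stimuli, 20
  repetitions, 8 participants, a 10-ms grid (100 Hz), 5 permutations,
  1,000 iterations.  Synthetic epochs are generated band-limited,
  baseline-free and artifact-free, so the desk preset skips the
  preprocessing stage; preprocessing is exercised by its own unit
  tests and enabled in the full preset.  The recovery scenario
  overrides the desk scale as described above (24 × 1 stimuli, 15
  repetitions, 20-ms grid, 4 permutations).

Other defaults worth knowing: SVM cost C = 1 with no feature scaling
beyond noise normalization; covariance shrinkage intensity computed
analytically from the training residuals; oblimin rotation with
gamma = 0 (direct quartimin) via gradient projection, components
retained at unrotated eigenvalue > 1 for both the behavioral and the
acoustic PCA; Spearman ties handled by average ranks; rater exclusion
at a modal-response fraction strictly above 0.8, scale-specific;
characteristics dropped below ICC(2,k) of 0.5; LTAS in 100-Hz bins up
to 8 kHz with the cosine computed on linear power spectra (dB offsets
would distort the angle); formant dispersion as the regression slope
of formant frequency on formant number (the mean-spacing reading is
available and identical for arithmetic progressions).

## Numerical and procedural choices

* **Partialling** operates on average ranks via least-squares
  residualization with an intercept; with no covariates it reduces to
  textbook Spearman correlation (tested to 1e-12).  Degenerate cases —
  constant vectors after ranking, covariates collinear with a target —
  return `NA` rather than a number, and such time points are excluded
  from clusters with a warning.
* **Vectorization** takes the strict lower triangle down the columns;
  the upper triangle is redundant by symmetry.
* **t → z conversion** goes through the *t* CDF in the tails
  (`lower.tail = FALSE` on the appropriate side) to avoid underflow.
* **Cluster ties**: membership requires *z* strictly above the
  threshold; the peak statistic uses the earliest time on ties; the
  corrected p is the plain fraction of null maxima at least as large
  as the observed size.
* **Cluster-size discreteness.**  On temporally *white* noise at desk
  scale, suprathreshold runs are 1–3 samples long and the max-size
  null is coarsely discrete, which makes size-based inference strongly
  conservative (family-wise error well below 1%).  Null calibration is
  therefore checked on AR(1) noise (phi = 0.7), matching the temporal
  smoothness that decoding and correlation time courses actually have;
  there the empirical family-wise error sits at 2–4% against the
  nominal 5%.  Sign-flip resampling assumes a symmetric null
  distribution per participant, which holds for correlation-type
  statistics centred on zero.
* **Determinism.**  Every random stage draws through a seed-scoped RNG
  (`with_seed`), and child seeds are derived arithmetically from the
  master seed, so a configuration plus one integer reproduces every
  array bit-exactly; the pipeline writes MD5 hashes of its outputs
  into a manifest to make re-run identity checkable.
* **SMO solver.**  The pairwise decoding inner loop solves the C-SVC
  dual with a maximal-violating-pair SMO specialized for the tiny
  training sets produced by subaveraging (8 pseudo-trials per fit),
  warm-starting each time point from the previous one; its decision
  values agree with libsvm (`e1071`) to the solver tolerance, which
  the test suite checks on random problems.

## What passing the synthetic checks does and does not show

The generator emulates the statistical *structure* the analysis
assumes: speaker-level latent traits expressed in time-windowed scalp
patterns, intercorrelated integer ratings, acoustic measures coupled to
traits, spatially and temporally correlated noise.  It does not emulate
acoustically realistic vowels, eye-blink or muscle artifact morphology,
non-stationary noise, inter-individual differences in scalp patterns or
latencies, or rating biases beyond additive noise.  Passing the
recovery checks therefore shows that the pipeline's statistics do what
they claim under the model's assumptions — correct chance calibration,
controlled false positives, recovery of planted windows, removal of
modelled confounds — not that real voice EEG contains such effects.

Known limitations: with few stimuli, shared stimulus-set residuals
bound how cleanly Model 3 can isolate unique contributions (see above);
decoding saturation compresses high-snr effects; and the per-channel
peak-to-peak rejection is stricter than a joint-across-channels
reading of the same threshold.  The ICA-based ocular cleaning step of
typical EEG pipelines is out of scope (it requires visual component
inspection); a hook accepts externally supplied component masks.
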