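---
title: "Cepstral voice biomarkers for Parkinson's disease: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cepstral voice biomarkers for Parkinson's disease: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdvoice)
```

## The problem

Hypokinetic dysarthria — the speech disorder of Parkinson's disease (PD) —
manifests as monopitch, reduced loudness, breathiness and imprecise
articulation. Acoustically these surface as elevated cycle-to-cycle
perturbation of the vocal-fold period (jitter) and amplitude (shimmer), a
reduced harmonics-to-noise ratio (HNR), and reduced utterance-level pitch
variability. `pdvoice` implements a screening pipeline that discriminates PD
from healthy-control (HC) voices using only short-time cepstral features of
the speech signal, in two settings:

* a **reading task**, where a recording contains one voice and can simply be
  cut into non-overlapping fixed-length samples; and
* a **phone-conversation task**, where a second (healthy) voice is present
  and must first be removed by **speaker diarization**, otherwise the
  interviewer's speech would contaminate the patient class and bias any
  classifier.

Because the corpus this design targets cannot be redistributed, the package
ships a generative stand-in: a source–filter synthesizer whose dysarthria
knobs are explicit, so every stage runs against data with known ground
truth.

## The synthetic voice model

`synth_voice()` follows the classical source–filter decomposition:

1. **Glottal source.** An impulse train whose per-cycle period derives from
   an f0 drawn once per 0.5 s utterance segment from
   Normal(`f0_mean`, `f0_sd`), perturbed per cycle by
   Normal(0, `jitter_pct`/100 × period); per-cycle amplitudes are perturbed
   by Normal(0, `shimmer_pct`/100). The impulse train was chosen over an
   analytic glottal-flow model because its jitter and shimmer are exactly
   controllable and re-measurable from the pulse times
   (`glottal_pulse_train()`, `estimate_perturbations()`). A double real
   pole near 200 Hz shapes the train with the −12 dB/oct roll-off of
   glottal flow.
2. **Aspiration noise.** White Gaussian noise mixed at the requested HNR
   (`hnr_db = Inf` disables it).
3. **Vocal tract and radiation.** Cascaded second-order resonators at the
   formants (two or more `(center, bandwidth)` pairs), then a
   first-difference lip-radiation filter (+6 dB/oct). Without the radiation
   term the source roll-off buries the formant structure and the spectrum
   is not speech-like. The waveform is peak-normalized to 0.9.

All randomness flows through one seeded generator per call (`with_seed()`
restores the caller's RNG state), so identical `(spec, seed)` pairs are
bit-identical.

**Class distributions.** `synth_cohort()` draws per-recording specs around
class means (`hc_class_defaults()`, `pd_class_defaults()`): HC ≈ 0.5 %
jitter, 3 % shimmer, 20 dB HNR, f0_sd 15 Hz; PD ≈ 2 % jitter, 8 % shimmer,
10 dB HNR, f0_sd 4 Hz (monopitch). These are configuration constants placed
in typical dysarthria-literature ranges — the target corpus publishes no
per-subject acoustics, so the class gap is necessarily invented and should
be read as "a clearly dysarthric class", not as an estimate of any real
population.

**Conversations.** `synth_conversation()` concatenates alternating
scripted turns with 0.25 s silent gaps (no additive background noise,
matching call recordings taken off-stream) and returns the exact speech
timeline. Turns are RMS-equalized to the quietest turn, emulating a
telephone channel's gain control; without this, per-turn peak normalization
leaves one voice systematically louder, which biases the energy-weighted
embeddings at turn boundaries.

**What the generator does not emulate:** phonetic content, prosodic
contours, coarticulation, overlapped speech, channel noise and reverberant
rooms. Passing tests therefore demonstrate that the *pipeline machinery* is
correct and that the statistical claims hold under controlled separation —
not that the same accuracies would be obtained on real clinical recordings,
where class separation is far weaker.

## Cepstral front-ends

Both feature sets share one pipeline (per 25 ms Hamming frame, 10 ms hop,
after 0.97 pre-emphasis):

power spectrum → filterbank energies → `log(max(E, log_floor))` →
orthonormal DCT-II → first 13 coefficients.

* **MFCC** uses 40 triangular filters with apexes equally spaced on the HTK
  mel scale `2595·log10(1 + f/700)` between 50 Hz and the Nyquist
  frequency.
* **GTCC** substitutes 40 4th-order gammatone magnitude responses
  `(1 + ((f − fc)/(1.019·ERB(fc)))²)⁻²` centred on the ERB-rate scale,
  where `ERB(f) = 24.7(4.37 f/1000 + 1)`. Realizing the gammatone bank as
  sampled frequency-domain responses (rather than time-domain IIR filters)
  lets GTCC share the MFCC code path and the same independent oracle; the
  3 dB bandwidth of this response is 0.886·ERB, the standard 4th-order
  relation. Time-domain equivalence is not claimed.

Decisions where common practice leaves room:

* **c0 included**: the 13 coefficients are c0..c12 (`include_c0 = FALSE`
  gives c1..c13). c0 carries log-energy; amplitude scaling of a noiseless
  input moves only c0 (a tested invariant).
* **Aggregation**: one feature row per audio sample is the per-coefficient
  *mean* over frames (median and mean+sd are available via
  `cepstral_config(aggregate=)`).
* **Normalization**: z-scores are fit on training rows only and applied to
  test rows — the leak-free reading. Fitting on the pooled table
  (`zscore_fit` on everything) reproduces the laxer "global" reading if
  needed for comparison.
* **`log_floor = 1e-10`** guards digital silence; it is recorded in the
  serialized config of every run.

## Speaker diarization

`diarize()` slides 1 s windows at a 0.25 s hop, embeds each window,
k-means-clusters the embeddings with `k = n_speakers` (plus one when a
noise cluster is requested; that cluster is identified afterwards as the
one with the lowest mean window energy and excluded from export), smooths
the window labels, and merges hop-sized strides into segments.

* **Embedding.** The default embedder is deterministic cepstral
  statistics: the energy-weighted mean and standard deviation of the
  per-frame MFCCs (26 values). Energy weighting matters: near-silent gap
  frames produce floor-value cepstra which would otherwise dominate
  boundary windows and make the clusterer separate silence from speech
  instead of speaker from speaker. A neural speaker embedding can be
  plugged in via `diarization_config(embedder = function(wave, cfg) ...)`;
  none is shipped.
* **Clustering.** Lloyd iteration with greedy farthest-point seeding from
  a seeded random start; assignment ties break to the lowest cluster
  index; converged when assignments stabilize (≤ 300 iterations). The
  within-cluster sum of squares is recorded per iteration and is
  non-increasing (tested).
* **Smoothing.** A recursive majority vote over 5 windows: positions
  before the current one contribute their already-smoothed labels, which
  makes one pass reach a fixed point of the filter; ties prefer the
  preceding label (temporal continuity), then the smallest label.
* **Boundary resolution.** Each hop-sized stride takes the label of the
  window centred nearest it (equidistant ties go to the later window so a
  speaker change takes effect promptly), and the final label runs to the
  end of the stream. The hop is therefore the boundary resolution; 0.5 s
  was measurably too coarse (boundary snap alone cost ≈ 5 points of
  time-weighted agreement on 3–4 s turns), which is why the default hop is
  0.25 s.
* **Scoring.** `diarization_accuracy()` maps true speakers to clusters by
  the best injective assignment and reports the time-weighted agreement
  over ground-truth speech; it is invariant under cluster relabelling.
  `speaker_purity()` reports how much of an extracted cluster's duration
  belongs to its speaker. Because contiguous strides must assign the
  silent gaps to someone, purity has a structural ceiling of roughly
  turn/(turn + gap) even for perfect diarization.

The subject in a two-party call is taken to be the cluster with the
greatest total speaking time (`dominant_cluster()`), overridable per call.

## Classification protocol

Three fixed families (`model_spec()`): a cubic-kernel SVM (one-vs-one
decision scheme, which degenerates to the single binary machine here;
margin penalty tuned over {0.1, 1, 10}), 1-nearest-neighbour with
Euclidean distance (nothing to tune — the inner loop degenerates and is
recorded as such), and a "wide" neural network with one hidden layer of
100 rectified units (softmax output, full-batch Adam, 200 epochs, ridge
penalty tuned over {1e-4, 1e-2, 1}; weight initialization is seeded in R
and the compiled training loop is deterministic).

`nested_cv_train()` runs stratified 5×5 nested cross-validation: the inner
loop grid-searches on each outer-train portion (ties to the smallest
value), the outer loop estimates generalization, and the final model is
refit on the full table with the majority-vote hyperparameter. *Training
accuracy* is reported as the mean accuracy on the outer-fold training
portions (the resubstitution alternative is a flag away);
*test accuracy*, sensitivity, specificity and F1 (PD positive) come from
`evaluate()` on the held-out table, which is touched exactly once per
configuration. `run_model_suite()` crosses the three families with
MFCC-only, GTCC-only and combined features — nine reports, mirroring the
reported experiment grid.

Tables are class-balanced by seeded sampling without replacement
(`build_tables()`). The default draw is at sample level, which can place
samples of one recording in both tables; `audit_table()` always reports
this subject overlap, and `subject_disjoint = TRUE` enforces the stricter
split. On the synthetic cohort the classes are strongly separated, so the
suite saturates near 100 % accuracy regardless; the audit exists because
on real data the sample-level draw is an optimistic-bias risk.

## Group inference

`unpaired_ttest()` implements the two-sided two-sample t-test (Student
pooled-variance by default — the conventional reading of "unpaired
t-test" — with Welch available and preferable under unequal variances).
Two zero-variance groups with equal means return t = 0, p = 1 rather than
erroring. `coefficient_panel()` runs one test per coefficient (mfcc_0..12
then gtcc_0..12) and annotates stars at p < 0.05/0.01/0.001/0.0001.
Correction defaults to none (matching the uncorrected-star convention of
the target analysis); Holm is available and reported side by side, which
is advisable with 26 tests. Note that per-segment feature rows from the
same speaker are pseudo-replicates: with few speakers the t statistics are
optimistic, which is another reason the panel is descriptive here.

## Numerical and testing choices

* Problem sizes in the shipped tests and acceptance script: 50/50-recording
  cohorts of 2 s recordings for end-to-end checks, 10-seed replications,
  500-replicate null calibration resampled from a 120-recording pool.
  These sizes make the full suite run in a few minutes while leaving the
  statistical checks well-powered.
* The null calibration resamples two disjoint 50-row groups from one
  same-class pool — exchangeable by construction, hence an exact null —
  and the rejection rate is assessed pooled over the 26 coefficients
  (a per-coefficient band of ±2 points around 5 % over 500 replicates
  would be violated by chance alone about two times in three across 26
  binomial rates).
* Chance-level checks on permuted labels are asserted on the mean over 20
  permutations (a per-permutation band on n = 40 would likewise fail by
  chance regularly).
* The cepstral oracle is a naive O(N²) Fourier sum with explicit cosine
  DCT sums, independent of the `stats::fft`/matrix code paths, compared at
  1e-8 relative tolerance; scale round trips at 1e-9; DCT orthonormality
  at 1e-10.
* Unperturbed-voice periodicity is asserted after a 10-cycle settling
  window because the resonators are IIR: their transients decay
  geometrically (≈ 0.08 per cycle at the default first formant), so the
  first cycles of the waveform are not yet periodic at machine precision.

## Known limitations

* The cepstral-statistics embedder suffices for clean, loudness-equalized,
  spectrally distinct voices; it is not a speaker model. Overlapped
  speech, noise robustness, and unknown speaker counts are out of scope.
* The synthetic class gap is large by design; none of the reported
  synthetic accuracies transfer to real recordings.
* WAV support covers integer PCM (8/16/24-bit) and 32-bit float, mono or
  multi-channel (averaged); compressed telephony codecs are out of scope.
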