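---
title: "Fingerprinting Doppler ultrasound audio: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprinting Doppler ultrasound audio: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dopplerprint)
```

## The problem

Pulsed-wave Doppler ultrasound renders blood flow in two simultaneous forms:
a spectral display of velocity against time, from which machines extract the
conventional indices (peak-systolic velocity PSV, end-diastolic velocity
EDV, pulsatility index PI, resistive index RI), and a continuous audio
signal that clinicians listen to but that is almost never recorded or
analysed. `dopplerprint` implements an audio-fingerprinting approach to that
second stream: each recording is reduced to a five-element spectral
fingerprint, a collection of fingerprints is indexed by principal component
analysis (PCA), and similar or dissimilar recording pairs are selected and
ranked by Euclidean distance between scores. The package also carries the
comparison branch (the time-domain indices above, fed through their own
PCA), the statistics used to validate the fingerprint classification against
a panel of human listeners, and a synthetic Doppler audio simulator so that
the entire pipeline runs, and is tested, without any real recordings.

## The fingerprint pipeline

For one recording sampled at $f_s$ (44100 Hz throughout), the stages are:

1. **Periodogram** (`compute_periodogram`). A one-sided power spectral
   density estimate over the full recording: rectangular window, no
   detrending, DFT zero-padded (or truncated) so that exactly
   $n_\text{freq} = 100{,}000$ equally spaced frequencies from 0 to
   $f_s/2$ are returned. Power is reported in decibels,
   $10\log_{10}(\mathrm{PSD}/P_\text{ref})$.
2. **Binning** (`bin_spectrum`). Consecutive blocks of 80 frequency values
   are averaged (dB values, matching the plotted spectrum; a trailing
   remainder is dropped), giving 1250 bins whose centres are the mean
   frequency of each block.
3. **Band selection** (`select_band`). Bins 10 through 200 (1-based, both
   inclusive; 191 bins) are retained, discarding low-frequency vessel-wall
   signal and high-frequency instrumentation noise.
4. **Peak detection** (`find_prominent_peaks`). The 10 most prominent local
   maxima are kept. For a peak of height $h$, each *base* is the minimum of
   the spectrum between the peak and the nearest strictly higher point on
   that side (or the spectrum end); the *prominence* is $h$ minus the higher
   of the two bases; the *width at half prominence* is the distance, in
   fractional bins, between the linearly interpolated crossings of the level
   $h - \text{prominence}/2$, searched no farther than the bases. The peak's
   *location* is its bin centre in Hz.
5. **Reduction** (`build_fingerprints`). The $10 \times 4$ peak parameters
   per recording (40 values) are reduced in three stages: (i) each of the
   four parameter types is divided by its maximum pooled over all peaks of
   all recordings; (ii) per recording the normalized values collapse to the
   sum of prominences, sum of heights, sum of widths, mean of locations and
   sample variance of locations; (iii) each of the five columns is divided
   by its maximum over recordings, so every column of the final matrix has
   maximum exactly one. All nine normalization constants are stored, and
   `apply_fingerprint` projects a new recording through the frozen
   constants, which is what makes the collection usable as a query index.

### Design choices in the spectral stage

* **dB reference.** Peak heights are dB values and flow into a
  max-normalization that is only meaningful (and only well-defined — the
  constants must be positive) if heights are positive. Full-scale-relative
  dB of any realistic recording is negative throughout, so the package
  expresses power relative to a tiny reference, $P_\text{ref} = 10^{-12}$,
  the convention of acoustic intensity level. Differences, prominences,
  widths and locations are unaffected; only the height offset moves. Zero
  power is floored at $-300$ dB.
* **Stage-(i) pooling.** The first normalization pools each parameter over
  the whole collection rather than per file. A per-file maximum would force
  every recording's largest height to 1 and destroy the between-recording
  loudness information that `sum_height` carries. Because recording gain is
  operator-controlled, `sum_height` is the one gain-sensitive feature; the
  other four are invariant to rescaling the audio (a property the test
  suite asserts).
* **Determinism rules.** A flat-topped local maximum is represented by its
  leftmost point; prominence ties for the last peak slot are broken toward
  the lower bin index; equal locations in the feature matrix are ordered by
  descending prominence. Recordings with fewer than 10 local maxima in the
  band are rejected rather than padded, so every feature matrix has
  identical shape and fingerprints stay comparable.
* **Variance denominator.** `var_location` uses the sample variance
  ($n - 1$); with $n = 10$ peaks the choice is material and is fixed here
  once.
* **Band arithmetic.** With the defaults, the 191 bins span roughly
  160–3530 Hz, which comfortably contains the Doppler shifts of carotid
  flow under the simulator's frequency mapping (see below). All of
  $n_\text{freq}$, bin size, band and peak count are exposed as parameters.

## Similarity indexing

`fit_pca` mean-centres the fingerprint matrix and takes the leading
principal components (default 4). No variance scaling is applied: the five
features already share a max-normalized scale, and autoscaling would inflate
whichever feature happens to vary least. Loadings follow the convention that
each column's largest-magnitude entry is positive, making scores
reproducible. `score_distances` computes Euclidean distances between
recordings in the leading score dimensions — two by default, the dimensions
a scores plot shows. `select_pairs` then picks, greedily and without
replacement of recordings, the closest cross-subject pairs (similar) and the
farthest cross-subject pairs (dissimilar); requiring the members of every
pair to come from different subjects prevents the selection from trivially
rediscovering repeated recordings of one individual. Greedy selection with
id-based tie-breaks is deterministic and independent of input row order.
`rank_pairs` orders the selected pairs under two distance tables (for
instance the fingerprint PCA versus the hemodynamic-index PCA) and reports
the Spearman correlation between the orders.

**Cross-validation.** `venetian_blinds_press` assesses component count with
interleaved row hold-out (every $s$-th row per fold). Held-out rows are
*not* simply projected onto the training loadings: complete-row projection
residuals shrink monotonically as components are added, so they cannot
reveal the model rank. Instead each held-out variable is predicted from the
row's other variables through the training loadings (variable-wise
deletion), the standard remedy; PRESS then genuinely rises once components
start fitting noise. This caps the assessable component count at $p - 1$.
PRESS is reported for inspection and does not auto-select the rank.

## Time-domain indices

`compute_indices` evaluates the conventional indices from a velocity
waveform: PSV and $V_\min$ are the extrema, $\bar V$ is the trapezoidal
time-average over complete cardiac cycles (a trailing partial cycle is
discarded), and EDV is the velocity at each complete cycle's boundary
(nearest sample), averaged over cycles for noise robustness — ultrasound
machines report EDV from their own proprietary landmark logic, so a
landmark had to be fixed here. Then $PI = (PSV - V_\min)/\bar V$ and
$RI = (PSV - EDV)/PSV$. Both are invariant under rescaling the velocities.
Repeated samples of one vessel are averaged per (subject, side) by
`average_indices`. Estimating the velocity envelope from the audio itself
is out of scope; the time-domain branch consumes waveforms (ground truth
from the simulator, or CSV input).

## The panel statistics

A listening panel hears sets of paired recordings and, per set, either
agrees (1) or disagrees (0) with the fingerprint classification.
`agreement_summary` reports the mean per-rater score, the grand total of
agreements, and the percent agreement rounded half-up to an integer.
`one_sample_ttest` tests the per-rater scores against the chance mean
(2.5 for five binary sets), two-sided, via `stats::t.test`.
`fleiss_kappa` implements the multi-rater chance-corrected agreement
statistic directly from its defining formulas and is validated against an
independent direct-evaluation oracle in the tests; note that the panel's
kappa depends on *which* sets raters missed, information that per-rater
totals alone do not determine.

## The synthetic Doppler simulator

The simulator exists so that every downstream stage has inputs with known
ground truth. It is a phenomenological model of what carotid Doppler audio
sounds like, not a physical model of insonated blood.

**Velocity waveform.** Each cardiac cycle of period $60/\text{HR}$ rises
from EDV to PSV along a raised half-cosine over the first `systole_frac` of
the cycle and decays exponentially (time constant `decay_frac` of the
cycle, rescaled to end exactly at EDV). The contract is only that per-cycle
maxima equal PSV, cycle boundaries sit at EDV, and the waveform never drops
below EDV; the pulse shape itself is a configuration choice. The two shape
parameters exist because the pulsatility index of a fixed shape is fixed:
sharper systole means lower mean velocity and higher PI, and spanning the
PI range observed in healthy dogs (roughly 1 to 4.4) requires varying the
sharpness, not just PSV and EDV.

**Audio synthesis.** The audible Doppler shift is modelled as
$f(t) = k \cdot v(t)$ with `doppler_scale` $k = 20$ Hz/(cm/s) by default —
the order of magnitude produced by a 5–9 MHz transducer at a 60° insonation
angle — placing carotid velocities in the few-hundred-Hz-to-4-kHz band
where real Doppler audio lives. The signal is an overlap-add of
Hann-windowed frames (1024 samples, 50% hop), each a sum of 64
random-phase sinusoids with frequencies drawn from a Gaussian centred on
$k\,v(t)$ with sd `spectral_bandwidth`/2 (default 200 Hz, emulating
spectral broadening), amplitude modulated proportionally to $v(t)$, plus
white noise at `noise_floor` (default 0.01) of the clean peak amplitude.
Output is normalized to peak amplitude 0.9 and is bit-identical given the
seed. The testable contract is that the short-time spectral centroid,
divided by $k$, tracks $v(t)$; `estimate_psv_edv` recovers PSV (trace
maximum) and EDV (cycle-boundary values) from it. The centroid estimator
suppresses broadband noise by flooring bins far below the frame maximum —
without this, the noise (mean frequency $f_s/4$) biases the centroid upward
exactly where the signal is weakest, in diastole.

**Corpus defaults.** `simulate_corpus` assigns subjects round-robin to two
canonical profiles — low-resistance (PSV 120, EDV 45 cm/s, broad pulse,
PI ≈ 1) and high-resistance (PSV 160, EDV 15 cm/s, sharp pulse, PI ≈ 4) —
with ~3% per-subject velocity jitter and a few beats/min of heart-rate
jitter. Defaults are 10 subjects with four recordings each (two per vessel
side, mirroring how such studies acquire data; it also gives the greedy
pair selection slack, which with only two recordings per subject can
strand two same-subject recordings for the final dissimilar pair), 4 s per
recording at 120 beats/min — exactly the required minimum of eight cardiac
cycles, enforced at construction.

**What the simulator does not emulate.** Transit-time and geometric
spectral broadening, wall-filter artifacts, machine gain riding, ambient
clinic noise, disease states, and any within-cycle waveform morphology
beyond the two-parameter pulse. Consequently, passing tests demonstrate
that the pipeline's operators are correct and that the method separates
hemodynamically distinct signals under controlled conditions — not that it
attains any particular performance on clinical recordings.

## Numerical choices and degenerate inputs

* Periodogram of an all-zero signal: floored at $-300$ dB with a warning.
* Peak detection on a spectrum with fewer than `n_peaks` local maxima, a
  non-positive pooled normalization constant, a pair selection that cannot
  find enough disjoint cross-subject pairs, a constant rating sample, or a
  panel that used a single category everywhere: each raises a typed
  condition (`insufficient_peaks`, `degenerate_feature`,
  `selection_error`, `degenerate_sample`, `degenerate_marginals`) rather
  than returning a misleading number.
* Audio files are written as 16-bit PCM (WAV or AIFF by extension);
  round-trips are exact to one quantization step, and out-of-range samples
  are clamped with a warning. Multi-channel input is downmixed by channel
  mean.
* All randomness flows from explicit seeds; synthesis and corpus
  generation save and restore the caller's RNG state.

## Problem sizes in the tests

The test suite and the acceptance script run entirely on synthetic data:
oracle comparisons use 100 random short spectra, 50 random $10 \times 5$
matrices and 100 random binary rating matrices; simulator recovery uses 20
random configurations at the minimum eight-cycle duration; the
discrimination check uses the default corpus (10 subjects × 4 recordings
× 4 s). These sizes exercise every operator and invariant while keeping a
full run in the order of a minute.

## A worked run

```{r example}
library(dopplerprint)
res <- run_pipeline("doppler_run", config = run_config(seed = 1))
res$pairs           # 5 similar + 5 dissimilar cross-subject pairs
res$ranking$spearman  # rank agreement of fingerprint vs hemodynamic branch
```

## Known limitations

The fingerprint discards all temporal structure (it is a single whole-file
spectrum; no spectrogram or cepstral features), `sum_height` is sensitive
to recording gain, and the five features are validated here only against
simulated audio. The PCA preprocessing (centering without scaling) and the
two-dimensional distance space are fixed but configurable choices; other
reasonable choices would select different pairs on the margins.
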