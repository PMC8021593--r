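---
title: "Seizure burden monitoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seizure burden monitoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(szburden)
```

## The problem

Nonconvulsive seizures in critically ill patients are invisible without
EEG, and expert review of continuous EEG is slow and scarce. A practical
bedside quantity is the **seizure burden**: the percentage of 10-second
epochs within a trailing 5-minute window that contain electrographic
seizure activity, updated every 10 seconds. Burden summarizes seizure
*prevalence* rather than individual events, maps onto the clinical
prevalence vocabulary (frequent = 10%, abundant = 50%, continuous = 90%),
and its 90% level — 4.5 minutes of seizure activity within 5 minutes —
approaches the 5-minute definition of status epilepticus, so an upward
crossing of 90% is treated as a status-epilepticus (SE) alert.

`szburden` implements this pipeline end to end for recordings from a
10-electrode circumferential headband (two lateral chains of five
electrodes, anterior to posterior, approximating Fp1–F7–T3–T5–O1 and
Fp2–F8–T4–T6–O2), sampled at 250 Hz and re-referenced to the 8-channel
longitudinal bipolar montage.

## Per-epoch classification model

The pipeline's atomic decision is binary: each nonoverlapping 10-second
bin is seizure or nonseizure, decided deterministically. Commercial
systems make this decision with a trained model whose weights are not
public; `szburden` substitutes a transparent conjunctive rule over the
same four feature families, with every threshold exposed in
`classifier_config()`:

* **Power** — Welch band powers (delta 1–4, theta 4–8, alpha 8–13, beta
  13–30 Hz; standard clinical edges, the analysis band being 1–30 Hz) and
  their ratios to total 1–30 Hz power.
* **Morphology** — RMS and peak-to-peak amplitude, line length
  $\sum_t |x_{t+1}-x_t|$, variance, excess kurtosis, and the second-half /
  first-half RMS ratio.
* **Rhythmicity/regularity** — sample entropy $\mathrm{SampEn}(m=2,\,
  r=0.2\,\mathrm{SD})$, low for self-similar rhythmic ictal activity, and
  normalized spectral entropy of the 1–30 Hz spectrum, low when power
  concentrates at one frequency.
* **Correlation** — maximum and mean absolute Pearson correlation over
  all channel pairs, high when rhythmic activity is coherent across
  derivations.

A bin is labeled seizure iff at least `channel_quorum` (default 2)
channels simultaneously satisfy the amplitude criteria (line length ≥ 2.0×
and RMS ≥ 1.8× that channel's background level) and the rhythmicity
criteria (SampEn ≤ 0.55 nats, spectral concentration
$1-H_{sp}$ ≥ 0.45), *and* the bin's maximum cross-channel correlation is
at least 0.5.

**Background normalization.** Amplitude criteria need a per-record
reference. The background level per channel is a causal running median of
line length and RMS over the trailing 60 bins (10 min) *that were
themselves labeled nonseizure*. Excluding detected seizure bins keeps a
long seizure from inflating its own reference and silencing the detector
mid-status; restricting to prior bins keeps the classifier causal, so
truncating a record never changes earlier labels. Until 6 background bins
have accrued, fixed fallback levels (2500 µV line length per bin, 12 µV
RMS — typical of moderate-amplitude background) are used.

**Calibration.** The default thresholds were fixed once against the
package's synthetic cohort at its default signal-to-noise ratio, targeting
at least 90% bin sensitivity and at most 5% bin false-positive rate, and
then frozen (`inst/extdata/classifier-default.yaml`); on the calibration
cohort they achieve 99% bin sensitivity with no false-positive bins. They
are a documented stand-in, not a reproduction of any proprietary model:
the contract they preserve is determinism, 10-second granularity and the
four feature families.

## Burden arithmetic and alerting

With labels $\ell_k \in \{0,1\}$, the burden at step $k$ is

$$ B_k \;=\; 100 \cdot \frac{1}{30} \sum_{j=\max(0,k-29)}^{k} \ell_j . $$

The denominator is fixed at 30 bins even during the first five minutes of
a recording. This is deliberate: the alert then requires a genuine 4.5
minutes of accumulated seizure activity, and a true seizure whose 90%
window is never completed before the recording stops (or that starts too
close to the record end) correctly fails to alert. `generate_alerts()`
fires on each upward crossing of the 90% level and re-arms only after the
trend falls strictly below it — one alert per excursion, avoiding alarm
storms, since the deduplication behavior of deployed systems is not
public. The record-level output is the maximum burden over the recording;
detection at threshold $\theta$ is equivalent to the maximum burden
reaching $\theta$.

## Events and scoring

Predicted events are maximal runs of seizure bins (optionally merged
across gaps of ≤ `merge_gap_bins` and filtered by `min_bins`; defaults 0
and 1). Matching against reference events uses the any-overlap rule —
the most common convention in seizure-detection scoring, and the natural
reading of an event counted "detected" without a stated overlap fraction.
False-positive events over reference HEP (highly epileptiform pattern)
intervals still count as false positives for seizure scoring but are
tagged, so the share of false alerts explained by HEP can be reported.
The false detection rate is false-positive events per hour of recording.
Confidence intervals are exact Clopper–Pearson (beta-quantile) intervals:
the published analysis names only "established formulas", and the exact
method behind its printed intervals could not be reverse-engineered, so
interval values are reported but never asserted against printed ones.

Patient-level sensitivity at each threshold uses duration-matched
positive sets: at 90%, records with a seizure ≥ 4.5 min; at 50%, ≥ 2.5
min; at 10%, any seizure. In the shipped reference-cohort summary
(`reference_cohort()`, 353 records, 1052 h) the ≥ 2.5-min positives are
taken as the 9 SE records plus the 3 SZ records in the 50–89% burden row —
the only assignment simultaneously consistent with the published
patient-level table and 100% sensitivity at the 50% threshold.

## The synthetic generator

`simulate_record()` emulates the four expert categories with ground-truth
annotations so the whole pipeline is testable without patient data:

* background on every channel: 1/f ("pink") noise at 12 µV RMS plus 3 µV
  white sensor noise;
* **NL** adds a 9.5 Hz alpha rhythm (15 µV, slowly amplitude-modulated)
  weighted toward posterior derivations;
* **SL** instead adds diffuse polymorphic 1–3 Hz delta (20 µV);
* **HEP** adds lateralized periodic sharp biphasic transients (~80 µV,
  1 Hz, left chain weighted anterior-to-posterior);
* **SZ/SE** superimpose rhythmic ictal activity on all channels: onset
  3.5–4 Hz at 70 µV with linear frequency and amplitude evolution
  (chirp), 5-s on/off ramps, a second harmonic for sharpness, and
  per-channel gains in [0.7, 1.2] to keep cross-channel correlation high.
  SZ intervals are shorter than 5 minutes (default one 2-min seizure); SE
  contains at least one interval of ≥ 5 minutes (default 6 min), so its
  ideal-label burden necessarily reaches 100%.

All randomness flows from the spec's single seed through a local RNG
(the session's `.Random.seed` is restored), making records bitwise
reproducible; cohort seeds derive deterministically from one master seed.

These recipes are invented stand-ins; the fidelity target is
**feature-level separability** (ictal bins have higher line length and
correlation and lower sample entropy than background), not clinical
realism. Passing tests on this simulator shows the pipeline's arithmetic,
causality and calibration behave as specified — it does not demonstrate
clinical accuracy on real EEG, which contains artifacts (chewing,
electrode pops), ictal–interictal-continuum patterns and montage
imperfections the simulator does not model.

## Numerical choices and degenerate inputs

* EDF I/O quantizes to 16-bit integers over ±3276.7 µV (0.1 µV
  resolution); files at other sampling rates are polyphase-resampled to
  the working rate of 250 Hz.
* A trailing partial bin (< 10 s) is discarded — features are defined on
  full bins only; all intervals are half-open `[start, end)` and bins are
  0-indexed.
* Welch estimation uses 2-s Hann windows at 50% overlap — nine segments
  per bin, a stable estimate at 0.5 Hz resolution.
* Degenerate conventions keep feature vectors finite and biased toward
  nonseizure: 0/0 power ratios → 0, constant-signal kurtosis and both
  entropies → 0, 0/0 half-RMS ratio → 1, zero-variance channels
  contribute 0 correlation.
* Sample entropy with no template matches returns 0 rather than infinity.
* `classify_burden_level` uses half-open category intervals
  ([10, 50), [50, 90), [90, 100]) so each printed threshold belongs to
  the category it names.

## Problem sizes

The test suite and examples run the full pipeline on a 20-record
synthetic cohort (2 SE / 2 SZ / 5 HEP / 11 NL-SL, 10-minute records) —
large enough to exercise every category and both error directions while a
complete run stays interactive; Monte-Carlo feature checks use 100–200
seeded replicates. These sizes are the package's own defaults for its
validation suite; nothing about the method depends on them.

## Known limitations

* The rule classifier is a transparent stand-in: its thresholds were
  calibrated on synthetic data and transfer to real recordings is
  untested and untestable here (no public recordings exist for this
  device).
* Only the four named feature families are implemented; any per-patient
  baseline adaptation or post-hoc label smoothing a deployed system might
  apply is intentionally not guessed at.
* Artifact handling is limited to the classifier's background
  normalization; there is no artifact-subtype detector.
* Event merging behavior of the published false-detection counts is
  unknown; `merge_gap_bins` is exposed rather than fixed.
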