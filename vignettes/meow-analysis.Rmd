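---
title: "Methods: acoustic meow characterization and listener-survey analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic meow characterization and listener-survey analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `catvoc`. It is the place where genuinely open design
decisions are recorded with their rationale.

## 1. The acoustic feature space

Each recording (mono PCM, 8 kHz) is analysed framewise — 32 ms frames
(256 samples), 10 ms hop (80 samples), periodic Hann window — and reduced to
ten per-recording values: mean and sample standard deviation (denominator
n−1) of F0, roughness R, and tristimulus T1, T2, T3. The framing guarantees
at least two periods of a 100 Hz fundamental per frame; the "mean and SD"
reading of the per-feature summary is the interpretation that yields exactly
a 10-value space (an alternative reading as a range statistic would too, but
SD is the conventional second moment and is what we implement).

### Fundamental frequency

`estimate_pitch()` correlates the square-root-compressed magnitude spectrum
of each frame with sawtooth-spectrum templates on a log-spaced candidate
grid (48 steps/octave, parabolic refinement over log-frequency). Templates
have cosine lobes at the fundamental and at prime-numbered harmonics with
`1/sqrt(k)` weights — the square-root compression of a `1/k` harmonic
amplitude decay — and are mean-removed and unit-normalized, so the cosine
similarity between frame and template is a pitch strength in [−1, 1]. Its
rectification to [0, 1] is the reported confidence. Consequences that the
tests verify: harmonic tones score high (well above 0.5), white noise
almost never exceeds 0.15, and silence gives exactly 0 with `f0 = NA`
rather than an error.

The confidence gate is **inclusive**: frames with confidence ≥ 0.15 count as
voiced ("below 0.15" is what gets ignored). F0 and tristimulus statistics
use voiced frames only; roughness, which is defined without a fundamental,
uses every frame.

The search range defaults to 100–1000 Hz, bracketing the meow F0 range the
synthesizer produces (250–700 Hz) with margin; the permissible range of the
interface is 50–2000 Hz.

### Roughness

`roughness_frame()` implements the partial-pair model: each unordered pair
of spectral peaks contributes

    (a1 a2)^0.1 · 0.5 (2 min(a1,a2)/(a1+a2))^3.11 · (e^(−b1 s Δf) − e^(−b2 s Δf)),
    s = s* / (s1 · f_min + s2)

with b1 = 3.5, b2 = 5.75, s* = 0.24, s1 = 0.0207, s2 = 18.96 (constants from
the partial-pair roughness literature; they are configuration, not fitted
here). The exponential difference peaks when the pair separation is a fixed
fraction of the critical band at the lower frequency — about 70 Hz near
1 kHz — and the amplitude terms make the total scale as `c^0.2` when both
amplitudes scale by `c`.

**Peak picking.** The model is meant for *partials* — genuine sinusoidal
components — not for every wiggle of a magnitude spectrum. Peaks are local
maxima above −60 dB of the frame maximum, capped at the 20 largest, **and**
above a linear contrast floor of 0.04 of the frame maximum (−28 dB). The
linear floor is the load-bearing part: the Hann window's first sidelobe sits
at −31.5 dB, and without the floor, clusters of sidelobe peaks — tiny but
equal-amplitude, which the model's scale-free `(2·min/(a1+a2))^3.11` term
rewards maximally — dominate the estimate and mask real modulation
sidebands. 0.04 is chosen from window properties (just above −31.5 dB), so
windowing artifacts never register as partials while harmonics and
modulation sidebands of depth ≳ 0.1 do. This mirrors the linear
contrast-threshold convention of spectral peak pickers in
music-information-retrieval toolboxes.

**Resolution constraint.** A 32 ms frame resolves structure no finer than
±62.5 Hz (Hann main-lobe half-width). Amplitude modulation below ~60 Hz
therefore produces sidebands that merge into the carrier lobe and are
invisible to any spectral pair model at this framing. The synthetic
generator's modulation rates are accordingly placed at 60–90 Hz — which is
also where psychoacoustic roughness is maximal for carriers in the meow F0
range — so that modulation depth is actually expressed in the feature.

### Tristimulus

T1, T2, T3 are the fractions of total frame energy at the fundamental,
harmonics 2–4, and harmonics ≥ 5. Each bin is assigned to its nearest
harmonic `k = round(f/f0)` if it lies within the harmonic's band; the band
half-width is 3% of `k·f0` (≈ half a semitone, absorbing tracker error and
glide within a frame), widened to at least 62.5 Hz — again the main-lobe
half-width, so a partial's leaked energy is collected whole. Nearest-harmonic
assignment prevents double counting when bands would overlap (f0 < 125 Hz).
The denominator is the *total* spectral energy, so noise and inharmonic
energy leave `t1 + t2 + t3 ≤ 1`; zero-energy frames are undefined and are
dropped from aggregation.

## 2. Feature screen and exemplar selection

`anova_screen()` runs a classic equal-variance one-way ANOVA per feature
column, independently, keeping columns with p < α (default 0.05). No
multiple-testing correction is applied and ANOVA assumptions are not tested
(deliberately — this mirrors the screening procedure the pipeline
implements; a Welch flag exists for sensitivity analysis). Screening is per
*column*; `screen_family_summary()` reports the per-family verdict, a family
counting as discarded only when both its mean and SD columns failed.

Distances to class centroids are computed, by default, after z-scoring the
kept columns over all recordings: Hz, roughness units and energy ratios are
incommensurate, and an unstandardized Euclidean distance would be dominated
by F0. `standardize = FALSE` reproduces raw-space behavior; whether the
original procedure standardized is unknown, so both are provided and the
mode is recorded in pipeline output.

Medioid = argmin distance to own-class centroid, outlier = argmax. Exact
distance ties break toward the lexicographically lowest `clip_id`,
independently per role — so two exactly equidistant points in a two-point
class name the same clip for both roles; with real-valued features this is a
measure-zero event, and the deterministic rule is what matters for
reproducibility. Selection is verified against an exhaustive-search oracle
on random datasets.

## 3. The survey battery

* **AES**: 22 nine-point items, 11 empathic and 11 unempathic; unempathic
  items are reverse-scored (`10 − x`) and the total ranges 22–198. The
  published item key is distributed with the instrument and is a
  configurable input; the package default (odd items empathic) is synthetic
  and clearly labelled as such.
* **CES**: 3 nine-point items summed, range 3–27.
* **Accuracy tables**: correct/incorrect counts with percentages to two
  decimals; 2×2 comparisons use the Pearson chi-square. Continuity
  correction defaults **off**; where conclusions could depend on the
  convention the pipeline reports both, and only convention-stable cells are
  asserted in tests.
* **Chance level**: exact binomial test against p0 = 1/3 (the "0.33%" print
  is read as the proportion 1/3), reporting both one-sided (greater) and
  two-sided p. Note that a reported 91/225 correct gives a one-sided
  p ≈ 0.015 — *above* chance at the 5% level — so the package reports the
  tests and does not assert any qualitative conclusion about chance-level
  performance.
* **Correct-identification count**: over the three *medioid* meows only
  (0–3); the 0–3 range forces this reading.
* **Mann–Whitney**: exact for both groups ≤ 20 without ties, otherwise
  normal approximation with tie correction; the switch is recorded in the
  output.
* **Spearman**: average ranks for ties, t-approximation p.
* **Cronbach's alpha**: `k/(k−1) (1 − Σ item variances / var(total))` on the
  reverse-scored item matrix.
* Missing or out-of-range answers exclude a record from the specific
  analysis only, with a warning.

## 4. Descriptor PCA and the valence reading

One observation = one participant × one meow response (11 descriptor
scores); this is the unit that makes "restrict to correctly assigned
responses" well defined. Default mode is correlation (descriptors
standardized) — the 11 scales share a 1–7 range but not necessarily a
variance; covariance mode is available and the mode is recorded in output.

Principal components are sign-ambiguous, so PC1 is oriented to put the
`calm_relaxed` loading ≤ 0: the negative PC1 side is then the
positive-valence side, and mirrored input data yield the identical descriptor
partition. Higher components orient their largest-magnitude loading positive
(pure determinism device). `valence_summary()` reports per-context PC1/PC2
means ± SD and the loading-sign partition.

## 5. What the synthetic generators emulate — and what they do not

**Audio.** `synth_meow()` renders additive harmonic tones with a linear F0
glide, per-octave harmonic rolloff, sinusoidal amplitude modulation
(envelope normalized by `1 + depth` so peak level stays comparable while
roughness varies) and Gaussian noise at a given SNR. The per-context
defaults follow the qualitative pattern that positive contexts show rising
F0 contours and negative contexts falling ones: waiting for food
480→640 Hz, brushing 400→520 Hz (mild modulation), isolation 640→440 Hz
(deeper modulation, longer calls). These ranges are plausibility choices of
this package — no per-context acoustic parameter ranges are published for
the breed in question — and are **not** calibrated to any recorded corpus.
Not emulated: vocal-tract filtering and formants (the original feature set
avoided formants as unreliable for band-limited signals), subharmonics,
chaotic phonation, multi-syllable meows, or recording-channel effects.
Passing tests therefore show parameter recovery and pipeline correctness,
not field validity on real recordings.

**Cohort.** `synth_cohort()` draws participant attributes by independent
Bernoulli (defaults: the observed sample composition, 146/225 female,
108/225 cat owners), context answers correct with ownership- and
context-dependent probability (defaults: the observed owner/nonowner medioid
accuracies), errors uniform over the two wrong contexts (no confusion
structure is published), and outlier-meow accuracy scaled by a single ratio
(default 0.55, approximating the observed medioid:outlier accuracy ratios).
Empathy items are drawn around group means on the item scale (defaults: the
published scale means divided by item counts) plus a shared per-participant
latent (SD 0.45) that induces realistic inter-item correlation — simulated
Cronbach's alpha lands near the 0.78–0.83 range reported for the
instrument — and unempathic items are generated on the reversed scale.
Descriptor scores are `round(4 + 3·valence·sign + noise)` clipped to 1–7,
a single-latent-valence model chosen because the analysis target is one
dominant valence axis on PC1. Not emulated: item-specific difficulty,
response styles, within-participant correlation of classification errors
across meows, or any arousal dimension.

## 6. Reproducibility machinery and problem sizes

All randomness funnels through one seeded generator per call; no function
mutates global RNG state. The pipeline fans a master seed out to per-stage
seeds by fixed offsets, stamps every CSV with a hash of the full
configuration, and is byte-identical across reruns of the same config.

Simulation sizes used by the test suite and acceptance script — 50 meows for
pitch recovery, 100 random datasets for the exemplar oracle, 500 null
replicates (six columns each) for screen calibration, 200 cohorts for the
chi-square power and size checks, one 225-listener cohort for PCA
recovery — were chosen as the smallest sizes at which the binomial
uncertainty of each estimated rate is comfortably below the margin being
asserted (e.g. 3 standard errors of a 5% rejection rate over 3000 null
tests is ±1.2 percentage points).

## 7. Known limitations

* The pitch tracker is a template-correlation design in the spirit of
  sawtooth-spectrum methods, not a reimplementation of any published
  codebase; confidence values are comparable across frames and clips but not
  numerically interchangeable with other trackers' scores.
* Roughness depends on peak picking; partials below the −28 dB contrast
  floor (deep in a dense spectrum) do not contribute.
* With three contexts the ANOVA screen has modest power at realistic
  per-class sample sizes; a feature family can be discarded by chance.
* The empathy and accuracy generative models are intentionally simple
  (single group factor, single valence factor); they support power and
  recovery analyses, not psychometric inference about real populations.
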