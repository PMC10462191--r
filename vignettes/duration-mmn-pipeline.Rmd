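---
title: "Simulating and analysing the duration-oddball mismatch negativity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing the duration-oddball mismatch negativity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

The mismatch negativity (MMN) is a negative deflection of the auditory
event-related potential (ERP), peaking roughly 150-250 ms after a rare
"deviant" sound embedded in a stream of frequent "standards". Because it is
generated pre-attentively, it is a practical probe of auditory sensory memory
in clinical populations who cannot perform behavioural tasks — here,
individuals with CLN3 (juvenile Batten) disease, compared with typically
developing (TD) controls. The paradigm is a duration oddball: 1000 Hz tones,
standards of 100 ms (85%) and deviants of 180 ms (15%), presented at three
stimulus onset asynchronies (SOAs: 450, 900, 1800 ms) that parametrically tax
the sensory memory trace. The scientific signature of interest is an
SOA-by-group interaction: TD listeners produce an MMN at every rate, while in
CLN3 the MMN survives at the medium rate (900 ms), is marginal at the fast
rate, and vanishes at the slowest rate.

Patient EEG of this kind is not publicly deposited, so the package is built
around a synthetic-cohort generator whose defaults encode exactly those study
conditions, and every downstream stage — preprocessing, MMN measurement,
statistics — is implemented as testable, reusable code whose behaviour can be
validated against the generator's ground truth.

## The generative model

**Paradigm.** A session is 14 blocks (2 x 450 ms SOA with 500 trials,
4 x 900 ms with 250, 8 x 1800 ms with 125; 1000 trials per condition). Block
order is randomized; within a block exactly `round(0.15 n)` deviant positions
are drawn uniformly under two conventions (the source description leaves them
open, so they are declared here): the first trial is a standard and no two
deviants are adjacent, preserving a local standard context before every
deviant.

**Single-source ERP kernel.** The response to a tone is a sum of Gaussian
deflections: obligatory components P1 (+2 uV, 60 ms, sigma 15 ms),
N1 (-3 uV, 110 ms, sigma 20 ms), P2 (+2 uV, 190 ms, sigma 25 ms), shared by
both tone types, plus — deviants only — an MMN Gaussian at 220 ms
(sigma 30 ms) whose peak equals the subject's injected amplitude for that
SOA. Gaussians are analytically integrable, so the injected window mean is
available in closed form for oracle tests. Two numerical conventions matter:
kernels are identically zero over the -100..0 ms baseline (baseline
correction is then exact on clean data), and each Gaussian is truncated at
+-4 sigma (a 3e-4 relative edge step) so that at the fastest rate a tone's
kernel cannot leak into the next trial's baseline.

**Scalp projection.** The MMN topography template has a frontal negative
lobe centred on Fz, equal positive weights at the two mastoids (the
polarity inversion that motivates the temporal reference), and is normalized
so the F3/Fz/F4 composite mean is -1. Two deliberate choices: (1) the
template is pinned to exactly zero at T7 and T8 so measured frontal
amplitudes are invariant to the T7/T8 re-reference, and (2) the composite —
not the Fz peak — is normalized to unit magnitude, so a subject's injected
amplitude is recovered as-is by the standard measurement (window mean of the
F3/Fz/F4 composite). Signals are generated by projecting the source kernel
through the template divided by its frontal-composite mean: obligatory
components then appear frontal-positive in their canonical polarity, and a
negative injected MMN amplitude yields frontal negativity with mastoid
positivity in the difference wave.

**Noise and artifacts.** Background activity is 1/f ("pink") noise, default
SD 5 uV per channel, spatially mixed through a Gaussian kernel over the
montage (rows L2-normalized) so neighbouring channels correlate as they do
under volume conduction — without this, correlation-based bad-channel
screening would flag everything. Blinks are 400 ms raised-cosine positive
transients with a fronto-polar topography, Poisson-timed at the subject's
blink rate. Declared bad channels are replaced by high-variance white noise.
All randomness is seeded; one top-level seed derives per-subject and
per-stage sub-streams.

**Cohort effect map.** Group-mean injected amplitudes are
TD: -1.05 / -1.11 / -1.12 uV and CLN3: -0.45 / -1.00 / 0 uV at
450 / 900 / 1800 ms, with between-subject SD 1.0 uV. These reproduce the
reported pattern at the reported group sizes (41 TD, 21 CLN3): the TD
contrasts sit near t = -6, the CLN3 900 ms contrast is clearly significant,
the 450 ms one lands near the conventional boundary, and 1800 ms is null by
construction. Ages are uniform on 6-26 (TD) and 6-28 (CLN3) years; age
slopes of -0.033 (TD) and +0.047 (CLN3) uV/yr, centred at the group mean
age, give the weak opposite-signed age correlations (about -0.17 and +0.25
when pooled over SOAs) without materially shifting group means. CLN3 stage
(1-3, sampled 9:10:6) adds +0.45 uV per stage unit centred at stage 2 —
amplitudes weaken with disease stage.

## The preprocessing chain

Order: decimate, band-pass, bad-channel handling, epoch, reject, baseline,
re-reference, ocular removal.

* **Decimation** 512 to 128 Hz with the classic 8th-order Chebyshev Type I
  anti-alias low-pass (0.05 dB ripple, cutoff 0.8 x new Nyquist), applied
  forward-backward. Even-order Chebyshev I designs sit at the ripple trough
  at DC, so the prototype is renormalized to unity DC gain; constants then
  pass bit-faithfully, which the tests rely on. All zero-phase filtering
  uses odd-reflection end padding (10 s) so start-up transients never reach
  the data.
* **Band-pass** 1-40 Hz, Chebyshev Type II of order 4 with 40 dB stopband
  attenuation, zero-phase. Type II designs are specified by their stopband
  corners; these are placed at `low/2` and `1.3 x high` so the nominal band
  itself lies in the flat passband (measured: 20 Hz within 0.01%, 0.1 Hz
  attenuated > 80 dB after two passes).
* **Bad channels** are flagged by robust (MAD-based) SD against the median
  channel SD (ratio threshold 5) or by mean absolute correlation with their
  5 nearest montage neighbours falling below 0.4 — declared quantifications
  of a qualitative published recipe ("standard deviation and covariance with
  3-7 neighbouring channels"); all three numbers are arguments. Flagged
  channels are rebuilt by Perrin spherical splines (order m = 4, 7 Legendre
  terms, ridge 1e-5); splines reproduce constants exactly and smooth fields
  to a few percent in leave-one-out, and the call refuses when >= 25% of the
  montage is bad.
* **Epochs** span the half-open window [-100, 800) ms on the post-decimation
  grid — 115 samples at 128 Hz — with onsets snapped to the nearest sample;
  edge events are dropped and counted.
* **Rejection** is two-stage: any sample beyond +-150 uV (stage 1), then,
  per condition among survivors, epochs whose peak absolute value in the
  first 500 ms post-onset exceeds the condition mean by more than 2 SD
  (strict inequality, so identical epochs survive; decisions are invariant
  to rescaling). "Condition" is resolved as SOA x tone kind: resolving it as
  SOA alone would systematically reject all deviants of a clean recording,
  because their maxima form a separated second point mass — the two-point
  85/15 mixture puts the deviant value beyond mean + 2 SD by arithmetic
  alone. The amplitude threshold is applied before re-referencing, matching
  the narrative order of the source procedure.
* **Baseline** correction subtracts the [-100, 0) ms mean per trial and
  channel. **Re-referencing** subtracts the T7 trace (T8 when T7 was flagged
  bad; an error when both are), after which the difference wave is invariant
  to any common additive offset. The published order epochs, averages, then
  re-references; re-referencing is linear, so applying it to epochs before
  averaging (as done here) yields identical condition means — the ambiguity
  is immaterial for every quantity computed.
* **Ocular artifacts** are removed by deterministic template regression
  rather than ICA: a virtual EOG (mean of fronto-polar channels) is
  thresholded at max(median + 4 MAD, 40 uV), the detected intervals dilated
  by 150 ms, and the resulting blink time course regressed out of every
  channel — a single spatial template, mirroring the usual practice of
  deleting one or two ocular components, but reproducible without
  stochastic unmixing. The 40 uV absolute floor keeps ERP peaks (a few uV)
  from ever entering the template, so blink-free data pass through
  unchanged.

## Measurement

Accepted epochs are averaged per condition; the difference wave is
deviant minus standard (the source text once writes "STD-DEV" but reports
negative-going deviant-minus-standard waves; DEV - STD is used throughout);
the MMN amplitude is the mean over channels F3/Fz/F4 and samples with
200 <= t <= 240 ms, endpoints inclusive on the grid. Grand averages weight
subjects equally. Subjects are retained when every condition keeps >= 50
accepted trials, or — the retention exception — when their composite
waveform stays within 3 between-subject SDs of the group mean at every time
point (the published exception is not operationalized; the pointwise band is
this package's declared convention).

## Statistics

* **LME harness.** `amplitude ~ soa * condition * group + (1 + age | subject)`
  fitted by REML (lme4/lmerTest backend), treatment coding with TD / STD /
  450 ms as references; a second shape replaces group by the CLN3 stage
  score. Age is constant within a subject, so the random age slope makes the
  fit near-singular by construction; it is retained for fidelity to the
  published model and singular fits are tolerated. The with-/without-age
  comparison refits both models by ML for the likelihood ratio.
  Satterthwaite degrees of freedom are backend-native and reported as such.
* **Planned contrasts** are paired t-tests of DEV vs STD window amplitudes,
  one-tailed toward negativity when testing for MMN presence (the reported
  one-sided intervals imply that choice), two-tailed otherwise.
* **Cluster permutation.** Paired t maps over all channel-time pairs;
  cluster-forming threshold is the two-tailed critical t at alpha = .05 with
  n-1 df (the published account states only "p < .05"); clusters connect
  suprathreshold points sharing a sign through montage adjacency
  (great-circle distance < 0.7 rad, which makes Fz adjacent to F3/F4 and
  keeps the 34-channel graph connected) and temporal contiguity; each
  cluster is scored by its summed t (maxsum). The null distribution of the
  single most extreme cluster maxsum is built from within-subject
  condition-label flips — equivalent to sign flips of the paired differences
  — and an observed cluster is significant outside the 2.5th/97.5th
  percentiles. Monte-Carlo p-values use (b+1)/(n_perm+1), with a relative
  tie tolerance of 1e-9 so permutations that reproduce the observed
  labelling count as extreme regardless of floating-point path.
* **JZS Bayes factor.** The paired-t Bayes factor under a Cauchy (scale
  0.707) prior on the standardized effect, computed by writing the Cauchy as
  a normal mixed over an inverse-gamma(1/2, 1/2) variance and either
  integrating adaptively over the mixing variable (default) or averaging the
  same integrand over 1e6 inverse-chi-square draws; the backends agree to
  well under 1%, and both agree with the independent noncentral-t
  formulation of the same marginal likelihood.
* **Bootstrap Spearman.** Rank correlation with a seeded percentile
  bootstrap CI over 1000 paired resamples (the resample count is not stated
  in the source; 1000 is the package default), significance declared only
  when the interval excludes zero; a 3-MAD outlier count is reported, though
  ranks make the estimate itself insensitive to outlier magnitude.

## Problem sizes and what the tests do (and do not) show

Simulating every full-length session (3150 s x 512 Hz x 34 channels x 62
subjects) would manipulate tens of gigabytes of samples for no extra
inferential content, so the package validates at deliberately chosen scales:

* exact checks (schedule geometry, rejection rules, baseline/reference
  algebra, spline constants) run at full fidelity;
* noiseless single-subject ground-truth recovery runs the
  amplitude-preserving chain (epoch, reject, baseline, re-reference, ocular,
  measure) and matches the closed-form injected window mean to 1e-6 uV.
  The two filters are linear but not amplitude-neutral at the percent level
  (any finite-order design changes a bump's window mean slightly), so exact
  recovery is defined on the unfiltered path, and the filters are validated
  separately by their measured frequency responses;
* cohort-scale recovery runs the full continuous chain, filters included,
  for all 62 subjects with one block per SOA (80/50/30 trials), acquired at
  256 Hz and decimated by 2 to the same 128 Hz analysis rate; recovered
  group means land within 2 empirical SEs of the injected ones, confirming
  that filter bias (measured at about +0.07 uV on the window mean, from the
  band-pass acting on the MMN bump) is small against between-subject spread;
* calibration and pattern-recovery studies (cluster-test false-positive
  rate; the TD-all-SOAs / CLN3-900-only headline pattern over 25 replicate
  cohorts) draw subject-level ERPs directly from the generative model —
  kernel plus between-subject amplitude variability plus residual ERP noise
  of trial noise / sqrt(n_trials) — because those statistics operate on
  subject ERPs regardless of how they were obtained.

The generator emulates the statistical structure the analysis assumes:
stationary 1/f noise, a fixed single-source topography, Gaussian component
shapes, linear age trends. It does not emulate non-stationary artifacts,
latency jitter between subjects, electrode drift, or genuine multi-source
physiology. Passing tests therefore demonstrate that the pipeline measures
what it claims under its own assumptions — parameter recovery, calibration,
and qualitative pattern reproduction — not that those assumptions hold for
any particular real recording.

## Known limitations

Ocular correction is a single-template regression, not full ICA; recordings
with mixed artifact species (muscle, channel pops) will pass residue through.
The spherical spline uses a 7-term Legendre truncation — adequate for 34
channels, low-pass in space by design. The LME reproduces the published
model shapes only; it is not a general formula interface. EDF export is out
of scope in this environment; recordings live as in-memory objects, with
events, tables and ground truth serialized as TSV/CSV/JSON.
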