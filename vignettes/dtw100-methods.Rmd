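---
title: "Scoring cortico-muscular coupling with DTW-100"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cortico-muscular coupling with DTW-100}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtw100)
```

## The problem and the model

Functional cortico-muscular coupling (FCMC) — the coordination between motor
cortex and effector muscle — degrades after global cerebral ischemia and can
recover under neuromodulation such as low-intensity pulsed ultrasound
stimulation. `dtw100` quantifies that recovery from paired recordings of a
local field potential (LFP, motor cortex) and an electromyogram (EMG, tail
muscle), both sampled at 2 kHz, by asking a single question: *how closely
does a subject's trial-averaged LFP/EMG pair resemble the same pair averaged
over a healthy cohort?*

Resemblance is measured with classic dynamic time warping. For two
sequences $X = (x_1,\dots,x_n)$ and $Y = (y_1,\dots,y_m)$:

1. local cost $D(i,j) = (x_i - y_j)^2$;
2. cumulative cost
   $C(i,j) = D(i,j) + \min\{C(i-1,j),\, C(i,j-1),\, C(i-1,j-1)\}$ with
   $C(1,1) = D(1,1)$;
3. distance $\mathrm{DTW}(X,Y) = C(n,m)$, the cost of the optimal monotone
   alignment path from $(1,1)$ to $(n,m)$;
4. length normalization $d = \mathrm{DTW}(X,Y) / (n + m)$, which is
   $\mathrm{DTW}/2n$ in the usual equal-length case;
5. percentage score $\mathrm{DTW\text{-}100} = 100\,(1 - A\,d)$, clamped to
   $[0, 100]$, computed per modality;
6. composite $= w \cdot \mathrm{LFP\ score} + (1-w) \cdot
   \mathrm{EMG\ score}$ with $w = 0.5$ by default.

The same chain runs in two domains: on the preprocessed trial-averaged time
series (*time-domain* score) and on their one-sided magnitude spectra
(*frequency-domain*, or FRE, score). No warping window or step weights are
applied — the recursion is the unconstrained classic one — and a 4 s epoch
at 2 kHz ($8000 \times 8000$ cells) is well within reach of the compiled
kernel, so no approximate DTW variant is used.

Two conventions deserve emphasis. The local cost is the *squared*
difference, so distances scale with the square of amplitude (doubling both
signals quadruples the distance). And the score is clamped: a percentage
scoring function must stay in $[0,100]$, while the raw affine formula goes
negative once $d > 1/A$.

## Preprocessing

Each stage is zero-phase and length-preserving, so epochs stay aligned to
stimulation onset:

* **Notch**, default 50 Hz, Q = 30 (−3 dB width 1.7 Hz): a standard
  constrained second-order IIR notch removing mains interference.
* **Baseline removal**: subtraction of a centred moving average (default
  window 1 s). This is the simplest drift remover that adapts to the local
  baseline, and its transfer function (one minus a Dirichlet kernel) is
  analytically checkable: a 0.1 Hz drift is suppressed by more than 90 %
  while a 40 Hz oscillation passes essentially unchanged.
* **Bandpass**: Butterworth, 0.5–200 Hz for LFP and 10–200 Hz for EMG,
  realized as cascaded fourth-order high-pass and low-pass sections.

### Numerical realization of "zero-phase"

The designed IIR responses are applied as their squared-magnitude (i.e.
forward–backward) response in the frequency domain over the whole epoch,
rather than by a time-domain forward–backward recursion. The reason is the
0.5 Hz corner: its impulse response spans seconds, so on a 4 s epoch any
recursive implementation leaves edge transients on the order of $10^{-2}$
of the signal RMS regardless of padding or initial-condition strategy, and
those transients break exact linearity. The frequency-domain application is
exactly linear, exactly zero-phase, matches the analytic filter response to
machine precision, and makes notch and bandpass commute exactly — all of
which the test suite asserts. The trade-off is the implicit circular
boundary of the epoch spectrum, shared with every FFT-based filter; for
baseline-removed, band-limited epochs the wrap-around discontinuity is
negligible.

Filtering commutes with averaging (both are linear), so the pipeline
averages a subject's 30 trials first and preprocesses the average — an
exact, not approximate, reordering that cuts the filtering cost by the
trial count. The per-trial primitives remain exported for workflows that
need trial-level preprocessing.

Epochs are half-open sample windows: a post-stimulus epoch is
$[\text{onset}, \text{onset}+N)$ and *includes* the 300 ms stimulation
burst, which makes 4 s epochs tile a recording with a 4 s inter-trial
interval exactly. A pre-stimulus epoch ends at the onset (exclusive); the
placement of the pre window immediately before onset is a package
convention — nothing in the underlying experimental description fixes it —
and is flagged as such here.

## The coefficient A and its calibration

$A$ rescales normalized distances into the percentage range. It is
adjustable by design and no canonical value exists; published per-sample
scores are therefore not recoverable without the original recordings. The
package's default policy makes every run self-contained: within each
domain, $A$ is calibrated on the pre-stimulation cohort so that the worst
(largest) observed normalized distance maps exactly to a floor score of 0:

$$A = \frac{1 - \text{floor}/100}{\max_i d_i}.$$

Calibration is per domain — time- and frequency-domain distances live on
different scales (raw microvolt waveforms versus amplitude spectra), and
one shared $A$ would squash one domain's dynamic range. Within a domain a
single $A$ is shared by LFP and EMG, preserving their comparability. A
fixed `coefficient_A` in the configuration overrides calibration, e.g. for
scoring new subjects on a frozen scale.

## The frequency-domain pathway

Spectra are single full-epoch DFT magnitudes — no segment averaging and no
taper — so bin frequencies are exact multiples of $1/4\,\mathrm{s} =
0.25$ Hz and a 40 Hz oscillation lands on a bin. Magnitudes are
amplitude-scaled (a unit sinusoid gives magnitude 1 at its bin; DC and
Nyquist carry weight 1, interior bins 2), and the spectrum is restricted to
the modality's bandpass range before warping, unless `spectral_band`
overrides both. DTW then runs on magnitudes; power and dB representations
are available as options but magnitude is the default because the spectra
being compared are amplitude spectra. Adjacent-bin decimation
(`bin_decimate`) is available to bound the spectral DTW cost and is off by
default.

## The synthetic cohort generator

No public recordings of this experiment exist, so the package ships a
generator whose defaults encode the study conditions: a normal cohort of 30
subjects, nine ischemic (BCAO) subjects before stimulation, and the same
nine after stimulation, each with 30 stimulus-locked 4 s epochs at 2 kHz.

Per subject, each modality is a fixed waveform replicated across trials
with mild amplitude jitter plus independent white measurement noise. The
LFP waveform mixes a stimulus-locked 40 Hz oscillation with band-limited
noise in proportions set by the regime's spectral concentration; the EMG
mixes a stimulus-locked 40 Hz-coupled component with 10–200 Hz noise
amplitude-modulated by the rectified LFP oscillation. The regimes differ
as the study system does:

| regime | LFP:EMG peak ratio | 35–45 Hz LFP power fraction | extras |
|---|---|---|---|
| `normal` | 1.2 | ≈ 0.7 | — |
| `bcao_pre` | 3 | ≈ 0.2 (broadband) | widened trial jitter and noise |
| `bcao_post` | 100 | ≈ 0.7 | bimodal LFP envelope, suppressed EMG |

Only ratios are constrained by the study's description; absolute scales are
package choices made once: normal LFP peak 1.2 against EMG 1.0, ischemic
LFP 3.0, post-stimulation LFP 1.5 (mild elevation over normal, carrying a
two-hump envelope) against EMG 0.015. The 100-fold post-stimulation ratio
thus arises from EMG suppression, consistent with a post-stimulation state
that resembles the healthy reference cortically while muscle output stays
inhibited. One descriptive figure is *not* reproduced: a linear additive
model cannot simultaneously exhibit a 100-fold time-domain peak ratio and a
10-fold spectral-maximum ratio for the same pair; the generator targets the
time-domain ratio.

Cohorts are bit-reproducible: subject streams derive from
`(cohort seed × 1009 + subject index × 9973) mod 2147483629`, so a
subject's data do not depend on cohort size, and generation restores the
caller's RNG state.

What passing tests on these cohorts do **not** show: the generator has no
biophysics (no neural-mass or motor-unit model), no artifacts, no
non-stationarity across trials beyond amplitude jitter, and its noise is
Gaussian. Recovery of the stimulation effect on synthetic cohorts
demonstrates that the pipeline measures what the generator encodes — not
that real recordings would yield the published group means.

## Group statistics

The nine subjects are the same animals before and after stimulation, so the
pre/post comparison is a paired two-tailed t-test on composite scores,
$t = \bar d / (s_d/\sqrt n)$ with $n-1$ degrees of freedom. An unpaired
variant is deliberately not the default. No multiple-testing correction is
applied across the two domains; both raw p-values are reported. If the
paired differences have zero variance the statistic is undefined and the
p-value is pinned to 0 or 1 by the sign of the mean difference, with a
warning.

## Numerical choices and degenerate inputs

* Backtrace ties prefer the diagonal step, then up, then left; the distance
  is unaffected, only the reported path.
* For unequal lengths the normalization divisor $n+m$ extends the
  equal-length $2n$ convention.
* The optimal path matrix is only materialized when $n \times m$ is below a
  cell budget (default $4 \times 10^6$); above it the distance is computed
  in $O(m)$ memory and the path is omitted.
* `dtw100_score` rejects $A \le 0$; calibration rejects all-zero distance
  sets (the scale would be undefined).
* Empty trial sets, ragged trial files and non-numeric cells are rejected
  with located errors; epochs that would run past a recording edge are
  skipped with a warning, and an all-skipped extraction is an error.
* Time-domain DTW may be decimated (`decimate` in the configuration,
  default off) by plain subsampling of both sample and reference; the
  score scale adapts because $A$ is recalibrated on the decimated
  distances.

## Problem sizes in the shipped tests

The unit suite exercises full 4 s, 2 kHz epochs wherever a property depends
on them (filter responses, spectra, Parseval). The repeated-study
experiment — 100 independently seeded full study designs checking that the
post-stimulation composite exceeds the pre-stimulation composite with
paired $p < 0.001$ in both domains — runs with 10-fold time-domain
decimation and 2-fold spectral binning, sizes chosen so the whole
experiment stays comfortably inside a routine test run while each study
still contains all 48 subjects at acquisition rate. The acceptance script
(`scripts/acceptance.R`) runs one study at full resolution.

## Known limitations

* Scores depend on the calibration cohort through $A$; scores from runs
  with different calibration sets are not directly comparable.
* DTW on raw amplitudes conflates amplitude and shape mismatch; that is
  faithful to the scoring model, but it means a uniformly rescaled but
  otherwise perfect signal does not score 100.
* The spectral pathway compares full-resolution magnitude spectra by
  default; whether binning before warping is preferable is an open
  modelling question, exposed as an option rather than decided.
* The equal 0.5/0.5 composite weighting is the conventional choice; the
  configuration exposes it but no evidence within the package favours
  another value.
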