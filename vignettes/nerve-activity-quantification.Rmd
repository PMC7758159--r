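---
title: "Quantifying peripheral nerve activity with nervequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying peripheral nerve activity with nervequant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nervequant)
```

## The measurement problem

Multi-unit recordings from small autonomic nerves (splenic sympathetic
nerve, celiac vagus branch) are a few microvolts of spiking activity buried
in broadband electrode noise and 50 Hz mains pickup, digitized at 4 kHz
after a high-gain amplifier. Two summary statistics are standard:

* **Firing frequency** — the number of detected spikes in a 10-minute
  analysis bin, with an **amplitude gain** (mean spike peak divided by the
  baseline noise floor) as a companion measure of unit recruitment.
* **Burst count** — for nerves whose activity arrives as multi-spike
  "activation ensembles", the number of ensembles per 10-minute bin,
  counted on a rectified and leaky-integrated version of the signal so
  that one ensemble produces one envelope peak however many spikes it
  contains.

`nervequant` implements both chains, the stimulation-protocol bookkeeping
used in stimulate-then-record experiments, the group statistics used to
compare treatment arms, and an intermodes-threshold area quantification for
stained tissue sections. A synthetic-recording generator with exact ground
truth makes every stage testable without animal data.

## Signal model and processing chains

The recorded nerve signal is modelled as

$$x(t) = \sum_i s(t - t_i) + n(t) + m \sin(2\pi \cdot 50\,\mathrm{Hz}\, t),$$

where $s$ is a biphasic extracellular spike waveform, $t_i$ are spike times
organized in burst ensembles, $n$ is broadband noise and the last term is
mains interference.

**Spike chain** (sympathetic recordings): a 50 Hz notch (biquad, $Q = 30$)
followed by a 300–1000 Hz Butterworth band-pass. Spikes are local maxima of
$|x_f|$ above $k \cdot \hat\sigma$, where $\hat\sigma$ is the noise floor,
separated by at least a refractory period.

**Burst chain** (vagal recordings): a stricter 300–550 Hz band-pass (no
notch: 50 Hz is far below the band), then full-wave rectification and a
leaky integrator

$$y_n = y_{n-1} e^{-1/(f_s \tau)} + |x_n| \left(1 - e^{-1/(f_s \tau)}\right),
\qquad \tau = 0.1\ \mathrm{s},$$

normalized to unit DC gain so the envelope stays in microvolts. A unit
impulse decays by $e^{-1}$ over exactly $\tau$. Envelope peaks above
$k_{env}$ times the envelope noise reference are merged into bursts when
their gaps do not exceed `merge_gap_s`, and bursts are counted per bin by
their onset time.

**Noise floor**: estimated from a post-mortem (activity-free) segment put
through the *same* filter chain, summarized by the scaled median absolute
deviation (consistent with the SD under Gaussian noise but insensitive to
residual artifacts). The envelope chain uses the median of the integrated
post-mortem segment, keeping both thresholds referenced to the same data.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| band-pass (spikes) | 300–1000 | Hz | in-band spike energy, rejects movement and EMG below 300 Hz |
| band-pass (bursts) | 300–550 | Hz | stricter band avoids high-frequency noise before integration |
| notch | 50, Q = 30 | Hz | mains; bandwidth 1.7 Hz leaves neighbours within 1 dB |
| filter order | 4 (prototype) | — | 8-pole band-pass, flat passband |
| `zero_phase` | TRUE | — | forward–backward filtering; event times not delayed |
| `tau` | 0.1 | s | integrator memory; sets envelope smoothness |
| `spike_k` | 3 | × floor | see the false-positive analysis below |
| `refractory_s` | 0.001 | s | one deflection, one event; set it to the expected spike *width* (2 ms for the synthetic templates) or both lobes of a biphasic wave are counted |
| `burst_k` | 2 | × envelope ref | envelope fluctuations are far tighter than raw noise, so a low multiplier suffices |
| `min_separation_s` | 0.1 | s | one envelope peak per integrator memory |
| `merge_gap_s` | 0.3 | s | $3\tau$: peaks within the integrator's memory are one ensemble |
| `bin_s` | 600 | s | the conventional 10-minute analysis bin |

The filter family, order, phase behaviour and both threshold multipliers
are not dictated by the measurement itself; they are declared defaults,
exposed in `pipeline_config()`, and recorded in every output file via the
configuration hash.

## The stimulation timeline

`stim_protocol()` encodes the alternating stimulation design: a 10-minute
window in which the nerve is stimulated every other minute (first minute
ON by convention; the phase is configurable) with 5 Hz trains of
monophasic 0.3 mA pulses, followed by the analysis bin. Pulse width is not
part of the published protocol and defaults to 1 ms; it does not affect
the analysis windows. Both stimulated and sham timelines are analyzed over
the same window, minutes 10–20 (`analysis_window()` returns
`c(600, 1200)`), so stimulation artifacts never overlap the quantified
segment; `blank_artifacts()` is provided for within-window analyses.

## Group statistics

Two-group comparisons use the pooled-variance Student t
($\mathrm{df} = n_1 + n_2 - 2$). Multi-group designs use a two-way
cell-means ANOVA: the error mean square is pooled within the $k$ cells of
the factor crossing ($\mathrm{df} = N - k$) and every cell pair is
compared with the Tukey–Kramer studentized-range statistic

$$q_{ij} = \frac{|\bar y_i - \bar y_j|}
{\sqrt{\frac{\mathrm{MSE}}{2}\left(\frac1{n_i}+\frac1{n_j}\right)}},$$

referred to the studentized-range distribution with $k$ means and $N - k$
df. This cell-means construction is what reproduces published error
degrees of freedom for unbalanced designs (e.g. groups of 10/11/6/6 give
$\mathrm{df} = 29$; 4/4/4/4/3/4 give $\mathrm{df} = 17$). Which
sums-of-squares decomposition a published main-effect F used cannot be
recovered from pairwise q values, so main-effect tables are deliberately
not produced. Normality/variance pre-screening (Shapiro–Wilk, Levene) is
out of scope; the synthetic generator draws Gaussian group values, so
calibration checks test the t machinery, not the pre-tests.

## Stained-area quantification

Images are quantized to 8 bits by linear min–max scaling. The intermodes
threshold repeatedly smooths the 256-bin histogram with a 3-bin running
mean (zeros outside the support) until exactly two local maxima remain,
then splits at `floor((j + k) / 2)`; histograms that never become bimodal
raise an error rather than returning an arbitrary level. The stained-area
fraction is the proportion of pixels strictly above the threshold,
averaged over fields of view per animal.

## What the generators emulate — and what they do not

`simulate_recording()` draws bursts as a homogeneous Poisson process
(`burst_rate` per 600 s), spike counts per burst as Poisson
(`spikes_per_burst`, mean 15), intra-burst intervals as exponential
(150 Hz), and adds one-cycle biphasic spike templates (20 µV peak, 2 ms
wide — fundamental 500 Hz, inside both analysis bands) to white Gaussian
noise (2 µV SD) plus a 5 µV, 50 Hz mains sine. These defaults are the
package's declared stated world: SNR 10 spikes on a realistic noise floor,
and an envelope SNR (median burst envelope peak over the envelope noise
reference) of about 4.4 under the burst chain.

Real recordings differ in ways the generator does not model: noise is not
white (electrode drift, EMG), firing is not Poisson (refractoriness,
rhythmic modulation), spike shapes vary across units and electrodes, and
mains interference wanders in frequency and harmonics. A green end-to-end
test therefore establishes that the chain recovers the truth of *this*
world, not that any specific animal recording is quantified correctly.

`simulate_if_image()` thresholds a smoothed Gaussian random field, giving
blob-shaped foreground at an exact coverage fraction with a bimodal
intensity histogram — adequate for validating thresholding, not a model of
real staining.

## The threshold multiplier and false positives

The spike threshold default $k = 3$ follows the package's stated design,
but a Rice-formula argument (confirmed by simulation in the test suite)
shows it cannot give high precision against Gaussian backgrounds: local
maxima of $|x_f|$ for band-limited Gaussian noise cross $3\hat\sigma$ at
roughly $2 f_{rms} e^{-9/2} \approx 10$ events/s at these bandwidths —
thousands of false events per 10-minute bin. With 100 true spikes per bin,
precision is about 0.02 regardless of spike amplitude; the corresponding
acceptance check is intentionally left failing rather than silently
retuned. Recall at $k = 3$ is essentially 1. For Gaussian backgrounds,
$k \approx 5$ brings the false-positive rate below one per minute;
comparative designs (treatment vs control on the same electrode) are
insensitive to this choice because the false-positive floor is common to
both arms.

## Numerical notes

* Butterworth band-pass design is done in pole–zero form (analog
  prototype, band transform, bilinear transform with prewarping) and
  expanded to coefficients only at the end; designs were cross-checked to
  machine precision against an independent reference implementation.
* Zero-phase filtering extends the trace by odd reflection, with the pad
  length taken from the slowest filter pole so start-up transients decay
  below $10^{-6}$ before reaching data — this matters for the high-Q
  notch, whose impulse response rings for ~0.2 s.
* Peak pickers report plateau maxima at their earliest sample and enforce
  minimum separation greedily in order of decreasing amplitude.
* Spikes exactly on a bin boundary belong to the later bin (all intervals
  are half-open); bursts are binned by onset, so a straddling burst counts
  once.
* Degenerate inputs: an all-zero noise segment yields floor 0 with a
  warning, and spike detection refuses a zero floor rather than returning
  every sample.
* The intermodes iteration cap (10,000) exists to terminate on
  pathological histograms; in practice bimodality is reached in tens of
  iterations.

## Known limitations

* No spike sorting: counts are multi-unit, and overlapping deflections
  within a refractory period count once.
* Burst counting undercounts slightly at high rates (about 3–5% at 60
  bursts per 10 min) because ensembles closer than `merge_gap_s` merge —
  in both truth and detection this is the intended semantics of an
  "ensemble", but it makes counts mildly sublinear in rate.
* The EDF interchange format is not read; recordings enter as delimited
  text with a sidecar annotation file.
* Imaging operates on single grayscale planes; no background subtraction,
  stack handling or colocalization.
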