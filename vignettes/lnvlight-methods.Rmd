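---
title: "Models and methods behind lnvlight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lnvlight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnvlight)
```

# The scientific problem

Large ventral lateral neurons (l-LNvs) of the *Drosophila* circadian
circuit integrate light input from three photoreceptor systems —
cell-autonomous cryptochrome (CRY), internal rhodopsin 7 (Rh7) and the
external eye structures — and drive acute light-evoked arousal.  Two
standard assays quantify this integration:

* **Light-evoked firing.**  Whole-cell current-clamp sweeps of 50 s
  darkness, 5 s of monochromatic light (365, 405, 450 or 635 nm,
  200 uW/cm^2^) and 95 s of recovery darkness, five sweeps per cell.
  The readout is the firing-frequency (FF) ratio — the firing rate
  during the 5-s light window divided by the baseline rate in the 50-s
  dark window — plus a post-stimulus profile of 10-s-bin rate ratios
  that captures how long the excitation persists after light-off.
* **Light-pulse arousal.**  Flies in activity monitors (one infrared
  beam-crossing count per minute per fly) receive three 5-min light
  pulses per night at ZT18, ZT19 and ZT20 for three nights.  The
  readout is the fraction of flies asleep at pulse onset that awaken
  during the pulse.

No raw recordings are deposited for these assays; what is published are
group-level values (FF ratios, arousal fractions and baseline rates per
genotype and wavelength).  `lnvlight` therefore pairs every analysis
stage with a *synthetic generator* whose generative parameters are
exactly those published values, so the whole pipeline can be validated
by parameter recovery: simulate with a known value, push the synthetic
raw data through the full analysis, and require the estimate to come
back.

# The ephys generative model

Firing is modelled as an inhomogeneous Poisson process with an absolute
refractory period, not as a conductance-based membrane model.  The
published recordings show predominantly tonic (non-bursting) firing at
2–5 Hz, and every analysis stage consumes only spike counts, so a rate
model with dead time is the simplest process with the right first- and
second-order statistics at these rates.

The instantaneous rate for a sweep with baseline $r$, fold change $k$
and decay constant $\tau$ is

$$
r(t) = \begin{cases}
r & t < t_{on} \\
r\,k & t_{on} \le t < t_{off} \\
r\left(1 + (k-1)\,e^{-(t-t_{off})/\tau}\right) & t \ge t_{off}
\end{cases}
$$

with $\tau = 0$ meaning an immediate return to baseline.  Spike trains
are drawn by thinning a homogeneous process at the profile maximum and
pruning inter-spike intervals below the refractory period
(non-paralyzable dead time, default 2 ms).  For a constant rate the
realized rate is $r/(1 + r\,\tau_d)$; at 4.2 Hz and 2 ms this is a
0.8 % deflation, well inside the acceptance tolerances, and the unit
tests check the dead-time-corrected expectation explicitly.

Traces are rendered at 10 kHz as resting potential (−50 mV) plus
Gaussian membrane noise (SD 1.5 mV), a +5 mV DC step during the light
window (light-evoked depolarization), and a stereotyped 2-ms biphasic
spike waveform of 40 mV amplitude at each spike time.

**Parameter provenance.**  Baseline rates (4.2, 3.6, 3.9, 5.2, 2.4 Hz
for control, *gl60j*, *cry-null*, *gl60j-cry-null*, *rh7-null*) and the
per-genotype x wavelength fold changes in
`defaultEphysParamTable()` are the published group values.  The decay
constants $\tau$ are *not* published anywhere as numbers; the defaults
(control: 25 s blue, 12 s violet, 6 s UV, 0 s red; mutants: 5 s for
short wavelengths, 0 for red) are qualitative reconstructions of the
reported persistence ordering (blue longest, red none, mutants
curtailed).  They shape only the post-stimulus profile — the FF ratio
itself is computed from the light window and is independent of $\tau$.
The refractory period, spike amplitude, noise SD and DC step are
generator plumbing with no published counterpart; they were chosen once
at physiologically conventional values and the spike-detection
validation (below) shows the analysis is insensitive to them at these
settings.

# Spike detection and the FF statistics

Detection (a) high-passes the trace by subtracting a 5-ms running mean
(computed via cumulative sums, O(n)); this removes the resting
potential, slow drift and the DC light step while leaving the 2-ms
spike transient essentially intact; (b) thresholds at 5x the median
absolute deviation of the filtered signal (the MAD is estimated on a
subsampled stride on long traces, which is statistically equivalent and
much cheaper than a full median); (c) takes each suprathreshold
excursion as one event at its peak sample, discarding excursions
narrower than 0.3 ms (single-sample noise exceedances); (d) splits an
excursion into two events only when two prominent maxima are separated
by a valley below half their height (two overlapping waveforms fused
into one run), and then enforces a 2-ms refractory floor, merging
closer events to the taller peak with a collision warning.  On
generator output at default noise the detector achieves >= 99 %
sensitivity and precision with sub-millisecond timing error; this is a
tested invariant, which is what licenses the pipeline's fast path
(`render = FALSE`) for large replicate studies.

Counting uses half-open bins $[a, b)$ on the protocol grid: five 10-s
baseline bins, the 5-s light window (a spike at exactly light onset
belongs to the light window), and five 10-s post-stimulus bins from
light-off.  The FF ratio converts both windows to rates before
dividing:

$$\mathrm{FF} = \frac{n_{light}/5\,\mathrm{s}}{n_{pre}/50\,\mathrm{s}}$$

This rate normalization is a deliberate design choice: dividing the
raw 5-s count by the mean 10-s bin count would halve every ratio and is
inconsistent with published ratios near 1 for non-responding genotypes
with ~4 Hz baselines.  The analyzed window is the 105 s covering
baseline, light and 50 s of post-stimulus decay, inside the 150-s
sweep.  A sweep with zero baseline spikes has an undefined ratio and is
excluded from aggregation (never assigned an infinite ratio), with the
exclusion counted and reported.  Aggregation averages sweeps within
cell, then cells within group; SEM is sample SD over cells divided by
$\sqrt{n}$ and is undefined at $n = 1$.

# The behavior generative model

Each fly is an alternating renewal process on the 1-min monitor grid.
Sleep bouts are 5 min plus an exponential tail (mean 45 min), so every
generated bout satisfies the standard *Drosophila* sleep criterion of
>= 5 min of inactivity by construction; wake-bout means are set from
the stationary sleep fractions (default 85 % of night minutes, 20 % of
day minutes asleep), and a wake bout that spans a lights-on/off
transition is redrawn from the new phase's distribution so each phase
actually reaches its stated sleep fraction.  Awake minutes emit
$1 + \mathrm{Poisson}$ beam crossings (mean 3): the floor of one
cross per awake minute keeps the generator's sleep/wake ground truth
and the analysis-side zero-run rule in exact correspondence, which the
tests verify at >= 99 % minute-level agreement.

At each pulse onset, a fly that is in a sleep bout awakens with
probability $p$ (the condition's published arousal fraction, from
`defaultBehaviorParamTable()`); an awakened fly stays active for a
geometric number of minutes (mean 10), a non-awakened fly's bout is
carried through the pulse window.  Carrying the bout through the
window is what makes the generated response *exactly* Bernoulli($p$):
without it, natural bout endings inside the 5-min window would inflate
the scored arousal of low-$p$ genotypes by several points.

Scoring mirrors the generator's contract from the analysis side: a fly
enters a pulse's denominator iff the five minutes before onset are all
zero; it is aroused iff any count lands in the 5-min pulse window;
flies with zero counts over the final 24 h are excluded as dead.  The
total arousal fraction is denominator-weighted
($\sum \mathrm{aroused} / \sum \mathrm{asleep}$) because the published
aggregation is unstated; an unweighted mean of the nine per-pulse
percentages is also reported and the two differ only when denominators
vary across pulses.

# Inference

Every pairwise comparison runs the same gated path: Anderson–Darling
normality on both samples at $\alpha = 0.05$; if both pass, an F-test
at $\alpha = 0.05$ chooses a pooled-variance or Welch one-tailed
t-test; otherwise the one-tailed Mann–Whitney U-test (exact when both
n <= 20 without ties, normal approximation with continuity correction
otherwise).  Three reading-level decisions are documented rather than
silent:

* The Anderson–Darling statistic is undefined below n = 8; smaller
  samples route to Mann–Whitney, the conservative branch.
* Tail direction is always supplied by the caller (the pipeline tests
  control > mutant); it is never inferred from the data.
* The t-test significance level is 0.05, the conventional
  pre-correction alpha for this workflow.

Multiplicity is controlled per family — all control-vs-mutant
comparisons within one wavelength (x intensity) panel — by
Benjamini–Hochberg step-up at $q = 0.1$, with tiers `*` < 0.1,
`**` < 0.05, `***` < 0.01 on the adjusted values (exclusive
boundaries).  The BH implementation is `stats::p.adjust`; the tests
check it against an independent brute-force step-up oracle on 1,000
random vectors, and a global-null simulation (all fold changes 1,
equal arousal probabilities) confirms the realized false-discovery
proportion stays at or below 0.1 up to Monte-Carlo error.

# Reproducibility and problem sizes

All randomness flows from one master seed through a platform-stable
string hash (`seedFrom`), giving every cell, sweep and fly its own
derived stream; reruns with the same configuration and seed are
byte-identical down to the written TSV and monitor files.

The validation runs use the published group sizes: 16/13/11 cells x 5
sweeps at 10 kHz for the FF-ratio recoveries, 35 cells for the baseline
recovery, and 32 flies x 3 nights x 3 pulses for the arousal
recoveries (roughly 220 scored pulse events per condition).  Replicate
studies that only need the sampling distribution of the FF statistics
(the 20-replicate significance-pattern check and the 100-family
global-null study) use the pipeline's spike-level fast path
(`render = FALSE`), which is statistically equivalent because detection
is separately shown to be >= 99 % sensitive and precise.

# What passing tests do and do not show

The generators emulate the statistical structure the analysis relies
on: tonic Poisson-like firing with a multiplicative light response,
stereotyped spike waveforms in Gaussian noise, clean alternating
sleep/wake with pulse-locked Bernoulli arousal.  Real recordings
contain features deliberately not modelled — bursting episodes,
electrode drift and seal instability, movement artifacts, arousal
latency spread, activity bleed across monitor channels.  Parameter
recovery on this synthetic data validates the *estimators and their
wiring* (windows, conventions, exclusions, multiplicity control), not
the biology; on real traces the spike detector's threshold and the
sleep rule's minute grid would face artifacts the simulation does not
produce.  Limitations worth restating: the post-stimulus decay
constants are qualitative reconstructions; the behavior model has no
circadian modulation beyond the day/night propensity switch; and the
dead-time deflation of the FF ratio (< 1 %) is accepted rather than
corrected.

```{r example}
# one small end-to-end run
res <- runEphysPipeline(list(seed = 1, genotypes = c("p12c", "gl60j"),
                             colors = "blue", n_cells = 4,
                             render = FALSE))
res$groups
res$comparisons[, c("label", "test", "p", "pAdj", "tier")]
```
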