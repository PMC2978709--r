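---
title: "Quantal analysis and morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal analysis and morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmjquant)
```

This vignette is the package's account of the science it implements: the
models behind each analysis, the assumptions they make, the parameters
that matter, and the design decisions that were genuinely open.

## The quantal model of neuromuscular transmission

Transmission at the neuromuscular junction is quantized: the spontaneous
fusion of one synaptic vesicle produces a miniature endplate potential
(MEPP), and a nerve impulse releases some number *m* of quanta — the
quantal content — whose summed depolarization is the endplate potential
(EPP). The package implements the *direct method*:

$$m = \frac{\overline{EPP}}{\overline{MEPP}},$$

with both averages taken per junction after two conditioning steps:

1. **Nonlinear-summation correction.** A recorded depolarization $v$
   saturates as it approaches the driving force $E = V_{rev} - V_{rest}$;
   the linear amplitude is recovered as $v' = v/(1 - f\,v/E)$. The shape
   factor defaults to $f = 0.8$ and the reversal potential to
   $V_{rev} = 0$ mV, the conventional values for this correction at the
   endplate; neither is usually measured directly, so both are arguments
   everywhere they enter.
2. **Normalization to −50 mV.** Amplitudes scale with driving force, so
   fibers with different resting potentials are made comparable by
   $v'' = v' \,(V_{rev}+50)/(V_{rev}-V_{rest})$.

The order of these steps is not dictated by their definitions, and they do
not commute because the correction is nonlinear. The package fixes
*correct at the fiber's own resting potential first, then normalize*: the
saturation happened physically at the fiber's actual driving force, so the
correction must be applied there. A regression test pins this order. The
correction is applied to MEPPs as well as EPPs; at MEPP scale (~0.6 mV
against E = 50–70 mV) it is a sub-1% adjustment, so this choice is
harmless but keeps the two amplitude families on the same scale.

## Readily releasable pool and release probability

During a 50 Hz train the pool of release-ready vesicles depletes. With
constant release probability $p$, pool size $N$ and no replenishment, the
expected quantal content of pulse $i$ given the cumulative release
$C_i = \sum_{j<i} m_j$ is exactly linear:

$$\mathbb{E}[m_i \mid C_i] = p\,(N - C_i).$$

The Elmqvist–Quastel estimator fits $m_i$ against $C_i$ by least squares
and extrapolates to the x-axis: the intercept estimates $N$, the slope
$-p$. The first pulse is always excluded (it is facilitated rather than
depressed). Release probability is then $p = m_1 / \hat N$.

**Fit window.** The default window is pulses 2–6 (a fixed, reproducible
choice for the "initial linear depression"), with an automatic
alternative (`fit_range = "auto"`) that grows the window from pulse 2
while the fit keeps $r^2 \ge 0.9$. At the study's operating point —
$N \approx 640$, $p \approx 0.027$ — the expected per-pulse depression is
only ~0.5 quanta against a binomial noise SD of ~4, so a 5-point window
cannot resolve the slope. Because the depletion relation above is linear
over the *entire* train when replenishment is negligible, the recovery
analyses use the full window `2:n_pulses`; this is a property of the
regime, not a tuning knob, and the deterministic exactness test passes
for any window.

**Known confound.** With replenishment, late pulses are partly refilled,
the apparent depression flattens, and the x-intercept overestimates $N$
monotonically in the replenishment rate. A test asserts this direction on
the early-window fit; at high replenishment some realizations have no
resolvable depression at all, and the estimator reports "no depression
phase" rather than a number.

## The synthetic-data generator

The generator exists so that every analysis can be checked against known
ground truth. It emulates:

- **Spontaneous activity:** homogeneous Poisson event times at a stated
  rate (default 8.97/min, the control MEPP frequency scale); each event is
  a difference-of-exponentials kernel (rise 0.5 ms, decay 5 ms — typical
  endplate kinetics) with amplitude drawn from a Gaussian with mean
  `q_mean` (default 0.61 mV) and SD `q_cv * q_mean`, truncated at
  `0.05 * q_mean` so quanta are strictly positive. Summary data constrain
  only two moments; the truncated Gaussian is the conventional quantal
  model. Amplitude variability is modelled per event; fiber-level
  variation enters through per-junction `q_mean` (which the driving-force
  scaling ties to the fiber's resting potential).
- **Evoked release:** at each stimulus, quanta ~ Binomial(current pool,
  current *p*); the pool is decremented and replenished continuously
  (never above its capacity); facilitation adds an increment to *p* after
  each stimulus, decaying exponentially (default tau 50 ms) — a minimal
  residual-effect model sufficient to reproduce paired-pulse facilitation;
  the summed depolarization passes through the forward saturation
  $v/(1 + f\,v/E)$, the exact inverse of the correction above, before
  entering the trace. `ppf_increment_for_target()` inverts the two-pulse
  expectation in closed form, so cohorts can be parameterized by their
  target paired-pulse ratio.
- **Recording realism:** per-sample Gaussian noise (default 0.05 mV),
  10 kHz sampling, fiber-to-fiber resting-potential variation in the
  study driver (Normal around −68 mV, SD 3 mV).
- **Muscle force:** a twitch is a difference-of-exponentials pulse (rise
  10 ms, decay 40 ms). In trains, each stimulus adds a twitch scaled by
  $1 - F(t)/F_{max}$ with $F_{max} = \texttt{peak\_g}/\texttt{fusion}$ —
  an activation-saturation model chosen because it keeps a single twitch
  exactly at `peak_g` while letting high-frequency trains fuse toward a
  plateau; `fusion -> 0` recovers linear summation. A global saturating
  transform could not satisfy both requirements at once.
- **Count data:** per-unit counts are negative binomial with the stated
  mean and dispersion (Poisson in the `Inf` limit). Published per-neuron
  SEMs imply variances far above Poisson (e.g. mean 64.3 with SEM 3.6 at
  n = 180 implies a variance of ~2300), so `nb_size_from_sem()` matches
  the dispersion to a printed SEM exactly. Perimeters and areas are Gamma
  distributed.

What the generator does **not** emulate: cable and conductance biophysics
(events are stereotyped kernels), electrode drift and access-resistance
artifacts, correlated noise, multi-vesicular coordination beyond the
binomial, image-level data (morphometry starts at count tables), and
fatigue or length–tension effects in muscle. Passing tests therefore
demonstrate that the analyses recover the parameters of *this* data model
at realistic noise levels — not that they are robust to every artifact of
real recordings.

## Event detection and measurement

MEPP detection tracks the baseline with a running median (window 200 ms —
wide enough that an event's ~25 ms footprint cannot inflate the median),
estimates the noise SD as the MAD of the residual, smooths the residual
with a 1 ms boxcar, and takes local maxima exceeding
`threshold_sd` (default 3) times the *raw* noise SD, separated by at least
`min_interval_ms` (default 5 ms). A peak only counts if it also rises a
full threshold above its own local pre-event baseline, which rejects
re-crossings on decaying tails. The smoothing is what makes a 3-SD
threshold usable on long traces: unsmoothed Gaussian noise crosses 3 SD
thousands of times per minute at 10 kHz.

EPP measurement takes, per stimulus, the window maximum minus the median
of the immediately preceding 2 ms. For paired pulses 10 ms apart the
second response rides on the first's tail; `subtract_prev_decay = TRUE`
fits a single exponential to the inter-stimulus segment and subtracts its
extrapolation before taking the peak. Without this, the measured ratio is
biased low by roughly the tail's curvature over the window (~10 points at
these kinetics).

## Group statistics

`group_compare()` is the pooled-variance two-sample two-tailed Student's
*t*-test (`stats::t.test(var.equal = TRUE)`), reported as mean ± SEM per
group with a signed percent change: **positive = reduction vs control,
negative = increase**, with the direction also reported as a word.
Welch's form is behind `welch = TRUE`. The degenerate case (zero variance
in both groups, equal means) reports *p* = 1. The unit of analysis
defaults to the individual neuron/junction/section, matching the
published figure captions; per-animal aggregation is a matter of passing
a per-animal table. The published captions mix per-neuron *n* and
per-animal *N*, and two printed percentages (the ~54%/~14% transporter
reductions) do not match arithmetic on their printed per-neuron means —
the package computes from whatever table it is given and does not guess
which aggregation produced a printed number.

Innervation classification thresholds terminal–receptor overlap at 0.9
(full) and 0.1 (denervated); the published classification was visual, so
these are a declared operationalization, configurable per call.
Stereological totals multiply the mean count over sampled sections by the
total section count — unbiased under systematic 1-in-5 sampling with a
random start, which the simulation-based tests verify.

## Numerical choices and degenerate inputs

- The saturation/correction pair is algebraically exact; a grid test
  holds the round trip to 10⁻⁹ mV.
- `estimate_rrp()` refuses fits with slope ≥ 0, zero variance in the
  responses, or $r^2$ below a configurable floor ("no depression phase"),
  and warns rather than clips when the implied release probability
  exceeds 1.
- Measured amplitudes can be slightly negative for release failures in
  noise; pipelines clamp at zero (a failure contributes zero quantal
  content) before conditioning, since the correction is undefined for
  negative inputs.
- All stochastic operations take an explicit seed and derive per-stage
  sub-seeds from it; no global RNG state leaks between stages, and
  identical configuration plus seed gives byte-identical study reports.

## Problem sizes

The bundled study driver (`run_study()`) uses desk-scale cohorts chosen to
resolve the published group differences while keeping a full run in the
tens of seconds: 12 junctions per group for the 1 Hz quantal cohort (60 s
of spontaneous recording and 40 evoked responses each — the analysis-grade
thresholds of ≥7 MEPPs and ≥40 EPPs per junction), 12 paired-pulse
junctions averaging 20 sweeps, 15 pool-depletion trains of 40 pulses, 9
muscles per group across 1/10/40/100 Hz in both stimulation modes, and
morphometry cohorts at the published per-group *n*. The recovery analyses
in the test suite and acceptance script use 500 trains/seeds where a mean
is being certified against truth.

## Limitations

The estimator analyses inherit the binomial-depletion model's assumptions:
uniform release probability across vesicles, no postsynaptic receptor
saturation or desensitization beyond the nonlinear-summation term, and
replenishment that is slow relative to a 50 Hz train. The published
experimental values themselves are not recomputable from raw data (none
are deposited); what the package certifies is (a) exact arithmetic
reproduction of every derived percentage from the published group means,
and (b) ground-truth recovery of the machinery on synthetic data at the
published operating points.
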