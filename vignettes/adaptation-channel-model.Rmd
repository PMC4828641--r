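---
title: "The adaptation-channel model behind ssasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The adaptation-channel model behind ssasim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssasim)
```

`ssasim` simulates and analyses stimulus-specific adaptation (SSA) in
single auditory midbrain neurons under the hypothesis that SSA is inherited
from activity-dependent synaptic depression within narrowly
frequency-tuned, convergent input channels.  This vignette is the package's
account of the science: the model and its assumptions, the parameters that
matter, what the synthetic data emulate (and what they do not), the
numerical choices, and the known limitations.

## The model, stage by stage

A stimulus sequence is a train of tones at a fixed onset asynchrony
(default 250 ms, i.e. 4 Hz).  Because adaptation accumulates trial by
trial, not sample by sample, every stage operates once per tone.

**Cochlear front end.**  Stimulus frequencies are mapped log-linearly from
the rat hearing range (0.5–40 kHz) onto a human range (0.125–10 kHz); the
map preserves octave relations and is configuration, not physiology — no
published formula exists for it.  Each of the (default 40, log-spaced)
channels responds with the sum of two paths evaluated at steady state:

- a *nonlinear path*: the tone's pressure amplitude `10^(level/20)`
  weighted by a gammatone-like magnitude profile one equivalent rectangular
  bandwidth (ERB) wide, then compressed by a broken stick
  `min(a·x, b·x^ν)` with `ν = 0.25` and a knee placed at 30 dB SPL for an
  on-CF tone;
- a *linear path*: the same profile at 2.5 ERB width with a small gain
  (0.03), uncompressed.

At low levels the narrow compressive path dominates and tuning is sharp; at
high levels compression caps it and the broad linear path takes over, so
the excitation pattern widens with level.  That broadening is the mechanism
by which a louder standard invades the channels of a fainter deviant — the
model's explanation for intensity-oddball adaptation — and it emerges from
the two-path structure rather than from an explicit bandwidth-versus-level
rule (an optional coefficient `bw_level_coef` exists for sensitivity
analyses).  A threshold-saturating Hill sigmoid (`θ = 30` model pressure
units, exponent 2, maximum normalized to 1) converts excitation to
auditory-nerve-like activity; the unit normalization fixes the otherwise
arbitrary scale of "synaptic activity" used below.

**Adaptation stages.**  Channel activities are weighted by a non-negative
vector `W` (the neuron's tuning), adapted per channel by subtracting the
accumulated depression `A_t` (clamped at zero — the subtraction can
transiently exceed the drive, e.g. a faint deviant following a loud
standard, and negative synaptic activation is non-physical; the clamp is
applied before both the output and the update), summed across channels and
passed through an output sigmoid to give the firing rate in spikes per
stimulus.  The per-channel recursion is

```
A_{t+1} = (1 − R) · (A_t + g(ASYN_t)),   A_1 = 0,
g(x) = [m + (M − m) · 2^(−x/τ)] · x .
```

`M` and `m` are the low- and high-activity slopes of the adaptation
function (dimensionless), `τ` (synaptic-activity units) the activity at
which the slope is `(M + m)/2`, and `R` the per-trial recovery fraction.
The paper the model derives from never reports `R`; it defaults to
0.1/trial and stays fixed during fitting.  Silent slots in a sequence
contribute zero drive but still advance the recovery, which is why alone
(control) sequences keep their silent positions explicitly.

## Stimulus protocols

All protocols are explicit timed event tables: oddball sequences (400
tones, 90/10 standard/deviant split enforced exactly, seeded uniformly
random order with no spacing constraint), deviant- and standard-alone
controls (the other role replaced by silence), the full 14-condition
protocol (1 frequency oddball at `Δf = 0.1` + 3 intensity differences × 4
frequency separations + 1 alone control, with
`Δf = (f₂ − f₁)/√(f₂ f₁) ∈ {0, 0.04, 0.1, 0.37}` and
`Δi ∈ {10, 30, 50}` dB), the repeated adaptation paradigm (RAP; trials of
three identical adaptors and a probe, `a a a p`, 2000 ms per trial
including a 1-s recovery gap, the adaptor roved over the 25 × 8 FRA grid
with 4 repeats), forward suppression (one adaptor, probe at adaptor offset
plus gap), and the FRA grid itself (25 logarithmic steps over 0.5–40 kHz,
levels ascending in 10-dB steps, 5 repeats).  Tone duration is 75 ms with
5-ms ramps throughout; octave conversions are computed from the `Δf`
definition (`0.1` ↔ 0.144 octaves) rather than taken from rounded printed
values.

## The synthetic population

`make_population()` is the study design, not a convenience fixture.  It
draws neurons with log-normal best frequencies across the rat range and an
exact-count split into two classes:

- **strong-SSA** units (70% by default): initial slope `M ~ U(0.55, 0.9)`,
  `τ ~ U(0.3, 0.6)`, narrow channels (1 ERB) under a broad synaptic
  envelope (σ ≈ 1 octave).  Narrow channels make adaptation
  frequency-specific, so the frequency-oddball CSI lands above the 0.18
  strong/weak cutoff.
- **weak-SSA** units: `M ~ U(0.28, 0.45)`, `τ ~ U(0.5, 1.0)`, channels
  broadened 3×.  Their CSI stays below 0.18 *because adaptation
  generalizes across the frequency pair*, not because they barely adapt:
  with the larger `τ` the adaptation slope stays near `M` at the drives
  the paradigms reach, so these units still cross the 0.6 suppression
  criterion in the RAP — but over a region almost as wide as their FRA.
  This keeps every strong `M` above every weak `M` and the population
  adaptation curve of the strong class above the weak class, while
  reproducing the narrow-versus-broad suppression-area contrast.

Each unit's anchor stimulus sits at its best frequency, 10 dB above
threshold, with the output sigmoid's half-saturation placed at the
unadapted drive of that anchor — the operating point where suppression of
the input translates most sensitively into rate suppression.  Spiking is
Poisson per stimulus (the minimal noise model consistent with
onset-dominated responses): driven counts with mean equal to the model
rate, an exponential onset envelope (20-ms decay) truncated to the tone,
first-spike latency `base + slope·drive` with negative slope and 1-ms
Gaussian jitter, and homogeneous spontaneous firing (0.5–4 spikes/s).

What the generator does *not* emulate: recording noise and drift, bursting
and refractoriness, spike-sorting contamination, across-trial rate
correlations, and any within-trial adaptation.  Tests passing on this
population therefore validate the analysis pipeline and the model's
internal consistency, not the biological fidelity of any particular
recorded dataset.

## Analysis choices

- **Rates** are spikes per stimulus in the inter-onset window, minus the
  expected spontaneous count, floored at zero; the spontaneous rate is
  estimated from the silent slots of alone sequences.
- **FRA**: response criterion at 20% of the peak above the spontaneous
  level (a common convention; the source literature states no edge rule),
  threshold the lowest level with any supra-criterion cell, best frequency
  the peak at threshold + 10 dB, bandwidth the contiguous supra-criterion
  run containing the BF with geometric half-step cell edges (a single
  supra-criterion cell has nonzero width).
- **FSA**: baseline is the mean probe rate over the lowest adaptor
  intensity row; suppression is `1 − probe/baseline` with the area defined
  by suppression ≥ 0.6.  The criterion's printed phrasing is ambiguous
  between this reading and `probe/baseline ≤ 0.6`; the alternative is one
  configuration switch away (`mode = "ratio"`).  Bandwidths are read at
  the adaptor levels nearest probe + 10 and + 30 dB, at the grid column
  nearest the probe frequency.  An FSA wider than the FRA is flagged, not
  forbidden — noise can produce it.
- **Indices**: singular denominators (both responses ~0, or `u₁ = 0`)
  propagate as missing values with reason codes, never as zeros — such
  units are discarded downstream, not imputed.  Classification cutoffs are
  boundary-inclusive (strong iff CSI ≥ 0.18; monotonic iff MI ≥ 0.75).
- **Bootstrap**: 1000 within-neuron resamples of trials per role,
  percentile intervals.  "Little or no response" is operationalized as:
  the 5th percentile of the resampled summed response must exceed the
  expected spontaneous count, else the SI is flagged unreliable.
- **First-spike latency**: first spike within tone duration + 50 ms
  (catching offset-delayed responses), median across spiking trials,
  missing when no trial spikes; the reported convention is standard minus
  deviant (positive = deviant earlier).

## Fitting

`(M, m, τ)` are fitted per neuron by nonlinear least squares on the
observed versus simulated `NRI_d` across conditions.  Because the synaptic
drive matrices do not depend on the adaptation parameters, they are
precomputed once and the optimizer re-runs only the compiled recursion.
Eight multi-starts (log-spaced in `τ`) of bounded L-BFGS-B are followed by
a Nelder–Mead polish: the objective is nearly flat along an `(m, τ)`
trade-off and finite-difference gradients stall there, while the polish
reaches the global minimum to machine precision on noise-free data.
Bounds are `M ≤ 3` and `τ ∈ [0.1, 3]`: with per-channel activity
normalized to at most 1, half-transitions far outside that range are
unobservable and the decomposition of `g` degenerates (`τ → 0` reduces
`α(x)` to the constant `m` for any positive drive).  `R` is held fixed,
matching the three-parameter formulation; a free-`R` mode exists but is
off by default.

Under Poisson noise at 40 deviant trials per condition the fit is
noise-limited, not optimizer-limited: a brute-force grid search over the
bounded parameter box scatters around the true `M` by a comparable margin,
because most of the 13 conditions sit at `NRI_d ≈ 0` and carry almost no
information about `M`.  Interpret single-neuron noisy fits accordingly;
the population-level fit of `y = g(x)` to (deviant-alone, deviant-alone −
standard-alone) rate pairs is the more stable quantity.  That fit profiles
`τ` on a log grid, solves the remaining two coefficients by constrained
linear least squares in closed form (the model is linear in `m` and
`M − m` at fixed `τ`), and polishes with Levenberg–Marquardt — robust even
when the curve degenerates to a straight line.

The per-neuron calibration (`calibrate_neuron`) reads the tuning profile
at threshold + 10 dB, interpolates it onto the channel array, and refines
it with a few multiplicative Richardson–Lucy updates against the
filterbank's own excitation spread; without the refinement the calibrated
model's best frequency lands about two grid steps below the measured one,
because low-CF channels are fractionally broader and skew the smeared
profile.

## Numerical and reproducibility choices

Every stochastic stage takes an explicit integer seed; one master seed
fans out deterministically to sequences, spike draws, bootstrap and
optimizer starts, and identical configurations produce byte-identical CSV
output.  The trial recursion is compiled (Rcpp) and skips channels that
are never driven.  NRI-based model checks average each condition over
three independent sequence permutations per neuron: a single 400-trial
sequence leaves sampling noise of order 0.005–0.01 on `NRI_d`, comparable
to the differences between near-floor conditions.  Deterministic model
checks in the test suite use 10–20 neuron populations and the full
13-condition protocol; these sizes make the whole suite run in a few
minutes on a single core while leaving the qualitative contrasts far from
their decision boundaries.

## Known limitations

- The deviant-alone control is only *largely* unadapted: uniformly random
  deviant placement occasionally puts two deviants close together, and the
  residual adaptation (amplified by the output sigmoid) leaves
  tone-to-tone fluctuation around 60–90% of the truly unadapted rate.
  This matches the assumption actually needed — `u₁` approximates the
  maximum response — but not a literal constant-rate reading.
- Adaptation is strictly per channel; cross-channel (e.g. inhibitory) and
  multi-layer interactions are out of scope, as is any within-trial
  dynamics in the rate model.
- The rat-to-human frequency map, the transfer-function parameters and
  `R` are stated defaults, not fitted quantities; conclusions that hinge
  on their exact values should be checked against the configuration
  switches exposed in `filterbank_config()` and `model_neuron()`.
- Weight calibration inherits cochlear spread at the reference level;
  for very broad channels the recovered `W` is a deconvolved estimate,
  accurate in correlation (r ≳ 0.95 on round trips) but not channel by
  channel.
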