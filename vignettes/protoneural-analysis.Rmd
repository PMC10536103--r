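---
title: "Methods: from proteinoid traces to protoneural models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from proteinoid traces to protoneural models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protospike)
```

Proteinoid microspheres — vesicles self-assembled from thermally
polymerised amino acids — show spontaneous electrical spiking driven by
transmembrane proton flux. This package implements the computational side
of characterising that activity: generating controlled synthetic
recordings, detecting and summarising spikes, abstracting the vesicle
population as a small neural network with a latency temporal code, and
relating firing rates to molecular descriptors. This vignette documents
the models, the parameters that matter, and the design decisions taken
where the underlying science leaves the choice open.

## The recording model and its synthetic emulation

Recordings are uniformly sampled scalar signals with an explicit unit.
Two units occur in practice: potential differences between electrode
pairs (volts) and differential pulse voltammetry (DPV) currents
(microamperes). A trace never exists without its unit: thresholds in
microamperes applied to a volt-scale trace are meaningless, so
`detect_spikes()` refuses a threshold tagged with the wrong unit and
`read_trace_csv()` rejects files without unit metadata rather than
guessing.

The synthetic generator emulates the reference acquisition — one sample
per second, spike trains with tens to hundreds of events over hours — in
two regimes:

- **Exact count** (`n_spikes`): spike times are sorted uniform draws in
  the slack interval left after reserving a refractory gap between
  consecutive spikes, then shifted apart by that gap. This guarantees the
  exact count, the minimum spacing, and uniform coverage of the
  recording.
- **Target mean interval** (`mean_isi`): interspike intervals are drawn
  as `refractory + Exponential(mean_isi - refractory)`, a Poisson process
  with dead time whose expected interval equals the target. This is a
  modelling choice: only count and mean-interval summaries of the real
  recordings are available, not their point-process law, and a dead-time
  Poisson process is the simplest law consistent with both the summaries
  and the detector's minimum peak distance.

The refractory gap defaults to 5 s, deliberately equal to the detector's
minimum peak distance, and spikes are kept half a gap away from the
recording edges. Together with a pulse amplitude above threshold and zero
noise these defaults make generation and detection exact inverses, which
is the backbone of the conservation tests: every generated cohort must be
re-detected spike for spike.

Spikes are rendered as Gaussian bumps (sd = `spike_width`/4, so a bump
spans about one `spike_width`) rather than rectangles: a smooth unimodal
pulse has a well-defined peak sample on a 1 Hz grid, whereas a rectangle
sampled at 1 Hz yields plateaus whose detected time would depend on
tie-breaking. Pulses closer than one `spike_width` would merge into a
single local maximum, so the renderer treats that as an error instead of
silently losing a spike.

What the generator does *not* emulate: the 24-bit ADC's 600-fold
oversampling and averaging, baseline drift, 1/f noise, asymmetric spike
shapes, and any electrochemical current response (the DPV module produces
the excitation program and its sampling instants only — no redox
kinetics). Passing tests therefore demonstrate the correctness of the
analysis machinery, not robustness to every artefact of real
electrochemistry.

The reference cohort (`cohort_specs()`) reuses the embedded
spike-characteristics table: each of the 12 proteinoid samples gets its
printed spike count. Recording durations were not reported; each duration
is taken as `n_spikes x mean_isi` seconds — the span implied by the
printed count and mean interval — which is the natural choice but not
authoritative.

## The DPV excitation program

The DPV program is a staircase of base potentials from −8 V to 8 V in
1 mV steps at 1 mV/s (so each level holds for 1 s), with a 0.2 V
rectangular pulse of 0.08 s at the end of each step, preceded by a 100 s
equilibrium hold; the current is sampled immediately before pulse onset
and at pulse end, the difference isolating the Faradaic component. The
waveform is represented exactly as piecewise-constant segments — the
default program has 16,001 levels, and a densely sampled rendering would
add nothing but memory pressure. `dpv_potential_at()` evaluates the
applied potential at arbitrary times; the pulse window is half-open
(`[onset, end)`) so each instant belongs to exactly one level.

## Spike detection and statistics

`detect_spikes()` implements threshold-plus-distance peak picking:

1. every *strict* local maximum above the threshold is a candidate — the
   inequality is strict because the temporal-code definition treats
   θ-crossing as "greater than θ", and the two conventions are kept
   consistent; the first sample of a flat maximum is its time, and edge
   samples are never peaks (a maximum needs two neighbours);
2. candidates are pruned greedily in order of descending height (earlier
   time wins ties) with a minimum-distance check against all survivors.

Height-priority pruning is the convention of standard signal-processing
peak finders; the alternative (left-to-right scanning) would keep a small
early peak at the expense of a large later one. The implementation is
checked against an exhaustive quadratic re-derivation on hundreds of
random traces, and must agree exactly.

Statistics follow the tabulated definitions: mean interspike interval as
the arithmetic mean of consecutive differences and spiking frequency as
its reciprocal in millihertz, `f = 1000 / mean_isi`, formatted to two
decimals. With fewer than two spikes both are reported as undefined
rather than `NaN`. One caveat uncovered while testing the embedded
reference table: its interval and frequency columns were evidently
rounded independently from unrounded values, so recomputing one printed
column from the other can differ by up to two units in the last printed
digit; two of its rows (`L-Glu:L-Arg`, `L-Asp`) are off by orders of
magnitude — consistent with a row shift at typesetting — and are excluded
from reciprocity checks. The embedded table is shipped as printed, not
corrected.

## Latency temporal coding and co-activation learning

For a column of N potentials the code is
\[
c_j = \mathbf{1}[p_j > \theta]\,(T - m), \qquad
m = \min\{p_k : p_k > \theta\},
\]
so all neurons firing in a column share one latency factor set by the
weakest suprathreshold potential: a column with barely-suprathreshold
activity codes close to T, strong activity codes lower. The definition
is declared over binary codes but evaluates to real latencies; the
package stores the real value as primary and exposes the binarised view
`c > 0` where consumption requires a firing decision (weight updates).
Raising θ can only zero entries, never create them — a monotonicity that
is property-tested.

Synaptic weights live in [−1, 1]; the printed 10 × 10 initialisation is
shipped verbatim (`load_initial_weights()`) and random initialisation is
uniform on the same range. The learning rule is the canonical Hebbian
co-activation update
\[
W \leftarrow \mathrm{clip}(W + \eta\, b b^{\mathsf T}, -1, 1),
\]
with the diagonal held fixed (no self-reinforcement) and η defaulting to
0.1 — small enough that saturation takes ~10 co-activations, large enough
to converge within one pass over a few hundred code columns. Perfectly
correlated pairs saturate at +1; never-co-active pairs keep their
initial weight: both limits are tested.

The connectivity indices are this package's concrete definitions — only
verbal descriptions of "first-order" and "second-order connection
potency" exist:
\[
\mathrm{PSI}_j = \frac{\sum_i \max(W_{ij},0)\,a_i}{\max(\sum_i a_i,\ \varepsilon)},
\]
with PPI applying the same form to `max(W,0)²/N`. Rectification makes
them excitatory-drive measures, the activity weighting makes silent
presynaptic partners irrelevant, and the normalisations bound both in
[0, 1] with an ε = 1e-12 floor so an all-silent network yields 0, not
NaN.

## Network simulators

Two architectures connect an input signal \(F_{in}(t)\) to an output
\(F_{out}(t)\): a spiking network of N leaky integrate-and-fire neurons
and a continuous-variable rate network. No dynamical equations accompany
the published architecture sketches, so the standard textbook dynamics
are adopted and documented:

- LIF: \(\tau_m \dot v_j = -v_j + U_j F_{in} + \sum_k J_{jk} s_k\), spike
  and reset at \(v_{th}\), optional absolute refractory period,
  single-exponential synaptic traces with \(\tau_s = \tau_m/2\) (the
  minimal smooth coupling that makes \(F_{out} = W^{\mathsf T} s\)
  well-behaved), forward Euler.
- Rate: \(\tau \dot x = -x + \tilde J \varphi(x) + \tilde U F_{in} +
  u F_{out}\), \(\varphi = \tanh\), with the output loop closed through
  \(W_{out}\) when feedback is on. How \(F_{out}\) is generated in the
  rate architecture is not specified in the source sketch; closing the
  loop through the same output synapses as the spiking case is this
  package's interpretation.

Forward Euler is used deliberately: the guard `dt <= tau/10` keeps the
leak stable, initial conditions default to zero, and correctness is
established not by a fancier integrator but by convergence tests — the
single-neuron constant-drive interspike period must match the closed form
\(\tau_m \ln(I/(I - v_{th}))\) within 1% at `dt = tau_m/1000`, and
halving `dt` must move the estimate by < 0.5%. Euler's bias at that step
size is dominated by the one-step quantisation of the threshold crossing,
which the tests' drive ranges keep well under the tolerance.

`drive_with_proteinoid()` bridges the modules: detected spike times
become rectangular input pulses, so slow electrochemical spike trains can
drive the (much faster) model networks. The time-scale mismatch is left
to the caller — the defaults make no attempt to compress hours of
recording into simulation seconds.

## The QSAR model

Mean firing rate is modelled as affine in molecular weight and peptide
length, fitted by ordinary least squares with intercept; 95% bounds use
the t distribution with n − 3 degrees of freedom. The published
coefficients are typographically lost in the source and the per-sample
descriptor values were never printed, so the embedded firing-rate table
is treated as data — its extrema and percent deviations are summarised,
not re-derived — and the fitting machinery is validated by parameter
recovery instead: noiseless tables must be interpolated exactly (the
acceptance script checks to 1e-8), and across 500 noisy replicates at
n = 100 each true coefficient must fall inside its 95% interval 93–97% of
the time. Synthetic descriptors default to molecular weights uniform on
[100, 2000] g/mol and lengths on 1..20 residues — spanning single amino
acids to small thermal polypeptides — with rate noise of 5 Hz against
rates of order 500 Hz, a ~1% noise level matching the tight regression
plane the activity data suggest. Percent deviation is reported signed, as
100 · (predicted − observed)/observed. Extrapolation outside the fitted
descriptor range is permitted but flagged; the embedded table itself
shows what unflagged extrapolation does, containing physically impossible
negative predicted rates.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and restores the caller's
RNG state, so pipelines are reproducible end to end; `run_pipeline()`
with a fixed seed produces byte-identical artifacts, which is tested. The
test and acceptance workloads use sizes chosen to exercise the methods
without waste: 200 random traces of up to ~10,000 samples for
detector–oracle equivalence, the full 12-sample cohort (≈186,000 samples,
≈4,200 spikes) for conservation, 1,000 random columns for the temporal
code, 10 constant-drive scenarios at `dt = tau_m/1000` for the LIF limit,
and 500 replicate fits at n = 100 for coverage. Cohort-level summaries
computed on the emulation (for example the mean spike count across the 12
samples) are means of the embedded table's counts by construction; they
are *not* estimates of the original recordings' summary statistics, whose
in-text values are inconsistent with the printed per-sample rows.

## Known limitations

- The point-process and pulse-shape models are plausible stand-ins, not
  inferences from raw data; real proteinoid recordings may have bursty or
  rhythmic structure the dead-time Poisson law cannot produce.
- The DPV module generates the excitation program only; no
  electrochemical response model is included, so it cannot predict
  voltammograms.
- The PSI/PPI indices and the network dynamics are declared definitions
  where the source material is verbal; conclusions drawn from them are
  conclusions about these definitions.
- The QSAR fixture's predicted column cannot be re-derived without the
  unprinted descriptors; the package validates its own fitter by
  synthetic recovery instead.
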