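# protospike

Spike-train analysis and minimal neural-network models for the spontaneous
electrical activity of **proteinoid microspheres** — thermal-protein vesicles
that emit action-potential-like current and voltage spikes and have been
proposed as "protoneurons" for unconventional computing.

The package is aimed at researchers analysing electrochemical recordings of
such self-assembled biomolecular systems (or any slow, sparse spiking signal
logged at ~1 Hz) who want a reproducible, fully seeded pipeline from raw
traces to spike statistics, network abstractions and structure–activity
models.

## What it computes

- **Synthetic traces.** Seeded generators for spiking recordings: spike
  trains with an exact spike count (uniform placement under a refractory
  gap) or a target mean interspike interval (Poisson process with dead
  time), rendered as Gaussian pulses on a uniform sampling grid with
  optional Gaussian noise. A 12-sample cohort emulating the reference
  spike-characteristics table ships as `cohort_specs()`.
- **DPV excitation program.** The differential pulse voltammetry staircase
  (equilibrium hold, base-potential steps with superimposed rectangular
  pulses, and the two per-step current-sampling instants), exactly
  represented and evaluable at arbitrary times.
- **Spike detection and statistics.** `detect_spikes()` finds strict local
  maxima above a threshold (default 0.0005 µA) and greedily prunes peaks
  closer than a minimum peak distance (default 5 s), keeping the taller
  peak. `spike_stats()` reports the count, mean interspike interval
  ISI&#773; = mean(tᵢ₊₁ − tᵢ) and spiking frequency f = 1000 / ISI&#773; in mHz.
- **Latency temporal coding.** For a column of potentials *p* and threshold
  θ, each neuron's code is c_j = 1[p_j > θ] · (T − m), where m is the
  smallest suprathreshold potential in the column and T the coding window.
- **Hebbian co-activation learning.** Weights W ∈ [−1, 1]^(N×N), updated by
  W ← clip(W + η · b bᵀ, −1, 1) on the binarised code b = (c > 0), diagonal
  held fixed. The printed 10 × 10 initial weight matrix ships as a fixture,
  and `psi_ppi()` provides first- and second-order excitatory connectivity
  indices.
- **Network simulators.** A recurrent leaky integrate-and-fire network
  (τ_m v̇ = −v + U F_in + J s, threshold/reset, exponential synapses) and a
  continuous-variable rate network (τ ẋ = −x + J̃ φ(x) + Ũ F_in + u F_out,
  φ = tanh), both forward-Euler with a dt ≤ τ/10 guard, plus
  `drive_with_proteinoid()` to feed detected spike trains into them.
- **QSAR model.** Ordinary least squares of mean firing rate (Hz) on
  molecular weight (g/mol) and peptide length (residues), with 95%
  t-intervals, prediction with extrapolation flagging, and percent
  deviation 100 · (predicted − observed) / observed.

## Worked example

```r
library(protospike)

# a 2000 s recording at 1 Hz with a 22.24 s target mean interspike interval
spec  <- trace_spec("L-Glu:L-Asp-like", duration = 2000,
                    mean_isi = 22.24, seed = 1)
tr    <- synth_trace(spec)
train <- detect_spikes(tr)          # 0.0005 uA threshold, 5 s min distance
spike_stats(train)
#> <spike_stats> 84 spikes, mean ISI 23.29 s, 42.94 mHz
```

84 spikes were generated and all 84 recovered; the empirical mean interval
(23.29 s) fluctuates around the 22.24 s target because a 2000 s recording
holds only ~90 interspike intervals, and the frequency is its exact
reciprocal (1000/23.29 = 42.94 mHz).

```r
d <- generate_descriptor_table(100, b0 = 100, b1 = 0.5, b2 = 10,
                               noise_sd = 5, seed = 1)
fit_qsar(d$firing_rate, d)
#> <qsar_model> rate = b0 + b1 * MW + b2 * length
#>   b0 = 97.7416 Hz  [94.618, 100.865]
#>   b1 = 0.500577 Hz/(g/mol)  [0.498523, 0.502631]
#>   b2 = 10.1329 Hz/residue  [9.96042, 10.3055]
#>   R^2 = 0.9996
```

The fit recovers the generating coefficients (100, 0.5, 10) inside each 95%
confidence interval.

A command-line wrapper is installed with the package:

```sh
protospike=$(Rscript -e 'cat(system.file("exec", "protospike", package = "protospike"))')
Rscript "$protospike" detect --input trace.csv --out report.csv
Rscript "$protospike" simulate --seed 1 --out-dir out/
```

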