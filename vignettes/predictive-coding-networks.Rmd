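---
title: "Greedy predictive-coding spiking networks: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Greedy predictive-coding spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
```

```{r setup}
library(pcsnet)
```

## The model

`pcsnet` simulates a recurrent network of `N` spiking neurons that tracks a
one-dimensional signal $s(t)$ online. Two assumptions define the model:

1. **Linear decoding.** Each spike of neuron $j$ adds one copy of that
   neuron's *representing filter* $g_j$ to a reconstruction
   $\hat s(t) = \sum_j \sum_i g_j(t - t^{\mathrm{ideal}}_{ji})$.
2. **Greedy error reduction.** A spike is fired only if it reduces the
   integrated squared error $\int (s - \hat s)^2\,dt$, net of spike costs.

Because a neuron cannot place a spike in the past, each spike is decided
with a delay $\Delta$: the decision taken at time $T + \Delta$ concerns a
waveform anchored at the *ideal* time $T$. The emitted (*real*) spike train
is the ideal train shifted forward by $\Delta$. Carrying out the error
difference gives a filter network: each neuron correlates its input with an
*input filter* $g^{in}_m(t) = g_m(\Delta - t)$ on $t \in [0, \Delta]$ (the
time-flipped, delay-shifted window of its representing filter), subtracts
the already-represented signal through *lateral filters*
$g^{lat}_{mj} = -(g^{in}_m * g_j)$, and compares the resulting membrane
potential with a threshold

$$\Theta^c_m(t) = \tfrac12 \int_0^\Delta g_m(x)^2\,dx + \nu +
  \mu \sum_{\text{own spikes}} e^{-(t - t_{\mathrm{spk}})/\tau_a},$$

where $\nu$ is a linear spike cost that sparsifies the code, and $\mu$ is a
spike-triggered threshold increment decaying with $\tau_a = 60$ ms —
functionally spike-frequency adaptation, which distributes activity across
the population and damps the "ping-pong" of sign-opposite neurons firing
alternately.

For an L2-normalized filter window and $\nu = 0$ the threshold is exactly
$1/2$; the self-coupling at lag $\Delta$ is $-2(\Theta - \nu)$, an identity
the test suite asserts to machine precision.

## Filter constructions

All representing filters are built from the basis
$\Gamma_n(t) = t^n e^{-t}$ (t in ms):

* **type 1 / integrator**: $\Gamma_3(t)$ — unimodal. These cells have a
  continuous rate-vs-amplitude curve, a single-signed phase-response curve
  and a unimodal spike-triggered average.
* **type 2 / resonator**: $\Gamma_3(t)(0.2 - 0.8\sin 0.6t)$ — bimodal.
  These cells respond to transients, fire doublet pairs at high drive, and
  show bimodal within-doublet PRCs and bimodal STAs.
* **off-cells**: sign-inverted copies.
* **heterogeneous**: $\Gamma_3(t)(0.2 \pm 0.8 f(\psi t))$, $f \in \{\sin,
  \cos\}$, $\psi \sim U(0, 1.5)$ per neuron.

Populations: `"homogeneous"` (half type-1, half off), `"type1_type2"`
(quarters of the four kinds) and `"heterogeneous"` (sin/cos and ± quarters).
Filters are rescaled to a common window norm so all thresholds are equal.
Two normalization targets are exposed, because the absolute filter scale is
a genuinely open choice: the default (`"type1"`) keeps the raw $\Gamma_3$
filter unchanged (window norm² ≈ 5.58, peak amplitudes ≈ 1.3–1.9), which
matches the regime where a handful of co-active neurons reconstruct
stimulus amplitudes of order 10; `"unit"` rescales to norm² = 1, the clean
$\Theta = \tfrac12 + \nu$ case.

A sign convention worth knowing: the bimodal (type-2) filter has a
*negative* window integral, so a positive constant input excites its
sign-inverted variant. Single-neuron protocols therefore run the type-2
characterization on the inverted cell; none of the modality claims depend
on this sign.

```{r filters}
bank <- filter_bank("type1_type2", N = 8, delta = 7.5, nu = 0.5, mu = 0.5)
bank
plot(pc_kernel(bank$g[, 1], bank$dt), main = "type-1 representing filter")
```

## The simulator and its anchoring convention

`simulate_network()` advances the stimulus grid one step at a time. At each
decision step every neuron's membrane potential is the windowed inner
product of its representing filter with its residual input (its own,
possibly noise-corrupted, stimulus copy minus the reconstruction). Within a
step, suprathreshold candidates are resolved greedily: the largest-margin
neuron fires, membrane potentials are updated, and the step is re-examined
(ties break to the lowest index; a `"parallel"` mode fires all crossers at
once; one spike per neuron per bin in both modes).

A subtle but consequential choice is *where* a decided spike's waveform is
subtracted from the other neurons' view of the signal:

* `lateral_anchor = "ideal"` (default): the waveform is subtracted from its
  backdated ideal anchor. The lateral effect at the firing step itself is
  the lag-$\Delta$ value $-2(\Theta-\nu)$ — instantaneous recurrent
  inhibition. This is the literal reading of the error-difference rule, and
  it is required for symmetry breaking: in a homogeneous population all
  neurons otherwise share identical trajectories and would fire in
  synchronized volleys forever.
* `lateral_anchor = "real"`: the lateral effect unfolds from the emission
  step as a causal postsynaptic potential $-(g^{in}_m * g_j)(u)$, zero at
  $u = 0$ and peaking at $u = \Delta$. This is the physical-PSP reading.
  It removes a reconstruction bias (below) but provides no instantaneous
  competition, so symmetric populations volley.

Neither reading is free of artefacts, and the difference matters
quantitatively. Under the default (ideal) anchoring, a candidate's decision
window can never contain spikes that will later be backdated into it, so
for filters with large DC content (the pure-$\Gamma_3$ homogeneous bank)
the network systematically over-fires at high drive: for a constant input
$s$ the steady-state reconstruction approaches
$2A_1/(A_1 + G(\Delta)) \approx 1.9$ times $s$, where $A_1 = \int_0^\infty
g$ and $G(x) = \int_x^\infty g$ — a closed-form prediction the simulator
reproduces to a few percent. Bandpass filters (type-2, heterogeneous) have
little DC mass and are essentially unaffected; their networks reconstruct
filtered-noise stimuli with normalized MSE of a few percent. The package
keeps the ideal anchoring as the default because it is the
oracle-verifiable form of the greedy rule (the test suite checks every
fire/no-fire decision against a brute-force evaluation of the error
difference on randomized small networks) and documents the bias rather than
patching it; the real-anchored variant is available for study.

```{r demo}
net <- filter_bank("type1_type2", N = 100, delta = 7.5, nu = 1.5, mu = 1.5)
s <- make_stimulus("filtered_noise", amplitude = 10, duration = 1000,
                   dt = 0.1, tau = 15, seed = 1)
sim <- simulate_network(net, s)
sim
plot(sim)
```

## Stimuli and noise

Deterministic stimuli (constant, step-and-hold, sine) are exact; the
stochastic stimulus is white noise passed through a zero-phase
(forward-backward) exponential filter with autocorrelation time constant
$\tau$, mean-centred and rescaled so its sample standard deviation equals
the requested amplitude exactly. The generator draws white noise of
variance $1/\mathrm{d}t$ (grid-invariant statistics) and discards a pad of
$6\tau$ at each end so the kept stretch is stationary. "Amplitude" of a
stochastic signal always means its standard deviation; for the sine it is
the peak.

Correlated background noise is modelled with `make_noise_bank()`: a limited
number of noise copies distributed over the population (contiguous index
blocks by default, so block membership is predictable; a seeded random
assignment is available). One copy = fully shared noise, `N` copies = fully
independent. Multiple banks can be summed per neuron, which is how the
half-independent/half-shared composition of the correlation protocols is
built. Noise corrupts only the encoders; reconstruction error is always
measured against the clean stimulus.

## Metrics

* **Coincidence factor** $\Gamma$: chance-corrected co-occupancy of
  time bins (default width 2 ms; doubly occupied bins count once). It is 1
  for identical trains and is asymmetric (the second train is the rate
  reference). Note that the chance correction $2N_1N_2/K$ is the classical
  ±p-window expectation; with same-bin counting the exact chance level
  would be $N_1N_2/K$, so independent Poisson trains sit at a small
  negative value ($\approx -\nu_2 p$, about $-0.016$ at 8 Hz) rather than
  exactly zero. The formula is kept in its classical form; the test suite
  asserts the analytic offset.
* **$\bar\Gamma$** (`mean_reliability()`): $\Gamma$ per neuron across trial
  pairs (consecutive pairs; later trial as reference), averaged over
  neurons, undefined values excluded. Near 1 = reliable, non-degenerate
  code; near 0 = highly degenerate code.
* **Normalized MSE**: $\sum(s - \hat s)^2 / \sum s^2$ — 0 is perfect, 1
  equals total silence.
* **Activity** $A$: spikes per neuron per second.
* **Efficiency** $E = 1/(\overline{MSE}\cdot A)$ (s), plus
  amplitude-weighted variants $E_a = E\,a$ and $E_{a^2} = E\,a^2$.

## Characterization protocols

`fi_curves()`, `prc()` and `sta()` emulate current-clamp protocols on
single model neurons; `correlograms()` computes signal and noise
cross-correlograms from repeated trials (chance-corrected, normalized to
the pair's average total spike count); `population_rate()` and
`spike_triggered_population_activity()` quantify coupling to the
Gaussian-smoothed ($\sigma = 6$ ms) network activity. The
unimodal/bimodal classification used in tests is operationalized as the
number of sign changes of the smoothed curve ($\sigma = 1$ ms), ignoring
lobes below 20 % of the dominant lobe — threshold-crossing protocols leave
small ripples around zero that visual classification would discount. The
PRC reports the next-spike shift (positive = advanced); for doublet-firing
cells the reference interval can be the within- or between-doublet ISI.

```{r single, eval = FALSE}
t2 <- filter_bank(list(neuron_spec("off_type2")), delta = 7.5, nu = 1.5,
                  mu = 1.5)
plot(sta(t2, noise_amplitude = 1.1, duration = 30000), type = "l")
```

## Experiments

`run_experiment(experiment_config(...))` packages the full protocols:
network demos, amplitude × $\tau$ efficiency sweeps with random
start-stimuli (each trial prepends an independent 500 ms filtered-noise
segment; raster differences across trials then measure the degeneracy of
the code, not noise), noise-robustness sweeps over relative amplitude ×
number of copies, trial-based correlation analysis, population-coherence
analysis, and the single-neuron battery. All tables carry the full
parameter set and are bit-reproducible from the config seed.

Default problem sizes are desk-scale: 2.5 s sweeps, 100 neurons at
dt = 0.1 ms, tens of trials for correlation estimates; the `scale`
parameter shrinks durations and trial counts proportionally, and the grids
are arguments, so full-scale runs are a config change.

## Numerical choices

* Time step 0.1 ms by default; $\Delta$ and kernel supports must be integer
  multiples of dt. Kernels are truncated at 50 ms or where they fall below
  $10^{-6}$ of their peak.
* All integrals are sample sums × dt with both endpoint samples of
  $[0, \Delta]$ included; this convention makes the discrete coupling
  identity $-g^{out}(\Delta) = 2(\Theta - \nu)$ exact rather than off by
  one endpoint term.
* The decision loop is compiled (Rcpp); decisions start once the delay
  window fits in the record ($t \ge \Delta$), with zero initial state
  (empty reconstruction, thresholds at base, no warm-up unless a
  start-stimulus provides one). MSE is evaluated over the full main
  window with no burn-in discard.
* The reported reconstruction is the ideal-aligned estimate; residual
  traces and optional membrane/threshold traces share the stimulus grid.

## What the synthetic stimuli do and do not emulate

The filtered-noise process matches the amplitude and autocorrelation-time
statistics the network model is analysed with, and the noise banks
reproduce the shared-vs-independent corruption structure. They do not
emulate heavy-tailed amplitude distributions, non-stationarities, or
spectral structure of real sensory signals or recorded field potentials
(an external 1-D recording can be supplied as a CSV via
`read_stimulus_csv()`). Passing tests therefore demonstrate correctness of
the implementation and reproduction of the model's behaviour under its own
stimulus assumptions, not performance on natural signals.

## Known limitations

* Under the default anchoring the homogeneous (pure type-1) network
  over-reconstructs high-amplitude slowly varying inputs by the analytic
  factor above; its normalized MSE at stimulus amplitude 10 is ~0.55–0.7
  rather than below 0.2, and mixed-network activity in the correlation
  configuration runs near 17 Hz rather than 8 Hz. The heterogeneous
  network, having no redundant filters to average private noise over, also
  degrades under strong independent per-neuron noise (MSE 0.5–0.95 at
  SNR 1, depending on the drawn filter set) even though its clean
  reconstruction error is only a few percent. The real-anchored variant
  removes the gain bias but volleys in symmetric populations; no anchoring
  we examined reproduces both the homogeneous-network raster irregularity
  and unbiased high-amplitude tracking simultaneously.
* Simulation is clock-driven; there are no transmission delays other than
  $\Delta$, no plasticity, and only one stimulus dimension.
* The shared-noise "central deflection" of noise correlograms and the
  strength of the resonator population coupling are weaker here than the
  model's qualitative account suggests; both are computed, not asserted,
  at desk scale.
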