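---
title: "Model and methods: a thalamocortical spiking circuit under deep brain stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package models

`tcmdbs` simulates a six-population spiking microcircuit of the motor
thalamo-cortex in a Parkinsonism-like state and measures how different
deep-brain-stimulation (DBS) pulse patterns change two network-level
readouts: beta-band (13–30 Hz) power of a simulated cortical local field
potential (LFP), and an SVD-based index of population synchrony. The
circuit contains three excitatory cortical layers — surface (S, 100
cells), middle (M, 100) and deep (D, 100) — a shared pool of cortical
interneurons (CI, 100), the thalamic reticular nucleus (TRN, 40,
inhibitory) and the thalamocortical relay nucleus (TCR, 100, excitatory):
540 neurons in total. Setting any population size to 0 removes it from
the circuit.

## Membrane dynamics

Each neuron follows the two-variable quadratic Izhikevich model,

$$\dot v = 0.04 v^2 + 5v + 140 - u + I(t), \qquad \dot u = a(bv - u),$$

with the reset rule: when $v$ reaches $v_{peak} + \zeta(t)$
($v_{peak} = 30$ mV, $\zeta$ Gaussian threshold noise with SD 0.1 mV),
$v \leftarrow c$ and $u \leftarrow u + d$. $I(t)$ collects the bias
current, delayed synaptic input, white Gaussian membrane noise (mean 0,
SD 0.5, entering the voltage equation as a current) and, for stimulated
cells, the DBS current. A Poissonian background-input term exists in the
configuration but is disabled; the simulations neglect it.

Integration is forward Euler at `dt = 0.1` ms (configurable). This is
the standard resolution for Izhikevich networks; the test suite verifies
that the spike count of a tonically driven regular-spiking cell changes
by at most one spike per second when the step is halved or refined
tenfold, and that off-stimulation beta power moves by well under 15%
when the step is halved.

Cell categories use the canonical parameter sets (RS, IB, CH, FS, LTS,
TC, RE). Heterogeneity follows the standard network randomization with
one amendment: the excitatory perturbation of the recovery increment is
proportional, $d = d_0(1 - 0.75r^2)$ with $r \sim U(0,1)$, which equals
the canonical $d_0 - 6r^2$ at the regular-spiking base $d_0 = 8$ but
keeps $d$ positive for thalamocortical relay cells ($d_0 = 0.05$); the
literal rule makes their $d$ negative, which removes spike adaptation
entirely and drives the relay population to kilohertz firing.

## Short-term synaptic plasticity

Every neuron owns one Tsodyks–Markram channel describing its outgoing
postsynaptic current (PSC): utilization $u$ (decay $\tau_f$), resources
$x$ (recovery $\tau_d$), current $I$ (decay $\tau_s$). On a presynaptic
spike, in this order: $u^+ = u^- + U(1-u^-)$, $\Delta I = A u^+ x^-$,
$x^+ = x^- - u^+x^-$. The network core indexes PSCs by the presynaptic
neuron — postsynaptic drive is a weighted sum of presynaptic PSC traces
read at the projection delay — which is also what makes the LFP ("sum
of all deep-layer EPSCs and interneuron IPSCs") well defined. Between
spikes the states decay by exact exponentials; a forward-Euler mode
exists for comparison, and an event-driven closed-form solver
(`eventDrivenPsc`, `tmSteadyState`) serves as the oracle the stepped
integration is tested against (agreement within 1% at `dt = 0.1` ms).

Defaults are the classic cortical classes: excitatory channels are
depressing ($U = 0.5$, $\tau_f = 17$ ms, $\tau_d = 671$ ms, $\tau_s = 3$
ms, $A = +1$), inhibitory channels slower and weaker-utilization
($U = 0.25$, $\tau_f = 21$ ms, $\tau_d = 706$ ms, $\tau_s = 12$ ms,
$A = -1$). The progressive depression of the excitatory channels under
sustained high-frequency drive — synaptic suppression — is the mechanism
through which high-frequency DBS acts in this model: the steady-state
per-spike transmission is monotonically non-increasing in drive rate
(a tested invariant).

## Connectivity: a reconstruction

The per-projection coupling weights, transmission delays, and
per-population parameter tables of the original circuit are published in
prior work and not reproduced here; `defaultConnectivity()` and
`defaultPopulations()` are therefore **documented reconstructions**,
chosen once so that the intact circuit displays the Parkinsonian
baseline phenomena (a sharp LFP spectral peak inside the beta band and
recurring population-wide synchronized events) and fully overridable
through the YAML configuration. The reconstruction works as follows:

* The deep layer D and the relay nucleus TCR form a strong excitatory
  loop with 22 ms conduction delay each way; with spike initiation and
  synaptic integration the closed loop resonates at ~18 Hz, inside the
  beta band. All-to-all random weights are drawn per connection as
  $|N(\mu, 0.25\mu)|/N_{source}$, which makes the operating point
  approximately invariant to population rescaling (used for the
  half-size test circuits).
* Recurrent D→D excitation lets a partial volley recruit the layer;
  CI inhibition (driven by D and TCR) and TRN inhibition of TCR
  terminate each volley; adaptation plus depression set the recovery
  time to roughly one loop period.
* CI interneurons are tonically excitable (bias 2.2 exceeds the
  low-threshold-spiking rheobase), so the inhibitory pool is active
  throughout; the principal cells are subthreshold and noise/loop
  driven.

Simulations start every neuron at its subthreshold rest state (the
stable nullcline intersection for its bias); categories whose bias
admits no rest state start at the reset voltage. Starting at rest keeps
a drive-free noiseless circuit exactly silent, a tested contract.

## Stimulation patterns

All protocols are event-time lists with a common pulse charge $A$
(`pulseTrain`), realized on the grid only at injection time:

* `cdbs f` — conventional DBS: pulses every $1/f$ from the 6-s onset.
* `adbs` — 20 pulses at 130 Hz at onset, then tonic 95 Hz.
* `bdbs` — 20 pulses at 130 Hz at onset, then 4-pulse packs at 130 Hz
  separated by 37 ms pauses. The pause is measured from the last pulse
  of one pack to the first of the next (pack-onset period
  $3/130 + 0.037 \approx 60.1$ ms, i.e. ~16.6 packs/s), the only
  reading consistent with the ~16 Hz harmonic structure such trains
  drive; the alternative pack-onset-period reading is available via
  `pause_mode = "period"`.

The stimulation current is delivered intracellularly to a seeded random
50% of the deep layer. Each pulse is realized as a rectangular current
of width 0.3 ms (a clinically typical pulse duration) whose time
integral equals the pulse charge. The width matters: a one-grid-step
impulse makes every supra-threshold amplitude act identically
(jump–spike–reset), so scaling the intensity five-fold would change
nothing. With a finite width, a strong pulse re-depolarizes the cell
after its first spike within the same pulse, producing intra-pulse
doublets/triplets at ×5 intensity — deeper synaptic depression and the
graded intensity effects the protocol comparisons rely on. The literal
one-step realization remains available (`pulse_width_ms = dt`).

Because the baseline pulse charge is not a published quantity,
`calibrateAmplitude()` defines the working intensity operationally: the
smallest amplitude (bisection to 1%) at which at least 95% of the
directly stimulated deep-layer cells fire at least once per pulse over a
1-s 130 Hz test train, evaluated in the embedded, noisy network. For
the default circuit this lands near 77 charge units (≈ 77 mV of
depolarization per pulse).

## LFP and spectra

The cortical LFP is the first-order point-source estimate
$\mathrm{LFP}(t) = \left[\sum_{i \in D} \mathrm{PSC}_i(t) + \sum_{i \in CI}
\mathrm{PSC}_i(t)\right] / (4\pi\sigma r)$ with $\sigma = 0.27$ S/m and
$r = 100\ \mu$m. Spectra are Welch averages over Hann-tapered segments
(1-s windows, 50% overlap by default; no pre-installed R package
provides a Welch estimator, so `computePsd` implements the averaged
periodogram directly on `stats::fft`, normalized so the integrated
density recovers the signal variance — both properties are tested
against closed forms). Beta power is the trapezoidal integral over
13–30 Hz; attenuation is off-window power minus on-window power
(positive = suppression). The off/on windows are exactly the first and
last 6 s of each 12-s run, with the stimulation switched on at 6 s; no
transient is trimmed (trimming is available but off by default).
Harmonic combs (e.g. the 20/40 Hz peaks under 20 Hz stimulation) are
detected as local PSD maxima within ±2 Hz of each multiple whose
power exceeds twice the local median background; without the prominence
floor the "local maximum" rule fires on most featureless noise spectra.

## Synchrony

`covarianceComplexity` forms the $P \times N$ samples-by-neurons matrix
(default: the binary spike raster binned at 1 ms; membrane-voltage mode
is also supported and is recorded cheaply at a 1-ms stride), centers
each column, and by default also scales each column to unit variance
before the SVD. The variance fractions
$\sigma_i = \lambda_i^2/\sum\lambda_j^2$ feed the normalized spectral
entropy $C$, and the synchrony index is $M = 1 - C$. The
unit-variance scaling is a deliberate choice: without it the index
measures variance concentration rather than co-fluctuation, and the
handful of tonically entrained stimulated cells (per-bin variance an
order of magnitude above the rest) masquerades as *increased* network
synchrony under 130 Hz stimulation. Standardization leaves every exact
anchor unchanged (identical columns give $M = 1$; orthogonal equal-norm
columns give $C = 1$; independent Poisson activity gives $M \to 0$) and
the plain centered variant is available via `scale = FALSE`. Silent
columns are dropped (with the count reported); natural logarithms are
used, and $C$ is base-invariant through the $1/\log N$ normalization.
The metric is only accurate for $P \gg N$; a warning is issued below
$P/N = 10$.

## The experiment battery

`runProtocol` runs a named protocol `repetitions` times (seed = base +
repetition index), computing per run the off/on beta powers, their
difference, and $M$ for both windows. `compareConditions` summarizes the
batteries and runs Welch two-sample t-tests of each protocol's
attenuation against the unstimulated condition (and of on-window $M$
against off-window $M$), reporting raw p-values with two significance
flaggings side by side — `*`/`**` at 0.05/0.01 and at 0.01/0.001 —
because both conventions appear in the comparisons this battery
reproduces; neither flagging is asserted by tests. The reference
experiment uses 100 repetitions; the test suite and examples run 10
repetitions on the half-size (270-neuron) circuit, a desk-scale choice
that preserves the operating point because weights are normalized by
source-population size.

# What the defaults reproduce, and what they do not

With the default reconstruction, across seeds:

* the unstimulated circuit shows a beta-band spectral peak (~18 Hz) and
  synchronized population events; a weight-shuffled, delay-flattened
  control concentrates far less of its power in beta;
* 130 Hz conventional DBS strongly attenuates beta and lowers the
  synchrony index; 20 Hz conventional DBS attenuates far less and
  imprints a 20/40 Hz harmonic comb on the on-period LFP;
* the burst-then-tonic pattern attenuates beta like 130 Hz DBS;
* five-fold intensity deepens the burst-pack pattern's attenuation
  (median ordering).

One reference phenomenon is **not** reproduced: at base intensity the
burst-pack pattern should leave beta statistically unchanged (its
~16.6 Hz pack rhythm pumping in-band power that offsets the synaptic
suppression), but in this reconstruction its attenuation remains
positive at roughly two thirds of the 130 Hz level. The gap survived a
broad search over loop gains, delays, synaptic time constants, pulse
widths and amplitudes; reproducing the null presumably requires the
original (unpublished here) weight and delay tables. The corresponding
acceptance test asserts the reference behavior and fails honestly.

Two further caveats. The first seconds of every run carry a mild
transient (synaptic resources start full), so the null protocol's
off-minus-on attenuation is slightly positive rather than exactly zero;
the 12-s protocol windows make this small against every stimulation
effect. And the synthetic fixtures (`makeRasterFixture`,
`makeSignalFixture`) exercise the metrics' edge cases exactly but are
not statistically realistic Parkinsonian surrogates — passing metric
tests says nothing about real LFP recordings.
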