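---
title: "The laminar cortex model in lcmr: equations, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The laminar cortex model in lcmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`lcmr` simulates a sheet of cortical columns, each containing one
mean-field unit per neuron type ("neuron group": all neurons of one type
in one column, lumped into a single membrane potential and a single output
rate). The cortex is laminar (layers I, II/III, IV, V, VI) and coupled to
a thalamic sheet (relay and inhibitory groups) through a conduction loop,
so thalamocortical latency is explicit. External drive enters as
spike-rate noise: asynchronous cortico-cortical background per column and
one synchronous sensory series into the thalamic relay.

Each 0.5 ms step advances five processes:

1. **Firing.** A group at membrane potential $V$ emits
   $F(V) = F^{max} / (1 + e^{-k (V - V^{HMF})})$ (AP/sec), a sigmoid with
   firing gain $k$ (1/mV) and half-maximum voltage $V^{HMF}$.
2. **Conduction.** Rates propagate unchanged and arrive after
   $s^{axon}/v^{AP}$ ($v^{AP}$ = 1 m/s), rounded to whole steps. Axon
   length combines the horizontal centre offset and the laminar depth
   difference in quadrature; cortex-thalamus links use a configured
   effective path length (10 mm by default, i.e. 10 ms latency).
3. **Synaptic transmission.** An afferent rate $\varphi_p$ through
   $N_{qp}$ synapses of one receptor generates a postsynaptic potential of
   amplitude
   $-\,g\,N_{qp}\,(V_q - V^{rev})\,\varphi_p e^{-\lambda \varphi_p}$, with
   $g$ the synaptic gain in uV/(mV·Hz) ($g_E$ for AMPA+NMDA, $g_I$ for
   GABA; converted to mV per mV·(AP/sec) internally, factor $10^{-3}$),
   $V^{rev}$ the reversal potential (0 mV excitatory, $-70$ mV GABA) and
   $\lambda$ a spike-adaptation constant making the drive maximal at rate
   $1/\lambda$. $V_q$ is the postsynaptic potential at the **current**
   step; the model equations do not fix this and the current-step choice
   is causal and consistent with an instantaneous synaptic-efficiency
   curve.
4. **Kernel convolution and aggregation.** Each receptor spreads its PSP
   in time with a normalised bi-exponential kernel
   $R(t) = A\,e^{-(t-\tau_0)/\tau_f}\,[1 - e^{-(t-\tau_0)/\tau_r}]\,
   H(t-\tau_0)$, $A = (\tau_f+\tau_r)/\tau_f^2$; the membrane change is
   the sum over presynaptic groups and receptors of kernel-convolved PSP
   contributions, each scaled by the dendritic attenuation
   $e^{-s^{dend}/\lambda^{PSP}}$.
5. **Membrane update.** The potential relative to rest relaxes as a leaky
   integrator. Treating the step's aggregate PSP $\Delta V$ as a constant
   injected current over the interval and integrating the membrane ODE
   exactly gives
   $u \leftarrow u\,e^{-\Delta t/\tau_m} +
   \Delta V\,\frac{\tau_m}{\Delta t}\bigl(1 - e^{-\Delta t/\tau_m}\bigr)$.
   The correction factor (0.975 at $\tau_m$ = 10 ms, $\Delta t$ = 0.5 ms)
   is the exponential-integrator form of the usual iteration equation;
   without it the discrete map carries a systematic
   $\Delta t/2\tau_m$ excess gain that a finer integration of the same
   equations does not reproduce, which is visible in the reference-oracle
   tests. With it, the engine agrees with a brute-force $\Delta t/10$
   integration to well under 2% RMS.

$\Delta t$ = 0.5 ms is a model constant, not a tunable discretization:
synaptic drive is injected per step, and all printed parameter values
assume it.

## Connectivity

The connection map is group-to-group: $N_{qp}$ synapses per postsynaptic
neuron, with a receptor mix (excitatory synapses split 50/50 between AMPA
and NMDA by default; configurable). Presynaptic neurons are spread over
columns with a planar Gaussian of sd $\sigma^{synp}$ (80 um for pyramidal
presynaptic groups, 40 um otherwise), truncated at $3\sigma$ and
renormalised over the columns actually present, so $N_{qp}$ is conserved
exactly on the open-boundary sheet (edges are nuisance; the analyses read
only central columns). Each (rule, postsynaptic column) pair draws one
wiring factor $X \sim \mathcal{N}(1, 0.2)$, truncated below at 0.2 to
exclude non-physical negative synapse counts (the truncation affects
$< 10^{-4}$ of draws). External-source rules (the noise afferents) connect
within-column with $X = 1$: they are stimulus realizations, not wired
populations. Delay rounding is to the nearest step; all of these choices
are recorded in the table metadata.

## Engine numerics

The kernel convolution is evaluated through the kernel's exact recursive
form: the discrete bi-exponential is a difference of two geometric decays,
so two leaky accumulators per (unit, receptor) realise the convolution in
O(1) per step with no truncation horizon. The discrete kernel is
normalised so its infinite sum times $\Delta t$ is exactly 1 (unit DC
gain); the sampled, truncated kernel returned by `receptor_kernel()` is
the reference form used in tests. Per-step cost is dominated by one sparse
matrix-vector product per (receptor, delay) over all units.

Simulations start at rest ($u = 0$), with rate histories pre-filled with
the resting rates and the kernel accumulators at their matching steady
state, so a zero-gain network is exactly stationary from the first step.
The warmup (10 s at study scale) is discarded; the recording window
(5.12 s, 10240 samples) is analysed.

At strong gain products (roughly $g_E \gtrsim 0.5$ together with
$g_I \gtrsim 3$ on the built-in fixtures) the delayed
excitatory-inhibitory loop can produce a divergent oscillation: PSP
amplitudes grow linearly with the driving force while rates saturate, and
the discrete map has no restoring term at extreme potentials. The engine
detects non-finite potentials and aborts with the step and group; sweep
drivers record the abort as a cell status instead of failing the sweep.
This is a property of the parameter regime, not of the integration step,
and the phase-diagram protocols operate inside the stable range.

## Stimuli

External inputs are Monte-Carlo rate series: Gaussian white noise,
low-pass filtered with a second-order Butterworth applied
forward-backward (zero phase), scaled to an sd of half the target mean,
shifted to the mean, clipped at zero and rescaled so the realized mean is
exact. The reference conditions are 1 AP/sec with a 20 Hz cutoff
(cortico-cortical background, independent per column, and non-stimulated
thalamic input, shared across columns) and 50 AP/sec with a 50 Hz cutoff
(stimulated thalamic input). Any monotone low-pass at the stated cutoff
would satisfy the contract; the filter and the sd convention are fixed
here for reproducibility. Paired stimulated/non-stimulated runs share the
cortico-cortical noise seed so their difference isolates the thalamic
condition.

## Analyses

Column excitation is the unweighted mean rate of the column's cortical
excitatory groups (thalamic groups belong to the thalamic sheet, not the
column). From it:

* **MFR** — temporal mean weighted by a Tukey (tapered cosine) window,
  taper fraction 0.25, weights normalised to 1. The taper suppresses edge
  effects of oscillatory series; a constant series is returned exactly.
* **PSD** — Welch's method: ten equal segments at 50% overlap (segment
  length $\lfloor 2N/11 \rfloor$), per-segment mean removal, Hamming
  window, one-sided density scaling. Band means over 2-15 Hz (low) and
  16-50 Hz (high) use bins whose centres fall inside the band; note a
  record must be long enough for the first non-zero bin to reach 2 Hz
  (the full 5.12 s window gives a 1.07 Hz resolution).
* **MSC** — mean magnitude-squared coherence over all unordered pairs of
  the central 10x10 block (all columns, with a note, on smaller sheets),
  with the same Welch segmentation and segment-averaged cross- and
  auto-spectra. The denominator is the symmetric
  $PSD(F_i)\,PSD(F_j)$, which keeps the estimate in $[0, 1]$; the
  asymmetric $PSD(F_i)^2$ variant is available
  (`corrected = FALSE`) for comparison, and is unbounded.
* MFR and PSD are read from the sheet's single geometric centre column
  (0-based index $\lfloor (n-1)/2 \rfloor$ per axis, so columns 5..14 form
  the central block of a 20-column axis).

The critical boundary is located operationally: bisection on
MFR$(g_E) > 5$ AP/sec (midway between the quiescent $<0.4$ and active
$>10$ regimes) at fixed wiring and noise, to a bracket of 0.003
uV/(mV·Hz), the finest gain interval the protocols distinguish. The
boundary line is ordinary least squares of the critical $g_E$ on $g_I$;
the algebraically inverted coefficients $(1/\text{slope},
-\text{intercept}/\text{slope})$ are reported alongside, because boundary
statements on the other axis are conventionally printed with the opposite
intercept sign and the fit does not resolve that sign. Quasi-static
hysteresis sweeps hold each gain plateau for 2 s (the transient-protocol
window length) without re-initialising, and warm up on the first
plateau's gain so each branch starts on its own attractor.

## The built-in fixtures and their provenance

Three self-consistent configurations ship with the package: `tiny`
(1 column, one excitatory + one inhibitory group, single receptor each;
the oracle workhorse), `small` (4x4 columns, cortical pyramidal +
interneuron and thalamic relay + reticular groups; the desk-scale
phase-diagram fixture) and `paper` (the full-scale reference
configuration: 20x20 columns of 56 um, 11 cortical + 3 thalamic groups).
Parameters with published reference values — geometry, step, propagation
speed, reversal potentials, spatial spreads, noise conditions, the
inhibitory $F^{max}$ = 200 AP/sec and $V^{HMF} = -45$ mV scan origins —
are used as-is and flagged `provenance = "published"`. The remaining
physiology, receptor kinetics and the quantitative synapse-count map are
not published at that level of detail; those entries are this package's
own choices, flagged `"fixture-assumed"`, and were designed rather than
fit:

* Excitatory groups use a steeper, lower-threshold sigmoid
  ($k$ = 0.5 /mV, $V^{HMF} = -50$ mV) than inhibitory groups
  ($k$ = 0.34 /mV, $V^{HMF} = -45$ mV). If both polarities share one
  sigmoid, interneuron recruitment tracks pyramidal recruitment
  proportionally and the low-activity branch deforms smoothly instead of
  ending in a fold; pyramidal recruitment must lead for a discontinuous
  jump. At rest an excitatory group fires ~0.11 AP/sec, keeping the
  quiescent region below 0.4 AP/sec.
* Synapse counts are *effective* counts of order 2-20, not anatomical
  thousands: with the lumped gain scale (uV per mV·Hz per synapse), the
  membrane amplification $\tau_m/\Delta t$ and no synaptic depression,
  the recurrent loop gain is proportional to $g_E N^{eff}$, and the fold
  must fall inside the printed gain range ($g_E$ of roughly 0.3-0.5
  uV/(mV·Hz)). Counts were placed by Newton continuation of the
  two-group mean-field fixed point with the discrete-map stability
  condition, targeting a fold line inside that range with a positive,
  shallow slope in $g_I$, and then frozen.
* Thalamocortical weights are small (under 1 effective synapse): the
  stimulated relay condition must be able to tip the cortex only near
  criticality, which bounds the drive it may inject far from the
  boundary.

What the fixture reproduces: the sharp first-order jump in mean rate
along $g_E$ (quiescent $\le 0.4$ AP/sec to active $\ge 10$ AP/sec), a
near-linear critical boundary with positive slope in $g_I$, wide
bistability with hysteresis under transient or quasi-static gain changes,
stimulus sensitivity sharply peaked at the boundary, and tipping of a
near-critical network by small inhibitory impairments (a 20 AP/sec drop
in inhibitory $F^{max}$, or a +2 mV threshold shift). What it does not
reproduce: absolute boundary coefficients and Region-2 rate magnitudes of any
particular cortical parameterisation (those depend on the detailed
synapse tables), and strong
Region-2 rhythmicity — with only one cortical E-I pair the active state
sits near rate saturation where oscillation amplitudes are small, whereas
the laminar cascade of the full model sustains mid-sigmoid oscillatory
states. Passing the suite therefore demonstrates the dynamical structure
of the model class, not quantitative agreement with any particular
cortical dataset.

## Problem sizes and seeds

The test suite and the acceptance script run at desk scale by choice: the
4x4 fixture, 3 s warmup and 1.5 s evaluation windows for rate probes, and
the full 10 s + 5.12 s protocol for the spectral cells; the 20x20
configuration is exercised with a short smoke run. A single master seed
expands deterministically (31-bit string hash, `derive_seed()`) into
wiring, per-stimulus, per-column and per-replicate seeds; replicate error
bars rebuild both wiring and noise, matching the convention of repeated
runs with different random kernels. The boundary location shifts by about
±0.02 uV/(mV·Hz) across wiring draws, so protocols that compare against a
measured boundary pin the wiring by passing the prebuilt connectivity.

## Known limitations

Mean-field groups carry no spike correlations, no short-term plasticity
(gain changes are protocol-imposed), and no ion-concentration dynamics;
seizure-like transitions here are gain-driven attractor switches. The
divergent-oscillation regime at strong gain products is reported, not
integrated through. LFP synthesis and structured visual stimulation are
out of scope.
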