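---
title: "A conductance-based model of theta-nested gamma in medial entorhinal cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A conductance-based model of theta-nested gamma in medial entorhinal cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Layer II/III of the medial entorhinal cortex (mEC) produces gamma
oscillations (40–140 Hz) nested within theta (4–12 Hz) drive. Two
canonical circuit mechanisms can generate such rhythms: interneuron
network gamma (ING), in which mutually inhibitory fast-spiking
parvalbumin-positive (PV+) interneurons synchronize among themselves, and
pyramidal–interneuron network gamma (PING), in which volleys of
excitatory-cell firing pace the interneurons. `mecgamma` implements a
spiking network model of this circuit — 100 fast-spiking interneurons (the
I population) and 400 stellate cells (the E population) under simulated
8 Hz optogenetic conductance drive — together with the analysis pipeline
used on slice voltage-clamp recordings, so that the transition between the
two regimes can be mapped as a function of the excitatory-to-inhibitory
(E→I) synaptic conductance.

The experimental observables the model reproduces are inhibitory
post-synaptic currents recorded in voltage-clamped cells during theta
drive. The model mirrors this with *readout cells*: five extra,
non-projecting observer cells per population, wired with the same afferent
rules as their population and held at 0 mV. Their clamp current
`sum(g_syn (V_hold − E_rev))` is the model's analog of an IPSC recording.
Because readouts emit no spikes and no synaptic output, removing one
changes nothing else in the network (a property the test suite checks).

## Cell models

Both cell types are single-compartment conductance-based models with
absolute conductances (nS) and capacitance (pF); voltages in mV, time in
ms, currents in pA.

**Fast-spiking interneuron.** The Wang–Buzsáki fast-spiking formalism:
transient sodium with instantaneous activation (`m = m_inf(V)`),
inactivation `h`, delayed-rectifier `n`, leak, and a gating rate factor
`phi = 5` that lets the cell fire tonically well above 150 Hz without
adaptation. Defaults (`fs_params()`): `C_m` 100 pF, `g_Na` 3500 nS,
`g_K` 900 nS, `g_L` 10 nS, `E_Na` 55, `E_K` −90, `E_L` −65 mV. Under a
sustained 7 nS excitatory conductance (the crest of the theta drive) the
default cell fires at ~160 Hz indefinitely — the defining behavior for
this population, which must keep firing when synaptic excitation is
removed.

**Stellate cell.** A Hodgkin–Huxley-type spiking core augmented with a
persistent sodium conductance (`g_NaP`, instantaneous activation) and a
two-component hyperpolarization-activated H conductance (fast and slow
gates with voltage-dependent time constants of tens to hundreds of ms,
reversal −20 mV). The restorative H current paired with the amplifying
persistent sodium gives the cell subthreshold resonance in the theta
band; `impedance_profile()` on the default cell shows a resonance peak
near 8 Hz (band 4–12 Hz), and zeroing `g_NaP`, `g_Hf`, `g_Hs` recovers a
non-resonant low-pass cell. The exact calibrated conductance values for
both cell types are not uniquely determined by the behaviors we target;
the defaults here were calibrated once, at design time, against the
qualitative contracts of the study — stellate resting potential a few mV
below threshold (≈ −53 mV with H active), one to two spikes per theta
cycle under a 3 nS drive alone, theta-band resonance, fast-spiking tonic
firing under 7 nS — and are exposed in full through `fs_params()` /
`stellate_params()` so that other calibrations can be dropped in.

**Heterogeneity.** Each maximal conductance of each cell is jittered
independently, `Normal(base, cv · base)` truncated at zero
(`jitter_population()`), with `cv = 0.1` by default for both populations.

## Network

Connectivity is Bernoulli-random per ordered pair (`sample_connectivity()`):
E→I with probability 0.4, I→E 0.3, I→I 0.3 (no autapses). Stellate cells
are never connected with each other — E→E connections do not exist in
this circuit. I→E peak conductances are lognormal (median 1 nS,
`sdlog = 0.5`); E→I and I→I conductances are uniform per class. The I→I
probability and weight, and the lognormal parameters, live in cited prior
calibrations rather than in the study this package models, so they are
documented defaults here (`connectivity_config()`), chosen together with
the cell calibration to put the interneuron network rhythm in the fast
gamma band.

Synapses (`default_synapses()`): I→E GABA-A, bi-exponential 0.4 ms rise /
6 ms decay, `E_GABA = −65 mV`; E→I AMPA, single-exponential 1 ms decay,
`E_AMPA = 0 mV`; I→I GABA-A with fast perisomatic kinetics (0.4 / 3 ms,
unitary 0.25 nS) and hyperpolarizing reversal −75 mV by default. The I→I reversal is the
experiment's key variable: `assemble_network(egaba_ii = ...)` accepts
−75 (hyperpolarizing), −55 (shunting), or `"distributed"`, which draws one
value per postsynaptic interneuron uniformly on [−75, −55] mV — we treat
the chloride reversal as a property of the cell rather than of the
synapse. Bi-exponential conductances are normalized so one presynaptic
spike peaks at exactly the edge weight.

The **E→I conductance axis**: the swept value is the per-edge (unitary)
AMPA peak conductance, `connectivity_config(g_ei_semantics = "per_edge")`.
The alternative per-target-total parameterization is also implemented
(`"total"`, and `class_conductance_summary()` reports both views of any
network), but only the per-edge reading reproduces the regime transition:
with ~160 E afferents per interneuron, a *total* of 3.6–18 nS spreads
into per-event conductances of ~0.02–0.11 nS that can never rival the
7 nS drive, whereas unitary conductances of several nS let a synchronous
stellate volley recruit an interneuron population spike — the PING
trigger.

**Theta drive.** The optogenetic stimulus is a non-negative raised-cosine
conductance, `g(t) = (g_peak/2)(1 − cos 2π f t)` with `f = 8 Hz`,
reversal 0 mV, peaking at 7 nS on interneurons and 3 nS on stellate
cells: the unique non-negative sinusoid with the stated peak and zero
trough. Each spiking interneuron additionally receives an independent
Ornstein–Uhlenbeck conductance noise (`make_drive_noise()`,
`sd = 0.35 nS` = 5% of the I peak, `tau = 1 ms`, total drive clipped at
zero), whose purpose is to prevent the common drive alone from
synchronizing the population; an unconnected I population under the noisy
drive shows no gamma-band population synchrony (tested).

**Delays.** Synaptic delays are configurable per class
(`synapse_spec(delay = ...)`). The default assigns 2 ms to E→I
(axonal conduction plus synaptic latency for the excitatory pathway) and
0 to the perisomatic inhibitory classes, whose sub-millisecond latency is
absorbed into the 0.4 ms conductance rise. The E→I delay matters for the
regime transition: it sets when a stellate volley lands relative to the
interneuron population's own firing, and 2 ms places the weak-coupling
rhythm near the experimentally observed ~125 Hz.

## Numerics

Fixed-step integration with `dt = 0.025 ms`: exponential Euler for every
gating variable (exact for the locally linearized gating ODE,
unconditionally stable) and a forward-Euler voltage update. Spikes are
registered at upward 0 mV crossings with a 2 ms refractory; the
postsynaptic conductance kernel starts at the spike time plus the edge
delay. Halving `dt` moves burst-onset spike times by well under 0.5 ms
and the deviation shrinks linearly with the step (tested); over longer
horizons the O(dt) firing-rate bias of any fixed-step scheme
accumulates as phase drift in tonically fast-firing cells, which is why
the package's claims rest on population rhythms rather than absolute
spike times. The engine aborts with a diagnostic if any |V| exceeds
200 mV. The test suite cross-checks the compiled integrator against an
independent RK4 integration of the same equations: subthreshold
trajectories agree to < 0.1 mV over a second, and f–I spike counts to
±1 spike.

Readout (clamp) currents are recorded at 2 kHz (`record_dt = 0.5 ms`),
comfortably above the 50–200 Hz analysis band.

## Analysis pipeline

Every current trace passes through the same chain as the experimental
recordings (`analyze_trace()`):

1. zero-phase 4th-order Butterworth band-pass, 50–200 Hz, applied
   forward and reverse (`zero_phase_bandpass()`);
2. analytic Morlet continuous wavelet transform, center parameter
   `omega0 = 6`, 32 scales per octave on a geometric grid from 40 to
   250 Hz (`morlet_cwt()`; the printed unit of `omega0` in the source
   material is a typo — it is the standard dimensionless Morlet
   parameter). The CWT is computed over the whole trace and then
   segmented into theta cycles; transforming 125 ms cycles separately
   would be dominated by edge effects at 50 Hz, where the wavelet spans
   most of a cycle. Coefficients are normalized so a unit-amplitude
   sinusoid has unit power (`|W|^2`, units pA²), making power quadratic
   in the input (tested against a brute-force direct-convolution CWT to
   within 1%);
3. per-cycle segmentation: the first theta cycle is discarded (startup
   transient), any cycle whose raw current exceeds 3000 pA is discarded
   as artifactual, and power is averaged over the retained cycles
   (`cycle_scalograms()`);
4. peak extraction (`peak_gamma()`): global maximum of the cycle-averaged
   power within 50–200 Hz; SNR = peak power / mean power over the whole
   computed scalogram (the averaging domain is not pinned down by the
   source description; the full scalogram is the least arbitrary choice);
   bandwidth = full width at half maximum along frequency through the
   peak's time bin;
5. quality exclusions (`apply_exclusions()`): drop if power < 20 pA²
   (Thy1 mode; 10 in PV mode), bandwidth > 100 Hz (110 in PV mode), or
   SNR < 5.

Spike-train analysis mirrors the voltage-recording procedures:
`phase_histogram()` (30 bins of width π/15 over the theta period, counts
normalized per cycle; phase 0 is the drive trough, i.e. zero conductance),
`isi_rate_histogram()` (instantaneous rate 1/ISI in left-closed 10 Hz
bins), and `spikes_per_cycle()` (mean ± SEM across cycles). Cycle
windows are `[k/f, (k+1)/f)` with cycle 0 discarded, matching the
scalogram convention.

## Synthetic ground truth

`make_theta_nested_gamma()` generates
`A · env_theta(t) · sin(2π f_gamma t) + noise (+ artifacts)` with a
raised-cosine theta envelope, and `make_phase_locked_spikes()` generates
spike trains with known per-cycle count distributions and phase
densities. Every fixture carries its generating parameters, and analysis
tests assert *recovery* of those parameters (median frequency error ≤ one
scale step across 100 random gamma frequencies in 60–150 Hz), never
regeneration. The fixtures emulate the statistical structure of clamp
recordings — theta-gated band-limited bursts plus noise and rare large
artifacts — but not their biophysics (no synaptic kinetics, no 1/f
background by default; a pink-noise option exists). Passing recovery
tests therefore validates the analysis code, not the realism of the
network model; the network-level claims are tested separately on
simulated traces.

## The in-silico experiments

`run_ei_sweep()` maps the regime transition: for each per-edge E→I
conductance and each wiring seed it rebuilds the network, runs it, and
summarizes the E-readout scalogram. At weak coupling (≈ 3.6 nS) the
interneuron network synchronizes among itself at ~120–140 Hz (ING);
removing E→I entirely (`simulate_ampa_block()`, the in-silico DNQX)
leaves the frequency in the same fast band, the signature of an
interneuron-generated rhythm. As the unitary conductance grows past
roughly 10–12 nS, stellate volleys begin to recruit interneuron
population spikes whose after-inhibition reorganizes the rhythm into a
slower (~60–80 Hz) excitation-gated pattern; which side of the boundary a
particular network falls on depends on its wiring seed — near the
transition both outcomes occur, exactly as in seed-replicated sweeps of
the original model. `classify_regime()` labels summaries ING- versus
PING-dominant with a 90 Hz threshold, the midpoint of the gap between the
two printed bands; a peak exactly at threshold counts as ING-dominant.

`run_egaba_variants()` repeats the paired control/blocked experiment at
very strong coupling (120 nS) for the three I→I reversal variants. With
hyperpolarizing inhibition the blocked network reverts to a fast
(≥ 100 Hz) interneuron rhythm. A caveat this package is explicit about:
in the Wang–Buzsáki realization of the fast-spiking cell, the
interneuron network still synchronizes under shunting (−55 mV) I→I
reversal — spike-level synchrony weakens (population vector strength
drops from ≈ 0.39 to ≈ 0.23) but the scalogram SNR stays above 5 at
every noise, heterogeneity and coupling level we probed. Whether
shunting abolishes the interneuron rhythm outright depends on the phase
response of the specific calibrated PV-cell model, which is not
determined by the behaviors this package targets; the SNR statistic is
also permissive for theta-gated signals, because the quiet trough bins
deflate the scalogram mean against which the peak is compared.

`estimate_physiological_gei()` implements the conductance-estimation
recipe applied to fast-spiking cells clamped at −70 mV: band-pass the
excitatory current, take the per-cycle gamma peak-to-peak amplitude, and
divide by the 70 mV driving force to express it as a conductance range.

## Problem sizes and determinism

Full-scale runs use 41 theta cycles (1 discarded + 40 analyzed,
5125 ms); the package's tests and the acceptance script use the
desk-scale convention of 11 cycles (1 + 10, 1375 ms), which keeps a
single 510-cell run at a few seconds of compute while the cycle-averaged
scalogram is already stable. Near-transition conductances remain
genuinely bistable across wiring seeds at either scale — that
seed-dependence is a finding, not noise, and the sweep reports medians
and per-seed values rather than pretending to a single number. Every
random choice (wiring, weights, heterogeneity, drive noise) flows from
explicit integer seeds; rerunning any experiment with the same seed list
reproduces its output exactly, and paired control/blocked runs share the
identical wiring and noise realization by construction.

## Known limitations

* The pyramidal-cell population of layer II/III is intentionally absent;
  the E population models stellate cells only, and no E→E coupling
  exists. Gap junctions and SST+ interneurons are likewise out of scope.
* Exact calibrated parameters of the original cell models live in prior
  work and were not printed in the study; this package's defaults are a
  documented re-calibration against the study's stated behaviors, not a
  copy. Quantities that depend on fine calibration (exact transition
  conductance, exact slow-band frequency) should be read with that in
  mind.
* The readout current is one cell's view of the network; per-readout
  variation is real and the experiment drivers expose all five E
  readouts.
* Desk-scale (10-cycle) scalograms have coarser cycle statistics than
  the 40-cycle convention; tests use tolerances sized accordingly.
* In this calibration the paired AMPA-block comparisons preserve the
  frequency structure faithfully, but the *power* contrast is muted:
  the reorganized slow state and the pure interneuron rhythm have peak
  powers of similar magnitude, so blocking excitation lowers power for
  some wirings and raises it for others, rather than producing the
  large reduction a strongly excitation-dominated network would show.
* The regime boundary is a band, not a point: slow-dominant wirings are
  absent at 3.6–6 nS, rare at 8–10 nS, and the majority from about
  12–14 nS upward. Near-boundary conductances are genuinely bistable
  across seeds.
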