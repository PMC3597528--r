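---
title: "A compartmental model of directional dendritic summation in retinal ganglion cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compartmental model of directional dendritic summation in retinal ganglion cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgcds)
```

## The scientific question

On-type retinal ganglion cells receive excitatory input from many bipolar
cells distributed over their dendritic trees. When several inputs along one
dendrite are activated in sequence — as happens when an object moves across
the retina — the summed somatic EPSP depends on the activation *order*:
sequences moving away from the soma (centrifugal) sum supralinearly, while
sequences moving toward the soma (centripetal) sum roughly linearly. This
centrifugal preference is the opposite of the classic cable-theoretic
expectation and of what cortical pyramidal cells do, and it depends on
HCN (hyperpolarization-activated cyclic nucleotide-gated) channels acting
together with subthreshold Na and delayed-rectifier K conductances.

`rgcds` implements a compartmental model of this phenomenon: a soma plus
unbranched dendrite (or an SWC-derived tree) populated with HCN, Na and
Kdr channels in per-region densities, driven by an uncaging-surrogate
synapse chain, integrated with an implicit cable solver, and analyzed with
the field's standard statistics — summation ratios, directional-selectivity
(DS) percentages, EPSP kinetics, spike probability and tail-current I–V
curves.

## The model

### Geometry

The standard cell is a 20 µm spherical soma plus a single 400 µm dendrite
of 0.6 µm diameter. Compartment lengths are capped at 0.1 of the local
space constant $\lambda = \sqrt{d\,R_m/(4 R_i)}$ (≈ 458 µm here), the
usual accuracy criterion for compartmental models. Path distance from the
soma — not Euclidean distance — is the coordinate for all spatial logic,
because electrotonic spread follows the cable. Dendritic positions are
labelled proximal (≤ 50 µm), middle, or distal (> 100 µm), matching the
experimental binning, and each region can carry its own channel densities.

A 400 µm dendrite makes the distal tree roughly 0.9 λ from the soma, which
produces the *partial* electrotonic isolation the directional mechanism
requires: distal sites have high local input resistance (large local
EPSPs) yet still transfer voltage to the soma. Much shorter or much
thicker cables attenuate the effect; very thin cables (< 0.3 µm) isolate
the distal dendrite so strongly that its local DS no longer reaches the
soma.

### Passive properties and channel densities

The standard parameter set (bundled as `inst/extdata/table1_std.yaml`)
uses $R_m = 28000\,\Omega\,\mathrm{cm}^2$, $R_i = 200\,\Omega\,\mathrm{cm}$,
$C_m = 1\,\mu\mathrm{F/cm}^2$ (the universal default) and a leak reversal
of −68 mV. Densities in mS/cm²:

| channel | soma | proximal | dendrite | distal |
|---------|------|----------|----------|--------|
| Na      | 5    | 20       | 20       | 20     |
| Kdr     | 2    | 5        | 5        | 5      |
| HCN     | 0    | 0.0005   | 0.001    | 0.005  |

The HCN gradient (10× denser distally than proximally, none at the soma)
is essential: it depolarizes the distal dendrite locally while barely
moving the somatic resting potential. An equal-total-conductance *uniform*
HCN distribution shifts the somatic rest more — one of the package's
property tests.

### Channel kinetics

**HCN.** A two-state (closed/open) gate with Boltzmann-sigmoid opening and
closing rates (base half-activation −82 mV, slope 5 mV, maximum rate
0.01 ms⁻¹, so τ ≈ 110 ms near rest — HCN1-like, consistent with the slow
inter-stimulus interactions the protocol's save/restore logic exists to
avoid). The activation rate is scaled ×0.33 and the deactivation rate ×2,
and a voltage offset applied to both rate functions is *calibrated* by
bisection (`calibrate_hcn_offset()`) so that exactly 25 % of channels are
open at −65 mV, the availability measured experimentally by tail-current
subtraction. E_HCN defaults to −20 mV (mixed cation reversal; configurable).

**Na.** Hodgkin–Huxley style m³h transient gating plus a small persistent
component. Two choices here matter and were genuinely open:

- *A persistent (non-inactivating) Na fraction* (0.038 % of the Na
  density, half-activation −52 mV, slope 16 mV, τ 5 ms). With purely
  transient m³h kinetics at the standard densities, a stable resting
  potential of −64 mV is unreachable: any m³h window current strong
  enough to depolarize the cell 4 mV from the leak reversal has a steeper
  negative slope than the leak-plus-K restoring slope, so the rest either
  stays near −67.5 mV or collapses into dendritic spiking. A shallow
  persistent component — the mean-field analog of the late openings that
  Markov Nav1.2 models produce — supplies the depolarizing current with a
  voltage dependence flat enough to be stable, and contributes a gentle
  subthreshold amplification of EPSPs.
- *Inactivation shifted out of the subthreshold range* (h half ≈ 10 mV
  depolarized relative to m). If h inactivates on the few-mV pedestal of
  a summed EPSP train, later inputs in a centrifugal sequence are
  *depressed* rather than boosted — that is precisely the mechanism that
  makes cortical dendrites prefer centripetal sequences. Keeping
  availability flat near rest lets the centrifugal boost win.

The m gate is shifted +8 mV so that regenerative events need roughly
−45 mV locally; standard stimuli stay below that, stronger
("near-threshold") contrasts cross it — more readily for centrifugal
sequences, reproducing the directional spike-probability asymmetry.

**Kdr.** n⁴ gating, shifted +15 mV so the rectifier is nearly silent at
rest and engages on the depolarized shoulder of large local EPSPs, where
it brakes the Na boost. A kinetic rate multiplier is exposed per the
general design (each channel type accepts an offset voltage and rate
multiplier) but defaults to 1.

### The uncaging-surrogate synapse

Each synapse is driven by an ideally voltage-clamped presynaptic
compartment. A stimulus pulse (3 ms, default trains at 20 ms intervals)
depolarizes the presynaptic voltage by the "contrast"; release follows an
exponential function with 2 mV per e-fold change; released transmitter
passes through a first-order filter with 75 ms rise and 125 ms fall time
constants; the filtered transmitter gates a three-state
(closed/open/desensitized) AMPA scheme with 0 mV reversal whose rates are
fast relative to the filter, which therefore sets the EPSP time course.
The somatic EPSP of the full chain has a 10–90 % rise of ≈ 41 ms and a
fitted decay of ≈ 120 ms, inside the measured envelope of uncaging EPSPs
(rise 48.6 ± 5.9 ms, decay 109.0 ± 14.4 ms).

Two scaling parameters are free and were fixed once: `g_max = 0.012` µS
makes single somatic EPSPs ≈ 1–2 mV and three-site summed responses
≈ 4–5 mV (the subthreshold experimental range), and the default contrast
is 20 mV. The contrast is larger than the "several mV" a bipolar terminal
would see because, with a 2 mV/e-fold release gain, pulse-evoked release
must exceed the spontaneous (baseline) release by a factor of ~3 × 10⁴:
thirty tonically releasing synapses would otherwise depolarize the
passive cell measurably. The presynaptic voltage is an arbitrary control
variable, so this choice only re-labels the release axis; baseline
release `r0` and transmitter units are absorbed into `g_max`.

Synapses are placed along the dendrite at statistically regular intervals:
successive spacings are gamma-distributed with mean 10 µm and mean/SD = 8
(shape = 64), the regularity statistic reported for the automatic
placement algorithm.

### Numerics

The solver advances voltage with a backward-Euler step on the tree (Hines
elimination, parents before children) and gates with exact exponential
(Rush–Larsen) updates; the AMPA scheme uses an occupancy-conserving
backward-Euler update. The default step is 25 µs; halving it changes
somatic EPSP peaks by < 0.5 %. Voltage clamp is implemented as a stiff
series conductance (10⁴ µS ≈ 100 Ω); the clamp current is reported as the
recording. The RC step response, sealed-end cable attenuation profile,
clamped gate equilibria, passive linearity and transfer-impedance
reciprocity are all verified against closed forms in the test suite.

`equilibrate()` runs until max |dV/dt| < 10⁻⁴ mV/ms everywhere.
`save_state()` / `restore_state()` snapshot the full state (voltages,
gate occupancies, synapse filter and receptor states); directional
protocols restore the equilibrium snapshot between directions, so
activation order cannot leak across runs — without the restore, a second
sequence within ~500 ms of the first is measurably altered.

The resting baseline (Vrest) for all statistics is the somatic voltage of
the equilibrated state; response charge is the baseline-subtracted
trapezoidal integral from the first stimulus onset to the end of the
trace (protocol traces carry ≥ 500 ms of tail, several decay constants).
"Decay time" is the time constant of a mono-exponential fitted between
90 % and 10 % of peak on the falling phase.

The voltage-step tail-current protocol defaults to an ideal whole-cell
clamp (every compartment follows the command). A somatic point clamp
cannot hold a thin dendrite at the command potential within the 5 ms tail
window, so tail amplitudes would confound channel activation with a
per-step driving-force error (reading ≈ 0.17 instead of 0.25 at −65 mV);
tail-current analysis, as practised, presupposes adequate space clamp.
`space_clamp = FALSE` restores the somatic point clamp.

## What the model reproduces

With the standard parameter set (all quantities computed by
`scripts/acceptance.R` and the test suite):

- somatic resting potential ≈ −63.7 mV (target ≈ −64 mV), with the K
  density balanced in proportion to Na;
- HCN depolarizes rest by ≈ 0.6 mV (< 5 mV constraint), mostly distally;
- adding HCN to the passive cable *reduces* the summed three-site EPSP
  peak by ≈ 5 % (reduced driving force plus resting shunt; ≈ 6 % reported);
- adding Na + Kdr (no HCN) amplifies single EPSP peaks by ≈ 8 %
  (≈ 6 % reported) with direction-neutral charge;
- the calibrated HCN availability, 25 % at −65 mV, is recovered
  (≈ 25.4 %) by the full simulated subtraction tail-current I–V pipeline;
- the DS sign structure: passive → small centripetal amplitude
  preference; HCN alone → direction-neutral charge; full model with
  middle/distal sites → centrifugal preference in both amplitude and
  charge; HCN removal (the ZD7288 surrogate) → preference eliminated;
  proximal-only sequences (< 100 µm) → no DS (|DS| below the 2 %
  detection gate used for null results);
- near-threshold stimulation spikes more readily for centrifugal than
  centripetal order.

The centrifugal DS of this reduced unbranched model is real but small
(≈ +0.3–0.6 % at the standard drive, growing with more distal site sets
and stronger stimuli up to the spike limit). Its sign survives ±25 % HCN
and Kdr density changes and the Na 15–35 mS/cm² range (K scaled in
proportion, the procedure used to keep Vrest at −64 mV), and it weakens
when Na is reduced 15 %. One reported property is *not* reproduced: a
15 % Na increase should strengthen DS, but here it pushes the distal
dendrite over spike threshold under the standard drive instead — the
subthreshold corridor of a single unbranched 0.6 µm cable is narrower
than that of the branched reconstructed morphologies, whose thin side
branches isolate the distal nonlinearity better. The corresponding
robustness assertions are kept in the acceptance tests and fail honestly.

## What the synthetic-data generator does and does not emulate

`make_epsp()`, `make_summation_fixture()` and `make_direction_fixture()`
generate bi-exponential EPSP waveforms (defaults: 1–4 mV, kinetics
matching the measured uncaging responses, 10 kHz sampling) with additive
white Gaussian noise, carrying their ground truth in annotations. They
exist so every analysis operation is testable without the simulator:
imposed summation ratios and DS percentages are recovered by the analysis
module with unit slope across randomized targets. They do not emulate
correlated recording noise, baseline drift, stimulus artifacts, or
spiking — passing recovery tests therefore validates the estimators'
arithmetic, not their robustness to structured noise in real recordings.

## Limitations

- Na/Kdr rate equations are not published for the original Markov models;
  the HH-style schemes here are pinned by behaviour (resting potential,
  subthreshold amplification, no spiking at standard drive) rather than
  by kinetic provenance.
- The standard morphology is a single unbranched cable; branched SWC
  reconstructions load and simulate, but the acceptance calibration is
  defined on the cable.
- No NMDA receptors, no inhibition, no Ca or KCNQ channels, and
  deterministic (mean-field) gating only.
- Pharmacology is idealized as setting a conductance to zero everywhere.

## Interfaces

The exported functions are the interface: `standard_model()` →
`equilibrate()` → `run_direction_pair()` / `run_same_site_train()` /
`run_voltage_step_family()` / `run_parameter_scan()` → the analysis
functions. Channel/passive parameters load from YAML
(`read_channel_config()`); morphologies from SWC (`load_swc()`); traces
and morphologies serialize to plain text. `scripts/acceptance.R`
recomputes the calibration quantities end to end. The problem sizes used
throughout (a 10-compartment standard cable, 13-step I–V families,
three-site protocols) are the scale at which the model's behaviour is
converged under the 0.1 λ and 25 µs discretization criteria.
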