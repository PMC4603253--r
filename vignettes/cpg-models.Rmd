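---
title: "Modelling bilateral locomotor CPG circuits with spinalcpg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bilateral locomotor CPG circuits with spinalcpg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

spinalcpg simulates the mammalian spinal locomotor central pattern
generator (CPG) as a bilateral network of conductance-based spiking
populations.  Rhythm generation rests on the persistent (slowly
inactivating) sodium current I_NaP: each rhythm-generating (RG) neuron
carries fast spiking currents (fast Na with instantaneous activation and
fast inactivation, delayed-rectifier K), a persistent Na conductance whose
slow inactivation variable terminates bursts and whose recovery times the
interburst interval, a leak current, and conductance-based synapses with
instantaneous rise and single-exponential decay.  Gate steady states are
Boltzmann sigmoids `1/(1 + exp((V - V_half)/k))` and voltage-dependent time
constants are bell curves `tau_max / cosh((V - V_half)/(2 k))`.

A single RG neuron (or a recurrently coupled RG population) traverses three
regimes as its leak reversal potential E_L is depolarized: **silence**,
**intrinsic bursting**, and **tonic** firing.  Network excitability is
controlled by a dimensionless drive `alpha` standing in for neuroactive
drug concentration, mapped onto each drive-sensitive population's leak
reversal as `E_L = E_L0 * (1 - drive_gain * alpha)`; since `E_L0 < 0`,
increasing drive depolarizes.  The standard single-population experiment
ramps the flexor RG population's mean leak reversal from -70 to -58 mV
(`alpha` from 0 to 12/70) and recovers the silence -> bursting -> tonic
sequence, a monotone rise of burst frequency, and a burst amplitude that
first rises (progressive recruitment and synchronization of neurons drawn
from a jittered excitability distribution) and then falls (persistent-Na
inactivation depressing within-burst firing).

## Architectures

Three bilateral architectures are provided as declarative builders.

* `build_model1()` / `build_model2()`: each side holds a flexor (RG-F) and
  an extensor (RG-E) center coupled by reciprocal inhibition through the
  Inrg populations, with the flexor dominant: the extensor baseline is more
  depolarized, so an isolated extensor center is tonically active and its
  bursting is imposed by rhythmic inhibition from the ipsilateral flexor.
  Left and right halves interact through three commissural pathways:
  inhibitory V0D (excited by the ipsilateral flexor, inhibiting the
  contralateral flexor), excitatory V3 (mutual flexor excitation,
  promoting synchrony), and the excitatory V2a-V0V pathway promoting
  alternation.  The two models differ only in that pathway: in Model 1 the
  V2a population is driven by the ipsilateral flexor and the V0V output is
  relayed through a contralateral inhibitory population (InV0V) onto the
  contralateral flexor; in Model 2 the V2a population is driven by the
  ipsilateral extensor and V0V excites the contralateral flexor directly.
* `build_unified()`: extends either model with the inhibitory V2b and V1
  classes.  V2b populations carry the reciprocal flexor-extensor
  inhibition (split into a flexor-coactive and an extensor-coactive half);
  V1 populations receive a tonic excitatory drive sourced from the
  contralateral side plus phasic inhibition from the contralateral V0D,
  and inhibit the ipsilateral extensor center and a tonically active
  interposed population (InV1) which in turn inhibits the ipsilateral
  flexor.  V1 thereby both disinhibits the flexor (raising locomotor
  frequency) and provides a second, commissurally gated route to
  flexor-extensor alternation.

In-silico manipulations are pure spec-to-spec transforms:
`apply_lesion()` removes populations by role or performs a hemisection
(which also removes every commissural projection and the contralaterally
sourced V1 drive), and `apply_knockout()` models axon-guidance mutants by
rerouting a fraction of axons (Netrin-1: V0D/V0V crossing reduced; DCC:
V0D/V0V/V3 crossing reduced; EphA4: a fraction of V2a axons aberrantly
crosses to the contralateral V0V).

## Frozen defaults and why

All numeric choices live in `cpg_defaults()` and were fixed once against
the qualitative regime structure the architectures must express; they are
the package's own parameter set, not transcriptions.

* **Membrane kinetics.** The canonical persistent-sodium burster
  formulation with `m_NaP` half-voltage -45 mV (slope -6) and `h_NaP`
  half-voltage -53 mV (slope 8, `tau_max` 2.5 s).  The inactivation slope
  is deliberately shallow so that firing just above the bursting range is
  fast enough (4-8 Hz) for a heterogeneous population to desynchronize
  into genuinely tonic collective activity at the top of the standard
  ramp; steeper slopes leave the population locked in slow synchronized
  volleys well past -58 mV.  The h_NaP time-constant scale exceeds the
  membrane time constant more than 300-fold, as required for a slow
  burst-terminating variable.
* **Synaptic reversals.** `E_synI = -80 mV`: inhibition must retain
  driving force near the hyperpolarized interburst potential (-70 mV
  region), otherwise commissural inhibition cannot phase-lock the slow
  rhythm.
* **Population heterogeneity.** RG leak reversals are jittered +/- 2.25 mV
  and persistent-Na conductances +/- 2%.  The spread creates the gradual
  recruitment that makes burst amplitude rise over the first part of the
  ramp; much larger spreads destroy the silent region at the ramp foot.
* **Recurrent excitation.** `p = 0.1`, weight 0.015 nS at full scale:
  strong enough to synchronize population bursts, weak enough that the
  bursting-to-tonic transition still occurs below -58 mV.
* **Drive gains.** RG-F 1.0; RG-E and V0D 0.15 (their excitability barely
  follows the drug); V3 0.8 and V2a 1.5 with a hyperpolarized V2a
  baseline, so the V2a-V0V pathway is silent at low drive and strongly
  recruited at high drive.  These gain asymmetries implement the
  frequency-dependent division of labour between the commissural
  pathways: V0D locks left-right alternation from the lowest coordinated
  drives, the V2a-V0V pathway joins at high drive, against the
  synchronizing pull of V3.
* **Scaling for desk runs.** `scale_network()` shrinks populations (RG 200
  -> 50 at scale 0.25, the size used throughout the tests and the
  acceptance script) while preserving the expected synaptic in-degree by
  raising connection probabilities.  Preserving in-degree rather than mean
  conductance matters: at `p = 0.1` a 12-neuron source population leaves a
  third of its targets without any synapse, which destroys slow-rhythm
  phase locking.  The halved-sizes/doubled-weights variant remains
  available (`mode = "weight"`).

## Analysis pipeline

`rate_histogram()` converts spikes to population rates in
spikes/(neuron x s) with 100 ms bins.  `detect_bursts()` applies hysteresis
thresholds (on at 30%, off at 15% of a rolling 90th-percentile reference
over 20 s, floored at 0.5 spikes/(neuron x s), minimum burst 200 ms), so a
constant tonic trace yields no bursts.  `classify_regime()` and
`regime_profile()` label silence / bursting / tonic;
`frequency_amplitude_series()` tracks the rhythm along a ramp.

Every windowed analysis excludes the first 10 s of a run as a settling
and entrainment transient (populations start from random phases).
`phase_relation()` computes the circular mean and concentration R of one
population's burst events within another's cycles and labels the relation
**synchrony** (mean phase within 0.2 of 0, R >= 0.7), **alternation**
(within 0.2 of 0.5, R >= 0.7) or **uncoordinated**.  The windowed
`coordination_report()` keys on dominant bursts (on/off fractions 0.45/0.2,
excluding small partial-recruitment events at low drive) and phases the
flexor-extensor relation midpoint-to-midpoint, which is invariant to the
strongly unequal and drive-dependent duty cycles of the two centers;
left-right relations between homologous centers use burst onsets.

`classify_deletions()` fits an expected-cycle grid to the
pre-perturbation rhythm (refusing to classify when the period CV exceeds
20%), flags expected onsets with no burst within a quarter cycle,
classifies the ipsilateral antagonist as sustained or rhythmic during the
deletion, measures the contralateral timing deviation, and reports whether
the post-deletion rhythm resumes on the extrapolated grid (non-resetting)
or not.  `phase_duration_slopes()` regresses flexor-referenced phase
durations (flexor phase = burst duration, extensor phase = inter-burst
gap) on the cycle period; in a flexor-dominated rhythm the extensor slope
is close to one and the flexor slope close to zero.

## Deletion probes

Spontaneous burst deletions are elicited deterministically: the
`deletion_probe_flexor` preset applies an inhibitory conductance pulse of
about 1.6 cycles to the left flexor center, the extensor probe to the left
extensor center (pulse lengths are calibrated from a short unperturbed
pilot run).  Suppressing the flexor releases the ipsilateral extensor into
sustained activity -- the signature of flexor-dominated organization --
while the contralateral rhythm continues within a tenth of a cycle of its
grid; suppressing the tonic extensor leaves the flexor timing essentially
untouched.

## Numerical choices

Integration is fixed-step exponential Euler (default `dt = 0.1 ms`),
stable for the stiff synaptic decays; gate curves are tabulated on a
0.05 mV grid with linear interpolation; synaptic events are delivered with
a one-step delay; spikes are upward crossings of -10 mV with a 1.5 ms
refractory gate.  Initial voltages are drawn uniformly in
`[E_L - 5, E_L]` mV (below rest, so that initialization cannot ignite a
spurious synchronized burst) with gates at steady state.  Runs are
deterministic given the connectome seed and simulation seed; the engine
uses its own Mersenne-Twister stream, independent of R's RNG.  Optional
Ornstein-Uhlenbeck conductance noise is off by default.  A dt-refinement
oracle (adaptive-step reference integration of the same equations) guards
accuracy in the test suite.

Problem sizes used by the test-suite and acceptance runs: scale 0.25
networks (50-neuron RG centers, 12-16 neuron interneuron populations),
ramps of 150 s and constant-drive runs of 40-90 s, analysis windows of
20-25 s.  These sizes reproduce the full-scale regime structure (the
scaling modes above) at desk-run cost.

## Design choices where the circuit diagrams are silent

* The V2b class must be coactive with both phases to mediate reciprocal
  inhibition; it is therefore realized as two named halves (V2b-F, V2b-E)
  sharing the V2b role.  In the unified build V2b carries the entire
  reciprocal inhibition (the Inrg populations remain but their
  flexor-extensor branch is handed over): with any substantial Inrg
  remainder, silencing V1 and V2b together would leave enough reciprocal
  inhibition to preserve alternation, contradicting the phenotype this
  architecture exists to express.  After silencing V2b alone in the intact
  cord, alternation is carried by the V1 route (tonic V1 inhibition of the
  extensor, rhythmically released by the contralateral V0D in phase with
  the contralateral flexor).
* A weak excitatory RG-F -> RG-E connection (masked by inhibition in the
  intact cord) lets the extensor center follow the flexor in phase once
  both inhibitory routes are silenced, producing flexor-extensor synchrony
  rather than mere tonic extensor activity.  The connection is
  deliberately one-directional: a reciprocal extensor-to-flexor branch
  would bombard the flexor center with asynchronous excitation from the
  tonic extensor and push it out of its bursting regime.
* The V1 tonic drive is implemented as a constant excitatory conductance
  tagged with its (contralateral) source side, not as an explicit spiking
  commissural population; a hemisection removes it.  The interposed InV1
  population is tonically driven from its own side, so it survives
  hemisection and its disinhibition (after V1 loss) slows the flexor
  rhythm.
* Deletion probes are controlled perturbations rather than spontaneous
  (noise-driven) deletions: reproducibility at desk scale.

## What the synthetic conditions do and do not show

The generator's defaults emulate drug-evoked fictive locomotion in the
isolated neonatal rodent cord: graded, slowly varying excitability, no
afferent feedback, no pattern-formation layer or motoneuron reflex
circuitry, and populations an order of magnitude smaller than real
interneuron classes.  Passing tests therefore demonstrate that the
hypothesized connectivity is sufficient to reproduce the qualitative
regime structure and its lesion/knockout phenotypes under these idealized
conditions -- not that the spinal cord realizes exactly these weights, nor
that quantitative frequencies or amplitudes transfer to real recordings.

## Known limitations

* The coordinated frequency range of the intact scaled models spans about
  0.5-0.85 Hz: the commissural inhibition that locks the left-right phase
  at low drive also accelerates the slow rhythm (escape-type half-center
  coupling), so the more-than-twofold frequency rise seen in drug
  titration experiments is only partially reproduced; the rise is largest
  when the rhythm-emergence region, where locking is still seed-dependent,
  is included in the analysed sweep.
* Regime boundaries at 50-neuron scale have finite-size seed variability
  of roughly +/- 0.01 in alpha.
* Because both the V0D and the V3 population are driven (and saturated)
  by the same flexor bursts, their per-cycle outputs scale together along
  the drive sweep: the switch from alternation to synchrony after V0V or
  V2a removal -- which requires the V0D influence to fall below the V3
  influence at high drive -- does not occur in the frozen conditions, and
  the same mechanism keeps the EphA4 knockout alternating (its intact V0D
  pathway behaves as in the V0V-removal case).  Deleting V0D itself, or
  both V0 classes, reproduces the corresponding phenotypes.
* A burst deletion elicited on one side detectably shifts the timing of
  the contralateral rhythm (a few tenths of a cycle): the commissural
  coupling strong enough to phase-lock 50-neuron populations also
  transmits perturbations, more than the near-invisible contralateral
  effects seen in isolated-cord recordings.
* No calcium dynamics, spike-frequency adaptation, conduction delays or
  multi-compartment structure; commissural delay is a single integration
  step.

## A minimal session

```{r, eval = FALSE}
library(spinalcpg)

# the isolated rhythm-generating population along the standard ramp
res <- run_experiment("fig5_isolated_rg", seed = 1, scale = 0.25)
rle(res$regimes$regime)$values     # silence -> bursting -> tonic
res$freq_amp                       # windowed frequency and amplitude

# intact Model 1 ramp and an ablation
intact <- run_experiment("model1_ramp", seed = 1, scale = 0.25)
intact$coordination[, c("t_mid", "frequency", "lr_label", "fe_label")]
hop <- run_experiment("ablate_v0_both", seed = 1, scale = 0.25)
hop$coordination$lr_label          # left-right synchrony: hopping

# outputs as TSV/JSON with an embedded config digest
write_outputs(intact, "model1_run")
```
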