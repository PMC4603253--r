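# spinalcpg

Conductance-based simulation of the bilateral mammalian locomotor central
pattern generator (CPG), for computational neuroscientists studying how
genetically identified spinal interneuron classes (V0D, V0V, V1, V2a, V2b,
V3) shape left–right and flexor–extensor coordination.

## The model

Rhythm generation rests on the persistent (slowly inactivating) sodium
current *I*<sub>NaP</sub>.  Each rhythm-generating neuron follows a
Hodgkin–Huxley-style current balance

C dV/dt = −ḡ<sub>Na</sub>m³h(V−E<sub>Na</sub>) −
ḡ<sub>NaP</sub>m<sub>P</sub>h<sub>P</sub>(V−E<sub>Na</sub>) −
ḡ<sub>K</sub>n⁴(V−E<sub>K</sub>) − g<sub>L</sub>(V−E<sub>L</sub>) −
I<sub>syn</sub>

with instantaneous activations, Boltzmann steady states
1/(1+exp((V−V½)/k)) and bell-shaped time constants
τ<sub>max</sub>/cosh((V−V½)/2k).  The slow inactivation h<sub>P</sub>
(τ<sub>max</sub> = 2.5 s) terminates bursts; its recovery times the
interburst interval.  Network excitability is driven by a dimensionless
drive α (emulating neuroactive drug concentration) through the leak
reversal mapping **E<sub>L</sub> = E<sub>L0</sub>·(1 − gain·α)**.

Populations and projections are declarative data
(`population_spec()`, `projection_spec()`, `network_spec()`).  Builders
construct two bilateral commissural architectures (`build_model1()`,
`build_model2()`, differing in the V2a–V0V pathway) and a unified
architecture with the inhibitory V1/V2b classes (`build_unified()`).
Pure transforms model genetic ablations and hemisections
(`apply_lesion()`) and axon-guidance knockouts — Netrin-1, DCC, EphA4 —
as partial axon rerouting (`apply_knockout()`).  A compiled (Rcpp)
fixed-step exponential-Euler engine simulates the spiking network with
seeded, bit-reproducible results; analysis routines compute population
rate histograms, hysteresis burst detection, silence/bursting/tonic regime
classification, circular-statistics phase labels
(alternation/synchrony/uncoordinated), burst-deletion classification
against an expected-cycle model, and phase-duration regression slopes.

## Worked example

```r
library(spinalcpg)

# An isolated 50-neuron flexor population under the standard ramp that
# takes the mean leak reversal from -70 to -58 mV:
res <- run_experiment("fig5_isolated_rg", seed = 1, scale = 0.25)
rle(res$regimes$regime)$values
#> [1] "silence"  "bursting" "tonic"
round(res$freq_amp$frequency, 2)
#>  [1]   NA   NA   NA 0.23 0.34 0.43 0.53 0.65 0.77 0.91 1.06 1.20 1.34   NA   NA
```

The population is silent at hyperpolarized leak reversals, bursts over the
mid range with monotonically increasing frequency (here 0.23 → 1.34 Hz)
and a burst amplitude that rises (recruitment) and then falls
(*I*<sub>NaP</sub> inactivation), and switches to sustained tonic firing
at the depolarized end.

```r
# The intact bilateral Model 1 under a slow drive ramp:
intact <- run_experiment("model1_ramp", seed = 1, scale = 0.25)
intact$coordination[, c("t_mid", "frequency", "lr_label", "fe_label")]
#>    t_mid frequency    lr_label    fe_label
#> 1  20000      0.55 alternation alternation
#> 2  40000      0.64 alternation alternation
#> 3  60000      0.75 alternation alternation
#> 4  80000      0.80 alternation alternation
#> 5 100000      0.80 alternation alternation
#> 6 120000      0.75 alternation alternation
#> 7 140000      0.67 alternation alternation

# Removing both V0 commissural classes leaves only the V3 pathway:
hop <- run_experiment("ablate_v0_both", seed = 1, scale = 0.25)
unique(hop$coordination$lr_label)
#> [1] "synchrony"        # left-right synchronous "hopping"
```

(Output shown is from these exact calls on the frozen defaults; other
seeds shift the numbers slightly.)

## Command line

A thin CLI over the same functions:

```sh
exec/spinalcpg build --architecture model1 --out edges.tsv
exec/spinalcpg run --preset model1_ramp --seed 1 --out out/
exec/spinalcpg sweep --preset model1_ramp --alphas 0.06,0.09,0.12
exec/spinalcpg report --seed 1
```
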