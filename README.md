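# alphacell

Conductance-based simulation of glucagon secretion from pancreatic alpha
cells, for quantitative physiologists studying how plasma glucose and amino
acids jointly set glucagon output.

Glucose suppresses glucagon secretion through an intrinsic chain — glycolytic
flux raises ATP, ATP closes K(ATP) channels (conductance g<sub>KATP</sub>),
the depolarized membrane fires smaller spikes, and P/Q-type calcium channels
with a high activation threshold no longer open enough to drive exocytosis.
Amino acids (postprandially, chiefly glutamine converted to glutamate and
co-released with glucagon) act in the opposite direction: glutamate on
AMPA/kainate-type ionotropic glutamate receptors adds cation current, raising
both the amplitude and frequency of membrane-potential oscillations, and the
secreted glucagon feeds back on the cell's own glucagon receptors, boosting
cAMP through transmembrane adenylyl cyclases (tmAC).

The model couples three components:

* **Metabolism** — lactate flux J<sub>lac</sub> = 2 p<sub>L</sub> J<sub>G6P</sub>;
  CO₂ production from the respiratory-quotient split
  J<sub>CO2</sub> = J<sub>O2,G</sub> + 0.7 (J<sub>O2</sub> − J<sub>O2,G</sub>);
  relative ATP (affine in the ATP-producing fluxes, rising 20% from 1 to
  6 mM glucose); g<sub>KATP</sub> as a decreasing Hill function of ATP.
* **Signaling** — steady-state cAMP from bicarbonate-stimulated soluble
  adenylyl cyclase (sAC), normalized to f<sub>cAMP,sAC</sub> ∈ [0, 1];
  autocrine tmAC response
  f<sub>cAMP,tmAC</sub> = 1 + (f₀/100) · RGS<sub>int</sub>ⁿ/(kⁿ + RGS<sub>int</sub>ⁿ)
  with f₀ = 175, k = 2.8, n = 8; net cAMP
  f<sub>cAMP</sub> = 0.75 f<sub>cAMP,sAC</sub> + 0.25 f<sub>cAMP,tmAC</sub>.
* **Membrane/secretion** — a Hodgkin–Huxley-type voltage equation
  C<sub>m</sub> dV/dt = −(I<sub>Na,AA</sub> + I<sub>Ca,AA</sub> + I<sub>K,AA</sub> +
  I<sub>KATP</sub> + I<sub>L</sub> + I<sub>SOC</sub>) with amino-acid scalings
  f<sub>AA,Na</sub> = 1 + 0.4 f<sub>AA</sub>, f<sub>AA,K</sub> = 1 + 0.2 f<sub>AA</sub>,
  f<sub>AA,Ca</sub> = 1 + 0.16 f<sub>AA</sub> and the cAMP factor
  f<sub>cAMP,Ca</sub> = 1 − 0.2 (1 − f<sub>cAMP</sub>); secretion
  GS = f<sub>cAMP,GS</sub> (GS<sub>L</sub> + GS<sub>PQ</sub> + GS<sub>m</sub>)
  from time-averaged channel-resolved calcium signals, with
  f<sub>cAMP,GS</sub> = 1 − 0.5 (1 − f<sub>cAMP</sub>).

The headline output is the relative glucagon secretion
RGS = GS / GS<sub>norm</sub>, normalized to the zero-glucose,
intrinsic-cAMP-only, no-amino-acid state. The autocrine loop is evaluated
feed-forward: an intrinsic-only pass yields RGS<sub>intrinsic</sub> (the
interstitial glucagon proxy), the tmAC Hill response converts it to extrinsic
cAMP, and a second pass yields RGS<sub>net</sub>.

## Worked example

```r
library(alphacell)
p  <- alphaParams()                 # calibrated defaults
sw <- runSweep(sweepSpec(glucose = c(0, 1, 6, 10), faa = c(0, 1)), p)
foldChanges(sw, at = c(1, 6))
```

```
Amino-acid fold change of net relative glucagon secretion
  G =  1.0 mM: 3.49-fold
  G =  6.0 mM: 2.00-fold
  extreme ratio (max high-AA / min low-AA): 6.98
  parameter hash: 8c7b5cc9595f
```

Raising the amino-acid level from fasting (f<sub>AA</sub> = 0) to
protein-rich-meal levels (f<sub>AA</sub> = 1) raises secretion ≈3.5-fold at
1 mM glucose but only ≈2-fold at 6 mM, and the spread between the
low-glucose/high-AA and high-glucose/low-AA extremes is ≈7-fold. A single
condition exposes the intermediate quantities:

```r
rgsNet(1, 1, p)[, c("gKATP", "fcAMP_sAC", "RGS_intrinsic", "fcAMP_tmAC", "fcAMP", "RGS_net")]
#    gKATP fcAMP_sAC RGS_intrinsic fcAMP_tmAC  fcAMP RGS_net
#   0.1374     0.995        2.8084     1.8855 1.2176  4.9675
```

At 1 mM glucose and high amino acids the intrinsic pass secretes 2.8× the
reference rate; that autocrine signal sits right at the tmAC half-activation
(k = 2.8), so extrinsic cAMP runs at 1.89× baseline and lifts net secretion
to 4.97× the reference. Membrane traces and their oscillation metrics come
from `simulateTrace()` / `oscillationMetrics()` / `compareTraces()`, and
`campDecomposition()` tabulates the stacked sAC/tmAC cAMP contributions.
YAML scenario files (see `inst/extdata/`) and a small CLI
(`inst/scripts/alphacell-cli.R`) drive the same functions from a shell.

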