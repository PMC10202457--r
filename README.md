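# pYtagKinetics

Mechanistic modeling and trace quantification for **pYtag** translocation
biosensors of receptor tyrosine kinase (RTK) activity.

A pYtag labels a receptor of interest with an ITAM (a paired-tyrosine
activation motif) and co-expresses a fluorescent tandem-SH2 reporter
(ZtSH2) that binds the motif once the activated receptor phosphorylates
it. Active receptor therefore pulls the reporter out of the cytosol, and
the **percentage of reporter cleared from the cytosol** is a quantitative,
single-cell readout of receptor activity. This package is for people who
use (or build) such biosensors and want to (i) understand mechanistically
why different ligands produce different activation kinetics, and (ii)
quantify per-cell intensity timeseries the same way across experiments.

## The model

An EGFR-like receptor carries three per-receptor states — ligand binding,
dimerization lumped with autophosphorylation, and reporter binding —
propagated by mass-action kinetics. Closing the state space gives 16
species: clamped free ligand N1 (bath ligand is in vast excess), free
reporter N2, four monomer states and ten protomer-resolved dimer states.
Rate constants: ligand association/dissociation `k1`/`k7`; dimerization
`k5` with dissociation `k6` (ligand-free dimers) or `k3` (ligand-bound);
reporter association/dissociation `k2`/`k4`, with reporter association
restricted to ligand-bound (phosphorylated) dimers.

Before stimulation the receptor pool N<sub>E,0</sub> partitions between
monomers and pre-formed inactive dimers:

    N_E0 = N3_0 + 2 N5_0,   k5 N3_0^2 = k6 N5_0
    N5_0 = [ (4 N_E0 + k6/k5) - sqrt( (4 N_E0 + k6/k5)^2 - 16 N_E0^2 ) ] / 8

(evaluated in a cancellation-free rationalized form). Ligand identity is
encoded by two dimensionless dissociation scale factors:
**β** multiplies `k7` (binding affinity) and **γ** multiplies `k3`
(dimerization affinity of ligand-bound receptors); β = γ = 1 is the
EGF-like base case, β = 50 / γ = 100 an epiregulin-like low-affinity
ligand. The measured activity is

    clearance(t) = 100 × (Z_total − Z_free(t)) / Z_total   [%]

and its experimental counterpart, computed by the quantification module
from cytosolic intensities, is

    activity(t) = −100 × ( I_cyt(t) / I_cyt,0 − 1 )

with I<sub>cyt,0</sub> the mean pre-stimulus cytosolic intensity.

## Worked example

```r
library(pYtagKinetics)

params <- modelParameters()          # base EGF-like calibration
analyticPrestimulusState(params)     # pre-stimulus monomer/dimer split

egf  <- ligandSpec("EGF",  dose = 5000)                 # saturating
ereg <- ligandSpec("EREG", dose = 20, beta = 50, gamma = 100)

trEgf  <- simulateTimecourse(params, egf)
trEreg <- simulateTimecourse(params, ereg)
classifyKinetics(trEgf)
classifyKinetics(trEreg)

gbm <- simulateGbmScenario(params, dose = 20)           # WT vs GBM mutant
c(wt  = tail(clearance(gbm$wt), 1),
  gbm = tail(clearance(gbm$gbm), 1))
```

This prints:

```
EquilibriumResult: N3o = 8.474e-08 M, N5o = 7.181e-09 M (dimerized receptor fraction 0.145)
  fixed-point residual max|dN/dt| = 0 M/s
RegimeLabel 'biphasic-rising' (tHalf 263 s, overshoot 0.527, early/late slope 12.6)
RegimeLabel 'peak-plateau' (tHalf 8.68 s, overshoot 1.05, early/late slope -8.79e+03)
       wt       gbm
 6.704029 20.132652
```

Reading the numbers: ~15% of receptors sit in pre-formed dimers before
stimulation, which carries the fast sub-minute phase of the saturating EGF
response (hence `biphasic-rising`: a rapid initial phase, then a slow
dimerization-limited rise over tens of minutes). The low-affinity ligand
(γ = 100) instead produces an early transient peak that relaxes to a
plateau (`peak-plateau`): its liganded dimers dissociate fast, so the
transiently activated pre-formed pool decays to a lower equilibrium. The
GBM-mutant receptor (650-fold stronger dimerization of ligand-bound
receptors than wild type, 6-fold vs 50-fold weaker ligand binding)
responds to the same epiregulin dose more strongly and more gradually —
its 30-min clearance is ~3× the wild type's and its time to half-max ~3×
longer.

The quantification side consumes per-cell intensity tables
(`CellTraceSet`, tidy TSV I/O): `clearanceActivity()`,
`repairAberrantFrames()`, `minmaxNormalize()`, `timeToHalfMax()`,
`ktrActivity()`, `aggregateReplicates()`, `sortByExpressionRatio()`.
`generatePopulation()` produces seeded synthetic populations with ground
truth for testing the full pipeline, and `fitLigandParameters()` /
`recoveryReport()` recover (β, γ) from clearance traces by multi-start
least squares.

See `vignettes/modeling-pytag-kinetics.Rmd` for the model's assumptions,
the parameter calibration rationale, numerical choices and limitations.

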