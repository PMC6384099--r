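---
title: "Stoichiometric accounting of clostridial fermentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stoichiometric accounting of clostridial fermentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermstoich)
```

# The problem

Batch fermentations of solventogenic clostridia are usually characterized
by HPLC end-point measurements: a handful of extracellular concentrations
at inoculation and at the end of the run. From these alone one wants molar
yields, an estimate of the gases that were not measured (CO₂, H₂), and two
closure checks — does the substrate carbon reappear in products, biomass
and CO₂, and do the substrate's electron equivalents reappear in products,
biomass and H₂? `fermstoich` implements that accounting as a tested
pipeline, with the IBE fermentation of d-glucose and the l-rhamnose
catabolism of *C. beijerinckii* (1,2-propanediol, *n*-propanol, propionate
via a bacterial microcompartment) as the built-in reference systems.

# Net changes and roles

All concentrations are mM and times hours throughout; fixing the units
removes a whole class of conversion mistakes. For each compound the net
change between the first and last sample is folded into a non-negative
amount and a role: *substrate* if the final concentration is lower than the
initial one, *product* otherwise. The rule matters for acetate, which is
dosed with the medium (ammonium acetate) and is reassimilated on glucose
but net-produced on rhamnose. "ND" (below detection) readings are stored
as 0 mM for accounting but kept distinguishable from true zeros; empty
cells are absent, not zero. In the packaged mixed-sugar culture the stored
start (37.3) and end (36.2) acetate concentrations imply a net consumption
of 1.1 mM; the package always derives nets from the stored endpoints rather
than treating separately printed "consumed" figures as independent facts.

# Biomass

Biomass is accounted as the 5-carbon formula unit C₅H₉O₂.₅N — five
monomers of the standard elemental cell composition CH₁.₈O₀.₅N₀.₂
(123.13 g/mol per unit from IUPAC atomic weights). The unit size is not
arbitrary: the conventional per-mole degree of reduction of biomass,
21 electrons, equals 5 × 4.2, the per-C-mol value of the standard
composition, so a 5-C unit is the size at which "one mole of biomass"
carries exactly those 21 electrons; it also reproduces the reference
cultures' biomass concentrations (26.6, 2.1, 11.7 mM) and recoveries.
Biomass observations resolve in a fixed order: a directly measured mM
value overrides a measured cell dry weight (g/L, divided by the unit
mass), which overrides the OD₆₀₀ calibration
`cdw = 0.28 × OD₆₀₀ + 0.13`. The calibration was established on
d-glucose-grown cells and does not transfer to the filamentous morphology
on rhamnose — hence the override order, with dry weight preferred whenever
it exists.

# Recoveries

Carbon recovery is
`100 × (Σ C·ΔP + 5·X + CO₂) / (Σ C·ΔS)` with `X` the biomass in mM of 5-C
units. CO₂ is not measured; it is estimated by product class — 1 mol per
mol acetate or ethanol, 2 per butyrate or butanol, 3 per acetone or
isopropanol — which is just the count of decarboxylations between pyruvate
and each product. Consumed acetate never generates CO₂ and enters only the
denominator.

Electron recovery replaces carbon counts by degrees of reduction,
`γ = 4C + H − 2O − 3N`, with biomass at 21 e⁻/unit and H₂ at 2 e⁻/mol.
Acids are registered as their undissociated species; only then does the
linear formula reproduce the conventional values (acetate 8, butyrate 20,
propionate 14, lactate 12). Since γ(CO₂) = 0, the electron recovery is
independent of the CO₂ estimate. Because γ is linear in the elemental
formula, any elementally balanced reaction scheme conserves total γ — the
property the test suite exercises on generated data.

**Integer display.** Recovery percentages are stored at full precision and
displayed as integers by truncation toward zero, a conservative convention
that never overstates how much of a balance closed (96.23 → 96,
88.67 → 88). It is also the convention under which the three reference
carbon recoveries (95.12, 96.23, 88.67%) reproduce their published integer
values exactly.

# H₂ by redox closure

H₂ is rarely quantified during such fermentations, so it is inferred from
the pathway stoichiometry. Each pyruvate oxidized to acetyl-CoA reduces
one ferredoxin. Reduced ferredoxin cannot reduce the solvent-forming
dehydrogenases directly; it either transfers its electrons to NAD
(covering whatever NADH deficit the product spectrum leaves) or is vented
as H₂ by the hydrogenase. Surplus NADH, where glycolysis delivers more
than the products consume, is vented the same way:

```
H₂ = max(0, Fd_red + NADH_produced − NADH_consumed)
```

Electron-bifurcating butyryl-CoA dehydrogenase is deliberately not
modeled; with a simple 2-NADH C₄ reduction this closure reproduces the
rhamnose reference culture exactly (Fd 42.6, NADH deficit 34.4, H₂ 8.2 mM,
electron recovery 96%), and it gives the classic 4 H₂ per glucose for a
homoacetate fermentation. For the glucose IBE culture the closure yields
93.3% electron recovery, below the published 98%; the H₂ convention the
original calculation used for that pathway is not recoverable from the
printed data, so the report deliberately carries two diagnostics instead
of a guess — the closure value and the H₂ that a 100% closure would
require (`required_h2()`).

# The pathway ledger

Pathways are declarative reaction lists (stoichiometry over registry
compounds and named intermediates, signed NADH/Fd/ATP coefficients per
unit flux); every reaction is checked for carbon balance at assembly.
Fluxes are resolved demand-driven: intermediates are at steady state, so
each producer runs at the rate its consumers plus any measured
accumulation demand. Two refinements handle the non-tree parts of the
network: acetate reassimilation via CoA transferase is *pinned* to the
measured acetate consumption, and in the mixed-sugar pathway the DHAP →
pyruvate flux is *capped* by the aldolase supply, with glycolysis from
glucose balancing the remainder. Demand-driven resolution means implied
sugar demand can fall short of measured consumption — that gap is exactly
the carbon the recovery calculation reports as unrecovered, so the two
views are consistent.

Two ledger conventions are exposed because both are in common use for the
same culture: `"observed"` sets the glycolytic and pyruvate-oxidation
fluxes from the measured products (42.6 mM DHAP-equivalents = acetate +
2 × butyrate) and is what the H₂ closure uses; `"discussion"`
approximates DHAP by the full sugar consumption (46.4 mM), which is the
convention behind the headline "92.8 mM NADH available" budget
(46.4 glycolytic + 46.4 ferredoxin, with complete Fd → NAD transfer).
One published intermediate figure — 15.5 mM at each C₄ reduction step —
is not derivable from the measured 11.7 mM butyrate under any convention
we could reconstruct (it corresponds to an equimolar acetate/butyrate
split of the acetyl-CoA pool rather than the observed one); the ledger
reports the observation-driven 11.7 mM per step and we document the
discrepancy here rather than reproduce it.

The normalized branch equations divide each branch's products by the
biomass-corrected basis (sugar consumed minus biomass mM, mole-for-mole:
46.4 − 2.1 = 44.3 mM), giving `1 lactaldehyde → 0.39 propanediol + 0.41
propanol + 0.18 propionate` and `1 DHAP → 0.43 acetate + 0.26 butyrate`.

**ATP.** Substrate-level phosphorylation is the only ATP source. Per mole
of sugar: the uptake/priming cost (−1 uptake − 1 rhamnulokinase for
rhamnose; 0 extra for glucose, whose net +2 already includes the priming
kinases), +2 for the triose-to-pyruvate phosphorylations assuming complete
1 sugar → 1 DHAP conversion, and +1 per mole of acid formed per mole of
the biomass-corrected basis. Propionate is credited a kinase ATP — the
propionyl-phosphate is dephosphorylated by a butyrate kinase moonlighting
as propionate kinase — which is required to land at the 0.87 ≈ 0.9 mol
ATP/mol rhamnose against ≈2.0 on glucose. The biomass-corrected basis is
used for the acid terms (the demand-driven fluxes would give 0.81); this
matches how the published ≈0.9 figure is constructed. Microcompartment
shell synthesis costs are real but unquantified and excluded.

# The synthetic-data generator

The generator emulates what the accounting assumes about the reference
cultures: products accumulate in fixed molar proportion to substrate
consumed, consumption follows a normalized logistic progress curve
(growth-coupled, saturating as the culture arrests), and additive Gaussian
noise emulates HPLC measurement error — applied to concentrations (never
to deltas or to the stored truth) and clipped at 0 mM, mirroring
detection-limited data, with the clip count recorded. The generator closes
each split itself: CO₂ takes the residual carbon, H₂ the residual
electrons, water the residual O and H, so a spec is either elementally
consistent or rejected (`carbon-inconsistent` / `electron-inconsistent`),
and the emitted truth lets the estimators in the balance module be scored
against known values. Default conditions mirror the reference rhamnose
culture: 243.4 mM initial sugar, 46.4 mM consumed over 56 h, the measured
product coefficients, biomass yield 0.045 units/mol; 15 time points and a
logistic rate of 0.25/h with midpoint at a third of the run are a
realistic sampling density and progress shape for such a batch culture.

What the generator does *not* emulate — mechanistic (Monod) kinetics, pH
dynamics, product inhibition, the unexplained growth arrest on rhamnose,
compound-specific detection limits, or correlated HPLC calibration error —
bounds what passing tests show: they validate the accounting and the
estimators on data that satisfy the accounting's own assumptions, not the
biology of any particular culture.

# Numerical choices

* Yields and recoveries are stored at full double precision; display
  rounding (2 decimals for yields, 3 below 0.1; truncated integers for
  percentages) is applied only at the edge.
* Single-time-point datasets are constructible (a dataset is any validated
  series) but rejected by `net_changes()` with an insufficient-data error.
* Zero net change omits a compound from the table entirely, so it cannot
  acquire a role by floating-point accident.
* A compound column that does not resolve in the registry is an error, not
  a silent skip; registries are user-extensible by YAML but the CO₂ class
  rule for the six rule compounds cannot be reassigned.
* The flux solver processes species in an explicit reverse-topological
  order stored with each pathway; degenerate demands floor at zero rather
  than going negative.
* Seeded simulations save and restore the caller's RNG state.

# Problem sizes

Everything is desk-scale: the reference cultures are two-point series of
at most 11 compounds, and the property tests use 15-point simulations with
30–100 replicates (branch-coefficient recovery, mean absolute error
< 0.02 at 1 mM noise). The full suite runs in a few seconds on one CPU.

# Known limitations

* The glucose IBE electron recovery depends on an H₂ convention the
  package cannot reconstruct; only diagnostics are reported (above).
* The ledger is stoichiometric, not kinetic or thermodynamic: no ΔG,
  charge balance, pH speciation, or flux optimization.
* CO₂ estimation ignores carbonate equilibria and dissolved CO₂.
* The OD calibration is strain- and condition-specific; treat it as a
  fallback, not a measurement.
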