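---
title: "Methods: dynamic FBA coupled to bioprocess economics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic FBA coupled to bioprocess economics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyseep)
```

## The problem

Strain and process design for products such as poly-3-hydroxybutyrate (PHB)
cannot optimise yield alone: PHB shares acetyl-CoA and reducing power with
biomass formation and accumulates intracellularly, so pushing yield starves
growth, stretches the batch, and can destroy productivity.  The package
ranks *whole scenarios* — a yield together with its consequent final
biomass, titer and operation time — by the monthly gross profit they would
generate in a batch plant, and then asks what flux distribution (and hence
what genetic interventions) the best-ranked scenario implies.

## Constraint-based core

Flux balance analysis (FBA) solves

$$\max_\nu f^T\nu \quad \text{s.t.} \quad S\nu = 0,\;
\nu_{min} \le \nu \le \nu_{max}$$

over the stoichiometric matrix $S$ of a metabolic reconstruction.  Because
PHB is intracellular while FBA assumes intracellular steady state, the
polymer is produced through an artificial export reaction (the same device
as the artificial biomass drain); the exported monomer stream is
re-interpreted as stored polymer when titers and PHB content are computed.
The PhaA/PhaB/PhaC pathway inserted by `add_phb_pathway()` uses a standard
stoichiometry — thiolase condensing two acetyl-CoA, an NADPH- or
NADH-dependent acetoacetyl-CoA reductase, and the synthase releasing the
C4H6O2 monomer (86 g/mol) — and every enzymatic step is elementally
balanced against real cofactor formulas, which the test-suite checks.
Published augmentation scripts for the source reconstructions do not print
their proton/water bookkeeping, so minor divergence from any particular
published variant is possible; the balance checks pin down the variant used
here.

### The LP solver

FBA instances are a distinctly awkward kind of LP: a zero right-hand side,
many fluxes at active zero bounds, and linearly dependent rows from
conserved moieties make them maximally degenerate, which trips up
general-purpose simplex routines that assume non-degenerate pivots.  The
package therefore carries a bounded-variable two-phase primal simplex
written for exactly this shape (`R/lp.R`): Bland's anti-cycling rule, a
fresh factorisation of the basis at every iteration, and artificial
variables that absorb redundant mass balances.  This is a robustness-first
design: problem sizes here are tens of columns, where re-factorising is
microseconds.  It is *not* suited to genome-scale models
(thousands of columns); for those, objectives computed by this package were
designed to be cross-checkable against external solvers, and the test-suite
verifies the simplex against an independent HiGHS-based oracle on random
ensembles and on the toy network.

Alternate optima are the rule in FBA, so reported flux *vectors* are always
the parsimonious representative: a secondary LP minimises the sum of
absolute fluxes at the pinned optimal objective.  Objective values are
unaffected; flux values and hence DFBA trajectories become reproducible
across solvers and pivot orders.  Flux variability analysis (`run_fva()`)
pins the objective through a surplus variable (`f'v - s = fraction * opt`,
`s >= 0`), which is an equality at the default `fraction_of_optimum = 1`
because no feasible point can exceed the optimum.

Tolerances: pivot and feasibility 1e-9 inside the simplex; all scientific
comparisons in the tests use 1e-6 absolute.

## Uptake kinetics

Glucose uptake follows substrate-inhibited Michaelis-Menten kinetics,

$$v(C) = \frac{v_{max}\,C}{C + K + C^2/K_i},$$

with per-organism parameters shipped as defaults (mmol, L, h units):
*E. coli* $v_{max}$ 10.5 aerobic / 18.5 anaerobic, $K$ 0.015, $K_i$
8941.7, $v_{O_2,max}$ 15; *C. necator* 3 / —, 0.015, 11139.0, 5;
*S. cerevisiae* 22.5 / —, 4.884, 27102.6, 1.5.  The blank anaerobic cells
are deliberate errors when requested: neither organism grows anaerobically
in the corresponding reconstructions.  The inhibition constants originate
from fits to reported inhibition onsets and are used as given.  The rate
peaks at $C^* = \sqrt{K K_i}$ and declines beyond it, which is why batches
started at high glucose accelerate slightly as the substrate falls.

Oxygen gets no kinetics: dissolved oxygen is assumed controlled, so the
oxygen exchange lower bound sits at $-v_{O_2,max}$ throughout aerobic
operation (closed for anaerobic).  Nitrogen and other nutrients stay at
model-default, non-limiting bounds.  Glucose/gram conversions use
180.16 g/mol throughout.

## Dynamic FBA

The batch mass balances

$$\frac{dX}{dt} = \mu X, \qquad \frac{dS}{dt} = -\nu_S X, \qquad
\frac{dP}{dt} = \nu_P X$$

are integrated by the *direct approach*: the LP is embedded in the ODE
right-hand side and re-solved (warm-started from the previous basis) at
every integrator evaluation, with the glucose exchange lower bound tracking
$-v(C_{glc}(t))$.  DFBA systems are stiff near substrate exhaustion, so the
integrator is `deSolve::lsodar` — adaptive, implicit when needed, with root
finding.  Three roots terminate or switch integration:

* glucose depletion, $C_{glc} \le 10^{-3}$ mmol/L (the law gives $v \to 0$
  smoothly, so a hard threshold defines the operating time crisply);
* the cumulative-consumption target that switches a two-phase run from the
  growth objective to the production objective;
* metabolic arrest: if the LP becomes infeasible mid-batch (typically a
  fixed synthesis flux outrunning the falling uptake capacity), all rates
  are set to zero and the event is recorded — it is a result, not an error.
  Initial infeasibility, by contrast, errors before integration.

Default tolerances are `rtol = 1e-7`, `atol = 1e-9`; the test-suite checks
that halving them moves the toy-batch outcome by far less than 0.1%
relative.  Yields are reported on the *initial*-glucose basis
(titer / 25 g/L at defaults) so that arrested batches remain comparable;
the residual substrate is reported separately.  `t_op` is the time of the
terminal event and productivity is titer / `t_op`, so
`productivity * t_op = titer` holds to machine precision.

Two open design points were resolved as follows.  In the production phase
of a two-phase run only the *objective* changes; growth is not forcibly
zeroed, the LP simply stops rewarding it (with a parsimonious solution this
sends biomass flux to zero whenever growth does not serve production).  And
the growth-associated scan fixes the flux through the PHB exchange rather
than an internal pathway step; at steady state they are equal, and the
exchange is the reaction every model variant shares.

## The toy network

`make_toy_model()` is a ~19-reaction aerobic heterotroph: glucose uptake,
lumped glycolysis + pyruvate dehydrogenase (2 acetyl-CoA, 4 NADH, 2 ATP,
2 CO2 per glucose), a homolactic overflow branch, transhydrogenase as the
NADPH source, lumped respiration at P/O = 2, acetate overflow, an ATP
maintenance sink, and a biomass reaction drawing 2 acetyl-CoA + 150 ATP +
2 NADPH per gram.  The coefficients were chosen once so that

* every optimum used in tests has a closed form from the balance algebra
  (e.g. maximum growth $g/13$ with oxygen slack, $(2g + 5 v_{O_2})/151$
  when oxygen binds, maximum product flux $\min(g, 2 v_{O_2}/3)$);
* the biomass yield (~0.43 g/g) and the emergence of overflow metabolism
  under oxygen limitation are realistic in kind.

It emulates the *structure* of the problem — a growth/product trade-off
through shared acetyl-CoA and NAD(P)H, oxygen-limited overflow, arrest when
production outruns uptake — but not genome-scale degeneracy, realistic
maintenance coefficients, or byproduct spectra.  Tests passing on the toy
network therefore validate the machinery and its invariants, not the
numerical claims about any particular organism, which require the published
genome-scale reconstructions as inputs.

## Economics

Per batch, gross profit is $GP = R - (RM + OP + US + DS)$ and the monthly
gross profit is $MGP = GP \cdot N_{bat}$ with the real-valued batch rate
$N_{bat} = 720/(t_{op} + 12)$.  Revenue applies 97% recovery and 98%
purity to the titer at 5.5 USD/kg.  Raw material charges the fixed 5000 kg
glucose allotment (350 USD/ton), identical across scenarios by design.
Operating costs follow standard stirred-tank design relations: isentropic
compressor power on the inlet air flow implied by $OUR = v_{O_2,max} X(t)$
at 20% bubble transfer efficiency; stirring power from inverting
$k_La = 0.002 (P_S/V)^{0.7} V_{super}^{0.2}$ against the $OTR = OUR$
balance; anaerobic stirring as the constant $c\rho N^3 d^5$ at 50 rpm;
metabolic heat at 0.50 kJ/mmol O2 (aerobic) or 235 kJ/mol glucose
(anaerobic).  Downstream: homogenization 0.35 kWh/kg CDW, centrifugation
0.5 kWh/m3 over three passes, extraction 9.25 L solvent/kg CDW, drying
2 kg steam/kg PHB, wastewater 0.5 USD/m3.

Three places required committing to a convention that the underlying design
sources leave open, and each is a documented single knob in
`econ_parameters()`:

* **Cooling conversion** — heat is priced as electrically driven chilling
  at a coefficient of performance of 4 (`heat$cooling_cop`).
* **Oxygen-transfer driving force** — saturation minus held setpoint,
  defaults 7.0 and 2.0 mg/L; a configurable kLa ceiling (0.2 1/s) flags
  physically implausible scenarios instead of silently pricing them.
* **CDW bases** — homogenization processes total biomass (cells +
  polymer), extraction the residual cells; both are configurable because
  "per kg CDW" coefficients are ambiguous between the two.

The mineral-medium recipe is priced per compound with overridable default
prices; upstream cost is constant across scenarios by contract, so none of
these choices can change a sweep's internal ranking — they shift all rows
together.  Absolute profit levels do depend on them.

## Scan procedures

`sweep_growth_associated()` fixes PHB fluxes over integers 0..floor(max)
plus the exact maximum (the maximum found by FBA with the PHB objective
under the initial-condition uptake bound); `sweep_two_phase()` walks the
growth-phase glucose allocation from 100% to 0% in 10% steps.  Both grids
are overridable and both sweeps evaluate rows independently (failures are
marked per-row and the scan continues).  A realistic PHB-content cap of
85 wt% restricts only the *selection* of the best row, never the
simulations, and the breakeven row is the first grid point with
non-negative monthly profit.  The all-glucose-to-product extremes of the
two scans describe the same process; they agree to within ~1% rather than
exactly, because the fixed-flux variant arrests just before full depletion
(the pinned flux becomes infeasible at vanishing uptake) while the
production-phase variant runs to the depletion threshold.

## Project finance

Equipment costs scale by the six-tenths rule and CEPCI inflation to the
824.5 base index, then the standard factor chain (installation 0.50,
piping 0.40, instrumentation 0.35, insulation 0.03, electrical 0.15,
buildings 0.45, yard 0.15, auxiliary 0.50 on purchase cost; engineering
0.25 and construction 0.354 on TPDC; contractor 0.05 and contingency 0.10
on TPC; working capital 0.10 and start-up 0.05 on DFC) assembles the total
investment.  The cash-flow construction is the one structural assumption:
straight-line depreciation on DFC less 5% salvage, tax at 34% on profit
after depreciation, depreciation added back to the net cash flow, salvage
realised in the final year, total investment as the year-0 outlay.  ROI and
payback are exact reciprocals by construction; IRR is found by bracketed
root-finding on (-0.99, 10) and reported as undefined when the profile
admits no sign change.  The shipped equipment list
(`inst/extdata/equipment_synthetic.csv`) is a synthetic example sized for a
295 m3 vessel — reference costs are plausible placeholders, not sourced
data, and real assessments should supply their own list.

## Intervention suggestions

`constrain_with_yields()` turns experimental yields into pinned exchange
fluxes (g/g at a given uptake, converted through molar masses), and
`diff_fva()` compares the FVA envelope of that reference with the envelope
of the best-ranked scenario: reactions active in the reference but pinned
to [0,0] in the target are knockout candidates, reactions whose target
minimum strictly exceeds the reference minimum are forced minima
(overexpression candidates), sign-flipped ranges are reversals.  The
classification tolerance is 1e-6 mmol/gCDW/h — the LP noise floor — and
reactions present in only one model are reported separately rather than
classified.

## Problem sizes and limitations

The test-suite and the acceptance script run entirely on the toy network:
~24 reactions, batch integrations of a few hundred LP solves each, full
sweeps of 11 scenarios in a few seconds.  Genome-scale reproduction
(growth rates and scenario tables of the published reconstructions) is
implemented but requires the model files as user-supplied inputs and an
LP backend suited to thousands of columns; the built-in simplex is not.
Further limitations are inherited from the method: stoichiometric models
predict neither polymer properties (molecular weight, crystallinity) nor
regulatory effects, fed-batch operation is out of scope, and oxygen is a
constant bound rather than a dynamic state.
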