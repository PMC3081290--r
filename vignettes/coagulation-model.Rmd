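---
title: "A mass-action model of blood coagulation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mass-action model of blood coagulation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coagsim)
```

## The model

coagsim simulates the onset of blood coagulation as a deterministic
mass-action reaction network. Writing $c$ for the vector of species
concentrations (mol/l), $S$ for the species-by-reaction stoichiometric
matrix and $v(c)$ for the vector of reaction rates,

$$\frac{dc}{dt} = S\,v(c),$$

where every rate is a signed sum of monomials
$\pm k \prod_j c_j$. This restricted rate-law form — no Michaelis–Menten
or Hill terms — covers the entire network, including reversible binding
written as a single reaction with a forward and a backward monomial, and
it is what makes an exact analytic Jacobian cheap to assemble (see
*Numerics* below).

The network has 58 species and 59 reactions before any drug is attached,
organised in groups:

* **Extrinsic (tissue-factor) core** — 32 reactions (`R1`–`R32`)
  following the classic TF-pathway scheme: TF binding of factor VII/VIIa,
  extrinsic tenase (TF·VIIa) activation of factors IX and X, intrinsic
  tenase (IXa·VIIIa), prothrombinase assembly on phospholipid
  (`Xa_Va_lipid`), meizothrombin (mIIa) as the intermediate of
  prothrombin activation, TFPI and antithrombin (ATIII) inhibition.
  Reaction `R9` (factor Xa activating prothrombin in solution) carries
  the historical rate-constant name `k16`.
* **Contact (intrinsic) pathway** — XIIa-driven activation of factor XI,
  XIa activation of factor IX, a membrane-dependent bootstrap activation
  of factor X by IXa, thrombin feedback on factor XI, and first-order
  XIIa decay standing in for plasma C1-inhibitor (rate constants
  `Kog*`).
* **Fibrinogen cleavage** — thrombin and meizothrombin cleave fibrinogen
  (species `I`, 7 µM in plasma) to the fibrin monomer pool `Ia`; `Ia` is
  the clot-detection species.
* **Protein C/S feedback** — thrombin–thrombomodulin activation of
  protein C, protein S cofactor binding, and APC·PS inactivation of Va
  (free, membrane-bound and prothrombinase-protected) and VIIIa
  (`RBu*`).
* **Phospholipid adsorption** — the species `PhosphoLipid` is a pool of
  protein-binding *sites* on phospholipid vesicles at 333 lipid
  molecules per site; Xa, IXa, Va and XIa adsorb reversibly, and
  solution/membrane duplicates (`R9d`, `R21s`, `R28d`) let components
  react in either state.
* **von Willebrand factor** — factor VIII circulates vWF-bound and is
  released on thrombin activation.

### Provenance of the parameterisation

The kinetic constants and plasma initial conditions are a
**reconstruction assembled from the published literature models** the
scheme is based on (the Hockin–Mann TF-pathway model, Kogan-type contact
kinetics, Stevens-type fibrinogen cleavage, Bungay / Kuharsky–Fogelson
protein C and adsorption treatments), not a verbatim transcript of any
single published table. Every parameter in the shipped model file
(`inst/extdata/coagulation_model_synthetic.json` — "synthetic" labels
exactly this status) carries a provenance tag:

* `source-model` — taken from the cited literature model;
* `fitted-here` — adjusted during assembly of this package so that the
  virtual assays behave physiologically (e.g. the solution-phase
  Xa–ATIII rate `k38` is set below the upper-range literature value, and
  the enoxaparin-catalysed inhibition rates were calibrated so that
  therapeutic enoxaparin prolongs PT and aPTT only marginally, which is
  its clinical signature);
* `external-constant` — standard reference values such as molecular
  weights.

Consequences of this status are discussed under *What the model can and
cannot show*.

## Virtual assays

**PT.** All plasma concentrations (clotting factors, inhibitors, any
attached drug, and the albumin binding pool) are multiplied by 1/3 to
represent reagent dilution; 1% of factor V is preactivated; tissue
factor is set to 4 nM *final* in-assay concentration; the PT is the
first time fibrin (`Ia`) reaches 100 nM. With 7 µM plasma fibrinogen and
1/3 dilution that threshold is 4.29% of the available fibrinogen — just
above 4%, i.e. the onset of massive cleavage rather than its completion.

**aPTT.** Same dilution and FV preactivation; the trigger is 2.2 nM
factor XIa plus 50 nM factor XIIa. The clot criterion is deliberately
the same single fibrin threshold as for PT, keeping one consistent clot
definition across assays.

**INR.** PT with drug divided by drug-free PT, with an ISI exponent
of 1 (an idealised reagent). The drug-free control INR is exactly 1 by
construction.

**Thrombin generation.** Dilution 2/3, phospholipid binding sites set
from 4 µM lipid molecules, TF trigger 5×10⁻¹² M; the readout is the peak
free thrombin concentration. The 1% FV preactivation is also applied
here (it is part of the common in-vitro preparation in this package;
`assay_config()` exposes it). The assay horizon is 3600 s: at strongly
inhibited concentrations the thrombin peak arrives after 30 min, and a
shorter horizon would truncate it into an artificial cliff.

Trigger and reagent concentrations are treated as **final in-assay
values set after dilution**, because the assay recipe sets them together
with the already-diluted plasma; the reagent phospholipid for PT/aPTT is
10 µM lipid molecules (an excess, as in commercial reagents), a package
choice since only the thrombin-generation assay pins this value.

## Drug mechanisms

Four anticoagulants are kinetic species with explicit mechanisms
(`attach_drug()`):

* **rivaroxaban** — reversible complexation of free, membrane-bound and
  prothrombinase-bound factor Xa (6 reactions, `RBay*`), with
  literature association rate and inhibition constants for free Xa
  (kon 1.7×10⁷ l/(mol·s), Ki 0.4 nM);
* **DX-9065a** — the same Xa-directed pattern with its weaker constants
  (Ki 41 nM) (6 reactions, `RDx*`);
* **melagatran** (the active metabolite of ximelagatran) — reversible
  binding of thrombin, meizothrombin and the thrombin–thrombomodulin
  complex (4 reactions, `RXi*`);
* **enoxaparin** — catalytic: heparin activates antithrombin
  (`ATIIIa`), the activated complex inhibits Xa (free, lipid-bound,
  prothrombinase), IIa, mIIa, IXa and XIa, and the heparin chain is
  *released* in every inhibition step, free to activate another
  antithrombin (11 reactions, `RHep*`). The heparin moiety
  (free + bound + ATIIIa) is conserved while inhibited-protease
  complexes accumulate — a property the test suite checks.

Protein binding of every drug is a reversible complexation against the
dimensionless albumin-pool species `Albumin_Factor` (1 in undiluted
plasma), so plasma dilution automatically raises the unbound fraction.

**Warfarin** is never a kinetic species: it is an initial-condition
transform multiplying factors II, VII (including the trace of
circulating VIIa, which is the same vitamin K-dependent protein), IX and
X and proteins C and S by a common fraction *f*.
`warfarin_fraction_for_inr()` inverts the simulated INR for *f* by
monotone bisection on (0, 1] to a relative INR tolerance of 10⁻³.
Including VIIa in the reduced set matters: the strong-TF response
otherwise stays pinned to the preformed VIIa seed and vitamin K
antagonism looks artificially weak exactly in the safety-relevant
scenario.

Unit handling: µg/l and mg/l convert through molecular weights
(rivaroxaban 435.88, DX-9065a 571.66, melagatran 429.47 g/mol, stored as
external constants); enoxaparin uses the average 4500 g/mol and
100 anti-Xa U/mg, so 100 U/ml = 1 mg/ml = 2.22×10⁻⁴ mol/l.

## Flow coupling and the washout threshold

In vivo, the clotting region exchanges material with flowing blood. The
open system adds, for every mobile species $j$,

$$\frac{dc_j}{dt} = F_j(c) + \alpha\,D_j\,(c_{j,\mathrm{blood}} - c_j),$$

with a single diffusion–convection constant $D = 5\times10^{-7}$ cm²/s
for all transported species and a general coupling constant $\alpha$
(cm⁻²) set by flow and geometry; $\alpha D$ acts as a first-order
exchange rate (1/s). Species bound to immobile tissue or to the thrombus
— TF, every TF-containing complex, and fibrin `Ia` — are not
transported. The reservoir is the undiluted plasma state (attached drugs
included) with the trigger absent, so triggers wash out like any
perturbation. At $\alpha = 0$ the open system is exactly the closed
model, a property the tests assert to solver precision.

Only *relative* orderings of $\alpha$ and of the critical threshold
$\alpha_{crit}$ are interpreted; the absolute scale has no direct
experimental counterpart.

**Clot decision.** An in-vivo coagulation event is a crossing of either
of two independent thresholds within 3600 s: thrombin (IIa) ≥ 2 nM
(≈0.1% of plasma prothrombin) or fibrin (`Ia`) ≥ 100 nM (reusing the PT
criterion). The two threshold values are package choices exposed in
`clot_decision()`, since only the two threshold *species* are fixed by
the model design. The 3600 s horizon bounds the bisection inner loop;
"suppressed" means no crossing within it.

**$\alpha_{crit}$** is the lowest $\alpha$ that suppresses the event for
a given trigger scenario, computed by geometric bisection on a bracket
whose low end clots and high end suppresses (auto-expanded by decades if
the initial bracket is wrong), to a relative bracket width of 10⁻³ by
default (10⁻² in the benchmarking sweeps, where only orderings across
regimens are consumed). The reported value is the suppressing end of the
final bracket.

**Trigger scenarios.** Four in-vivo scenarios: extrinsic strong/weak
(TF 10⁻¹¹ / 10⁻¹⁴ M) and intrinsic strong/weak (XIIa 10⁻¹¹ / 10⁻¹⁴ M),
undiluted plasma. The strong extrinsic trigger (contact with
subendothelial tissue) is safety-relevant — excessive prolongation there
flags bleeding risk; the other three represent situations where massive
clotting should not occur, so *failing* to suppress them flags
thrombosis risk.

## Benchmarking and classification

`benchmark()` evaluates each dosing regimen (rivaroxaban 5–53 mg OD/BD,
ximelagatran as melagatran, DX-9065a constant infusion levels,
enoxaparin, warfarin titrated to INR 1.5–4) under all four scenarios,
for either metric (clot time at $\alpha=0$, or $\alpha_{crit}$), at
C_trough/C_mean/C_max plasma levels. Classification uses C_mean (the
spread is reported but not used for flags): a regimen is **safe** if it
does not exceed the warfarin INR-3 reference on the strong extrinsic
trigger (clot time ≤ reference; $\alpha_{crit}$ ≥ reference), and
**efficacious** if it reaches the warfarin INR-1.5 reference in *all
three* efficacy scenarios (clot time ≥ reference; $\alpha_{crit}$ ≤
reference). A scenario suppressed even at $\alpha = 0$ counts as maximal
prolongation/inhibition. `therapeutic_window()` aggregates flags over
total daily dose (x BD = 2x mg/day) and reports non-monotone flag
patterns instead of masking them — e.g. 10 mg BD and 20 mg OD share a
20 mg/day total but different C_mean levels, so their flags may
legitimately differ.

## Numerics

* **Solver**: `deSolve::lsoda` (switching stiff/non-stiff, BDF in the
  stiff regime) with rtol 10⁻⁸ and atol 10⁻¹⁴ mol/l; the network spans
  sub-pM to µM concentrations with fast binding, so stiffness is
  assumed. The Jacobian is assembled analytically from the monomial
  structure in compiled code, which is what makes a full PT run cost
  tens of milliseconds.
* **Clot detection**: in-vitro assays store a dense trajectory
  (1201 output points) and refine the threshold crossing by linear
  interpolation plus re-integration of the bracketing interval on a
  200-point grid; the in-vivo path uses the solver's root-finding
  (`lsodar`) and stops at the first crossing. The two agree to well
  under 0.5% (tested).
* **Negative concentrations**: output values within 100·atol of zero
  are clipped to zero; anything more negative raises an error, because
  beyond round-off a negative concentration indicates a model or
  parameter defect, not noise.
* **Determinism**: everything is deterministic; repeated runs are
  bit-identical.

Problem sizes used by the shipped tests and the acceptance script: the
full 58-species model for all assays, a 51-point concentration grid
(0–500 µg/l in 10 µg/l steps) for the thrombin-generation sweep, the
8 rivaroxaban arms plus the INR-1.5/3.0 warfarin references across all
four scenarios for the benchmarking (40 regimen×scenario cells per
metric), and $\alpha_{crit}$ bisection at relative tolerance 10⁻² there.

## What the model can and cannot show

The synthetic-parameter status matters for how results should be read.
The structure (pathways, mechanisms, assay and scenario definitions,
classification logic) is faithful; the quantitative constants are
literature-sourced and in part calibrated here. The package's own
computed behaviour (all numbers below are produced by the test suite and
`scripts/acceptance.R`, not assumed):

* drug-free PT ≈ 27.8 s and aPTT ≈ 41.5 s — the correct ordering and
  magnitude regime for diluted-plasma assays, though absolute times are
  reagent-dependent quantities that this reconstruction does not claim
  to match;
* the rivaroxaban thrombin-peak curve falls steeply at low
  concentrations and levels off, with a two-segment breakpoint at
  ≈180 µg/l;
* dose–response monotonicity holds for every drug in both assays; all
  four trigger scenarios clot at rest and are suppressed by sufficient
  flow; washout thresholds order by trigger strength and by
  anticoagulation intensity;
* under the clot-time metric, rivaroxaban regimens first reach the
  efficacy references in all three efficacy scenarios at a total daily
  dose of 20 mg, and the safety boundary also falls at 20 mg/day
  (20 mg OD safe, 10 mg BD and above-20 regimens not), so the window
  concentrates around 20 mg/day; under the $\alpha_{crit}$ metric the
  efficacy boundary is again 20 mg/day while the safety cut lands one
  dose step lower (10 mg/day). These boundary placements sit within a
  few percent of the warfarin references and should be read as
  sensitive to the reconstructed parameter set.

Known limitations: no platelets, no fibrinolysis, no spatial or
hydrodynamic resolution (flow is a single lumped exchange term), no
pharmacokinetic time courses (regimens are constant plasma levels),
calcium handled implicitly inside rate constants, and contact-pathway
inhibition lumped into first-order decays. The factor-sensitivity of the
INR to factor VII is muted because the preformed VIIa trace, not VII
conversion, seeds the diluted-plasma PT at a 4 nM TF trigger.
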