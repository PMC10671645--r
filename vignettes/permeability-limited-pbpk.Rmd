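---
title: "Permeability-limited whole-body PBPK: model, metrics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permeability-limited whole-body PBPK: model, metrics, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permpbpk)
```

## The model

`permpbpk` implements a whole-body physiologically based pharmacokinetic
(PBPK) model in which drug exchange inside every tissue is
permeability-limited rather than perfusion-limited. Twelve tissues (adipose,
bone, brain, gut, heart, kidney, liver, lung, muscle, pancreas, skin, spleen)
are each divided into four well-stirred subcompartments:

* **TC** — residual blood cells and **TP** — residual plasma, the blood
  trapped in the tissue vasculature;
* **EW** — extracellular water and **IW** — intracellular water.

Three blood pools (arterial, venous, portal vein), each split into plasma and
blood cells, close the circulation: arterial blood perfuses the typical
tissues; pancreas, spleen and gut drain into the portal vein, which joins the
hepatic artery to perfuse the liver; liver and the remaining tissues drain
into venous blood; venous blood perfuses the lung, which returns to the
arterial pool. That gives 12 × 4 + 3 × 2 = 54 states.

Three flux laws connect adjacent subcompartments:

* **Passive permeation** across each membrane (TC↔TP, TP↔EW, EW↔IW):
  `J = PS (C_a fu_a fi_a − C_b fu_b fi_b)`. Under the pH-partition
  hypothesis only unbound (`fu`), unionized (`fi`) drug crosses membranes,
  so the driving force is the free, unionized concentration difference.
  `PS` (L/h) is the permeability–surface-area product.
* **Active transport** on the cell membrane only (EW↔IW):
  unidirectional clearances, `J = CL_uptake C_ew fu_ew` into the cell and
  `J = CL_efflux C_iw fu_iw` out of it.
* **Metabolism** in any subcompartment, including residual and circulating
  blood: `J = CL_met C fu`.

Transporter and metabolic fluxes deliberately scale with `fu` alone and not
with `fi` — enzymes and carriers act on the unbound species regardless of
ionization. This asymmetry with the passive law is intentional and is
implemented literally.

Because every flux is linear in concentration, the whole body assembles into
a linear time-invariant system `dC/dt = A C + f(t)` (`assemble_system()`).
Two structural facts are used as correctness anchors throughout the tests:

* **Mass balance.** For every state `j`, the volume-weighted column sum
  `Σ_i V_i A[i,j]` equals `−CL_met(j)·fu(j)`. With no metabolism anywhere
  the system is *closed*: all column sums vanish, mass is conserved exactly,
  and `A` has eigenvalue 0 with a uniform right eigenvector — the
  even-distribution equilibrium.
* **Stability.** `A` is a compartmental (Metzler) matrix: no eigenvalue has
  positive real part.

## Dosing

Three regimens are supported (`dose_regimen()`): an IV bolus into venous
plasma (`C_vp(0) = dose/V_vp`), a constant-rate IV infusion into venous
plasma (running for the whole horizon unless stopped), and first-order oral
absorption, implemented as the analytic forcing
`Dose · Ka · e^(−Ka t)` into the **intracellular water of the gut**.
Bioavailability is 1 by construction; first-pass loss emerges from the
gut → portal vein → liver topology rather than from a bioavailability
factor. An explicit depot-state formulation is equivalent and is used as a
solver cross-check in the test suite (agreement to 1e-9 of the trajectory
peak). `Ka = 1` 1/h stands for fast and `Ka = 0.01` 1/h for slow oral
absorption.

## Derived metrics

* Tissue concentration: the volume-weighted mean of the four subcompartments.
* `Kp(t)`: tissue concentration over *venous plasma* concentration, the
  venous plasma serving as the surrogate of systemic plasma.
* `Vd(t)`: total amount in the body over `C_vp · BW` (L/kg). The tally
  includes the portal-vein blood. The classical definition omits it, and that
  variant is available (`include_portal = FALSE`), but only the full tally
  makes the closed-system equilibrium come out at exactly 1 L/kg; the
  literal variant undercounts by about `V_portal/BW` (≈ 0.004 L/kg here).
* Pseudo-steady state: after a single dose to an open system, the terminal
  phase in which all compartments decay with a common slope and
  concentration ratios freeze. `detect_pss()` declares it when all
  per-tissue log-slopes agree with the venous-plasma slope within a relative
  1e-3 and the relative drift of `Vd(t)` stays below 1e-4 per hour; `Vdss`
  is read off that plateau.

## The null case as calibration anchor

The reference parameterization assumes density 1 kg/L for all tissues and
blood and no binding or ionization (`fu = fi = 1` everywhere). Under these
assumptions classical steady-state theory predicts `Kp = 1` in every tissue
and `Vdss = 1` L/kg, so any departure of the dynamic `Kp(t)` or `Vd(t)` from
unity isolates what the permeability-limited dynamics add. The closed-system
null case (no metabolism, no transporters) reproduces `Kp = 1` and
`Vdss = 1.000` L/kg to numerical precision:

```{r null-case}
phys <- load_physiology()
r <- run_scenario(scenario_spec("iv_bolus", ps_fold = 10), phys)
round(r$vdss, 6)
range(r$kpss)
```

## Physiology: a reconstructed reference table

The shipped table
(`inst/extdata/physiology_human70_synthetic.csv`) is a 70 kg / 300 L/h
human reference physiology assembled from standard reference-man tissue
volumes and cardiac-output fractions, with residual-blood fractions in the
range reported for exsanguinated rat tissues and extracellular-water
fractions in the range used by whole-body PBPK platforms. It is labelled
*synthetic*: it is this package's own reconstruction, balanced exactly to a
70 L total volume and a 300 L/h cardiac output, not a transcription of any
single published table. Residual blood is split 45%/55% into cells/plasma
(hematocrit 0.45), and every blood flow is split the same way — flowing
blood is treated as homogeneous, so the cell fraction of flow equals the
hematocrit.

Quantities anchored by model *structure* — the closed-system equilibrium,
near-unity Kpss of fast tissues, infusion steady states with hepatic-only
metabolism — are insensitive to the details of this table. Bolus
pseudo-steady-state Vdss values are not: the terminal mode sits close to the
slowest tissue pole `(Q + CL)/V` (adipose, in this table), and the
pseudo-steady-state Kp of slow tissues grows like the reciprocal of the
distance to that pole. Two physiologies that agree in every balance can
therefore give bolus Vdss values tens of percent apart. Users comparing
against a specific published table should load it via
`load_physiology(path)`; the loader validates every flow and volume balance
and repairs sub-0.05 L print-rounding discrepancies by rescaling muscle (the
designated slack tissue).

## Numerical choices

* **Integration.** `deSolve::lsoda` with the analytic (constant) Jacobian,
  `rtol = 1e-9`, `atol = 1e-12` mg/L, on a log-spaced output grid (240
  points by default) that resolves both the first minutes after dosing and
  the terminal phase. Concentrations below `−10^3·atol` abort; values in
  `[−10^3·atol, 0)` are clamped to zero for metrics.
* **Exponential rescaling.** In many open-system bolus scenarios the spectral
  gap between the two slowest modes is small compared with the decay rate
  itself, so concentrations underflow long before the terminal ratios
  converge. `run_scenario()` therefore integrates `y = C e^{st}` with `s`
  set to the terminal rate (from the closed form below): the trajectory then
  tends to a constant, and `Kp`/`Vd` — ratios, invariant under the rescaling
  — can be read at arbitrary depth into the terminal phase. Horizons are set
  to ~15 spectral-gap time constants and extended four-fold (up to five
  times) if the plateau criteria are not met.
* **Closed forms.** `vdss_closed_form()` computes Vdss without time
  stepping: infusion from the steady-state solve `A C = −b`; bolus from the
  dominant right eigenvector of `A`; oral dosing from the particular
  solution `−(A + Ka I)^{-1} g` when `Ka` is slower than every system mode
  (flip-flop kinetics) and from the dominant eigenvector otherwise.
  `solve_analytic()` provides full closed-form trajectories through the
  spectral decomposition. Simulation and closed form are two independent
  routes to the same quantities; the test suite holds them to 0.5% on Vdss
  across all scenario grids and to 1e-6 on trajectories (where the solution
  is within ~6 decades of its peak — beyond that, comparisons probe the
  conditioning of the eigenbasis, not solver accuracy).
* **Flip-flop boundary.** With this physiology the all-tissue
  intracellular-metabolism bolus scenario has a terminal rate ≈ 1.18 1/h,
  slightly *faster* than the fast-absorption `Ka = 1` 1/h. "PO fast" is then
  genuinely absorption-limited, and its Vdss follows the flip-flop branch
  instead of matching the IV bolus — the bolus/PO-fast identity holds
  exactly in every grid cell whose terminal rate is below `Ka`, and the
  `flip_flop` flag marks the cells where the premise fails. Slow absorption
  (`Ka = 0.01`) is flip-flop in essentially every open scenario, which is
  why its Vdss values are reported with `t_pss` rather than asserted as
  converged equilibria.

## Scenario grids

`reproduce_table()` encodes four factorials over the standard regimens
(infusion 100 mg/h; bolus 100 mg; PO 100 mg at `Ka` = 1 or 0.01 1/h):
a permeability sweep (PS/Q ∈ {0.01, 0.1, 1, 10, 100}, applied jointly to the
TP↔EW and EW↔IW membranes, with intracellular metabolism CL = Q in all
tissues), hepatic-only metabolism by subcompartment (CL/Q_liver ∈
{0.1, 1, 10}), all-tissue metabolism by subcompartment (CL/Q ∈
{0.1, 0.5, 1}), and transporters (uptake/none/efflux at CL = Q, at low
0.1 Q and high 1 Q permeability, with IW metabolism CL = Q). Design choices
worth stating:

* The PS fold scales both tissue membranes jointly. The within-tissue
  TC↔TP membrane and the plasma↔cell exchange in the circulating pools
  stay at 1000 L/h (effectively instantaneous plasma/cell equilibration)
  unless overridden.
* The metabolism grids that do not sweep permeability use PS = 1 × Q as
  their baseline, which makes the permeability-sweep cell at PS = Q, the
  all-tissue IW-metabolism cell at CL = Q, and the no-transporter
  high-permeability cell one and the same compound — an identity the test
  suite asserts to 1e-6.
* "Low" and "high" permeability in the transporter grid are 0.1 × Q and
  1 × Q.

The grids reproduce the qualitative structure of permeability-limited
distribution: metabolism *raises* bolus Vdss (the opposite of the classical
extraction-ratio prediction, `reference_perfusion_model()`) while lowering
infusion Vdss; residual-blood metabolism moves bolus Vdss more than tissue
metabolism at matched clearance; uptake transporters raise and efflux
transporters lower Kp and Vdss, most strongly for low-permeability
compounds; hepatic-only metabolism pushes liver Kpss below 1 and every
non-metabolic tissue above 1.

```{r hepatic}
r <- run_scenario(scenario_spec("iv_bolus", ps_fold = 1, met_site = "iw",
                                met_tissues = "liver", met_fold = 1), phys)
round(r$kpss[c("liver", "lung", "kidney", "adipose")], 4)
round(r$vdss, 3)
```

## Global sensitivity analysis

`sobol_vdss()` estimates first-order (S1) and total-order (ST) Sobol indices
of Vdss over eight compound fold-parameters: metabolic clearance in each of
the four subcompartment types, the two tissue-membrane PS products, and the
uptake and efflux transporter clearances — all expressed as folds of each
tissue's blood flow. The baseline fold is 1% of tissue blood flow (an
alternative convention uses 10%; the baseline is a config parameter), and
each input ranges log-uniformly over baseline/10 to baseline×10 — the
distribution is symmetric in fold space, a choice this package makes
explicitly. The design is Saltelli's (n base samples → n(d+2) model
evaluations), with the Saltelli-2010 S1 estimator and Jansen ST estimator
and percentile-bootstrap confidence intervals. Model evaluations go through
the closed-form Vdss, which the test suite pins to the simulated value;
1000 base samples run in about a minute. Indices of `Vd(t)` on a coarse
time grid are available alongside the scalar endpoint via the `times`
argument. Everything is deterministic given the seed, and the global RNG
state is left untouched.

With the shipped physiology the rank structure at n = 1000 is: under
infusion the plasma↔EW permeability carries the largest total-order index,
and after a bolus the permeability folds and efflux outrank subcompartment
metabolism and uptake.

## What the synthetic data do and do not show

The toy-body generator (`make_toy_body()`) produces reduced physiologies —
liver, lung, gut plus generic tissues — with randomized volumes and flows
that satisfy every balance equation by construction, always retaining the
gut → portal vein → liver loop. Tests on toy bodies exercise the assembly,
conservation, and oracle-equivalence logic on hundreds of random instances,
which the single human table could not. They do not validate the human
physiology itself, nor anything the linearity assumption hides: saturable
transport or metabolism, lymphatic return, ionization/binding gradients
between subcompartments, or mechanistic oral absorption are all outside the
model by design.

## Problem sizes used by the test suite

The suite runs the full 54-state system throughout: the four scenario grids
(140 scenario runs, each a stiff integration plus an eigen solve), 100
random toy bodies, and Sobol designs at n = 48 for the determinism/coverage
contracts and n = 1000 for the rank statements. The complete suite finishes
in a few minutes on one core.

## Known limitations

* Linear kinetics only; no Michaelis–Menten saturation of transport or
  metabolism.
* The pH-partition hypothesis is taken literally; membrane-potential-driven
  permeation of ions is not modeled.
* No lymphatic circulation, endothelial or organelle subcompartments.
* First-order oral absorption is a deliberate simplification; flip-flop
  conclusions for very slow absorption depend on it.
* The shipped physiology is a reconstruction (see above); absolute bolus
  Vdss values are sensitive to it even where every balance is satisfied.
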