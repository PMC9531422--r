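---
title: "From perturbation measurements to flux control coefficients: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From perturbation measurements to flux control coefficients: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fluxcontrol)
```

`fluxcontrol` estimates how much control each enzyme of a reduced
*E. coli* network exerts over the steady-state fluxes of an L-tryptophan
production process.  This vignette is the package's own account of the
science: the models, their assumptions, the tunable parameters, the
numerical choices, and what the synthetic-data validation does and does
not show.

## The reduced network

The packaged model (`ecoli_trp_model()`) covers glycolysis and glycerol
dissimilation, the methylglyoxal (MGO) pathway, the TCA cycle, the
pentose phosphate pathway, L-serine biosynthesis and the
chorismate/L-tryptophan route, with exchange reactions for the four
perturbation substrates, product/by-product secretion and gas exchange —
53 reactions over 59 metabolites.  Only the network's size and pathway
inventory are documented, so the reaction list here is a reconstruction: linear segments without measured intermediates
are lumped (aconitase into isocitrate dehydrogenase, the succinyl-CoA
steps into one reaction, SDH+fumarase, PHGDH+PSAT, DHQ synthase+
dehydratase, shikimate dehydrogenase+kinase, G6P dehydrogenase+
lactonase), and the counts 53/59 are enforced as invariants rather than
guaranteed reaction-for-reaction identity with the original.

Three metabolite tiers matter for the mathematics:

* **balanced, measured** (39 species): these carry steady-state balances
  `S v = 0` and are the columns of the elasticity matrix;
* **measured cofactors** (ATP, NAD(H), NADPH, glutamate, phosphate):
  reported in the 45-species metabolome panel but excluded from balances —
  their poise is folded into effective Gibbs energies and kinetics;
* **extracellular and unmeasured currency species**: bookkeeping only.

Two regulatory edges named in the study are encoded and enter the
elasticity mask: feed-forward inhibition of indole-3-glycerol-phosphate
synthase by anthranilate, and inhibition of glycerol kinase by fructose
1,6-bisphosphate.

The `dg0_prime` column holds *effective* standard transformed Gibbs
energies (kJ/mol, pH 7.0, ionic strength 0.15 M, 310.15 K): curated
literature-scale values with the typical cofactor poise absorbed, since
cofactors do not contribute concentration terms here.  They are
synthetic in the sense of being chosen for the packaged model, not
measured for it.

## Thermodynamics-based flux analysis

For every covered reaction, `dG' = dG0' + RT * sum_i s_i ln(c_i/c0)`
over the balanced metabolites, and a nonzero flux must run downhill:
`v_j > 0` requires `dG'_j <= -epsilon` (default `epsilon = 1e-6` kJ/mol,
the strict-inequality surrogate inside the mixed-binary program).
Measured concentrations constrain `ln c` to mean ± 2 sd (floored at
1e-8 M); unmeasured metabolites default to 1e-7–1e-1 M, which covers the
physiological range.

Implementation choices worth knowing:

* **Loopless FVA first.**  The loop law is enforced only for reactions
  that can actually participate in an internal cycle — the support of the
  null space of the stoichiometry restricted to non-exchange columns,
  computed over *all* cytosolic species.  Including the currency species
  here is deliberate: an ATP-driven futile cycle has net cofactor
  turnover, is thermodynamically admissible, and must not be excluded;
  only genuinely closed cycles are.  Reactions whose loopless flux range
  collapses to `[0, 0]` are passed to TFA as fixed zeros.
* **Few binaries.**  A direction binary is introduced only where the
  feasible `dG'` range (over the concentration box) straddles zero;
  elsewhere the sign is fixed a priori.  With measured concentrations
  this leaves around 15 binaries on the packaged model, and the
  branch-and-bound solver warm-starts from the sign pattern of the LP
  relaxation, so most subproblems solve without branching.
* **Variance criterion.**  "99.9 %" is read as an optimality fraction:
  the growth objective is constrained to `>= 0.999 * z*` before
  per-variable minima/maxima are computed (`variability_at_optimum()`).
  `fraction = 0` reproduces plain FVA; ranges are nested in the fraction.
* **Sampling.**  `sample_flux_space()` fixes the directions of a TFA
  optimum and runs hit-and-run in null-space coordinates (warm-up 100
  steps, thinning 10), with the basis restricted to coordinates the
  bounds leave free.  The contract is approximate uniformity on the
  fixed-direction polytope, not a reimplementation of any particular
  sampler.
* **big_M = 1000** in flux units; the Gibbs couplings use tight
  per-reaction constants from the precomputed `dG'` ranges instead of a
  global big-M, which is what keeps the relaxations strong.
* **Solver.**  All programs go through a bundled dense bounded-variable
  primal simplex (two-phase, Bland's-rule fallback, periodic
  refactorisation) plus depth-first branch and bound.  At this problem
  size (a few hundred variables) a dense method is entirely adequate;
  the test suite cross-checks it against an independent LP implementation
  and against exhaustive enumeration of binary patterns.

O2 uptake and CO2 evolution constraints bound their exchange reactions
directly; because extracellular species carry no balances in the reduced
model, respiration constrains those fluxes but does not propagate through
carbon balances.  This is a known reduction artifact, stated rather than
hidden.

## Lin-log control analysis

During the 21-minute analysis window the proteome is taken as constant,
so every internal reaction keeps `e/e_ref = 1` and lin-log kinetics give

```
v_k / v_k_ref = 1 + sum_i eps_ki * ln(c_i / c_i_ref).
```

The regression for row `k` uses `y_m = v_km/v_k_ref - 1` against
`x_im = ln(c_im/c_i_ref)` over the 12 perturbed states, weighted by the
inverse first-order (delta-method) variance of `y`.  The allowed-nonzero
pattern (`elasticity_mask()`) contains each reaction's substrates,
products and declared effectors among the balanced measured metabolites,
with three refinements that each have a physical reading:

* feed-driven boundary reactions (substrate and O2 uptake) get empty
  rows — their rates are set by the pumps, not by intracellular
  concentrations — while secretion exchanges keep their intracellular
  substrate;
* reactions far from equilibrium (`dG0' < -15` kJ/mol) lose their product
  entries, since product elasticity vanishes with thermodynamic
  displacement;
* rows are capped at 4 stoichiometric entries (largest coefficients
  first; effectors always kept), and the biomass reaction is thereby
  restricted to its four dominant precursors.

With the mask in place, `C_S = -(S_R diag(v_ref) eps)^(-1) S_R diag(v_ref)`
and `C_J = I + eps C_S`, computed over the *measured, independent*
balanced metabolites (rows of the reduced stoichiometry `S = L S_R`).
Restricting to measured species is what keeps the linearized system
invertible, and both summation theorems survive the restriction exactly
because every retained row balance holds at the reference.  Reference
fluxes are projected onto the balance space before inversion — flux
estimates entering the analysis are balanced by construction, and the
theorems require `S_R v_ref = 0` exactly.  Reactions with zero reference
flux are excluded from `C_J`'s rows (a scaled FCC is undefined there)
but keep their zero columns in `C_S`, i.e. zero control.

Monte Carlo propagation (default 10,000 cycles; the demo configuration
and the test suite use 40–500) resamples concentrations lognormally
(matching mean and sd, hence strictly positive), fluxes normally with
truncation to the TFA ranges when available and re-projection onto the
balance space, and recomputes the whole chain per cycle.  Cycles with a
singular linearization are dropped and counted; more than half dropped
aborts the run.

## What the synthetic data can and cannot show

`make_ground_truth()` draws elasticities with thermodynamically sensible
signs — positive for species consumed at the reference flux direction,
negative for species produced and for declared inhibitors — and redraws
until the reference steady state is locally stable and well conditioned.
The reference point itself is anchored to a TFA solution of the packaged
model under the reference process rates (glycerol feeding at
2.17 mmol/gCDW/h, i.e. 0.2 g/gCDW/h; residual growth 0.02 1/h; product,
acetate and respiration rates at process-scale values), with a direction
profile that keeps every pathway of the network active, as the measured
flux maps of the production state show.  The three alternative substrate
uptakes get small nonzero reference fluxes: a lin-log reference must
carry flux in every direction the design perturbs, because a scaled
deviation from a zero flux is undefined.

The perturbation generator imposes the published feed profiles
quantitatively: the biomass-specific uptake of stage *g* equals feed
rate × feed concentration / (reactor volume × biomass), with the
analysis reactors at 0.5 L and 25 g/L CDW (a chosen operating point of
the right magnitude; the source reports only reactor hardware and feed
settings).  During a perturbation only the fed substrate's uptake is
nonzero — the analysis medium carries no other carbon source.  Noise is
multiplicative lognormal at 5 % CV on rates and metabolome by default,
with truthful standard deviations recorded.

One structural property of this design deserves emphasis: all twelve
states differ from the reference only through four boundary channels, so
the concentration responses span (at most) a four-dimensional space.  On
the packaged 53-reaction model some elasticity rows are therefore not
identifiable from the design — exactly as in the real experiment — and
those rows fall back to flagged minimum-norm (ridge `1e-6`) estimates.
The end-to-end recovery validation (noise-free exactness to 1e-6,
Monte Carlo interval coverage ≥ 90 % at 5 % CV over 100 replicates)
therefore runs on `toy_branched_model()`, a four-uptake network in which
the design spans the full response space by construction.  Passing those
checks shows the estimator chain is correct and calibrated; it does not
show that the 12-state design identifies every elasticity of a
53-reaction network, which it provably cannot.

The fed-batch simulator mirrors the three-phase 15 L process: 4 g/L
glycerol batch, exponential feeding (feeds A/B: 1.0 L at 120 g/L, 4.5 L
at 400 g/L) at a set-point mu of 0.07 1/h, and a constant phase (feed C,
800 g/L) dosed at 0.2 g glycerol per g CDW and hour fixed at the switch,
with induction there and leaky production (half strength) already in the
exponential phase, as observed.  Yields (Yxs 0.32 g/g, product yield
0.30 g/g, maintenance 0.03 g/gCDW/h) are chosen for process-scale
realism, not fitted.  Integration is fixed-step RK4 (`dt = 0.005` h)
with all consumption terms vanishing smoothly at substrate depletion
(half-saturation 5e-5 g/L for maintenance/production, Monod Ks 0.1 g/L
for growth), which is what lets the cumulative mass ledger close to
better than 1e-6 relative without clamping.  The MGO sub-model is
deliberately phenomenological — formation above a specific-uptake
threshold, production shut-off above 30 mg/L MGO — reproducing the
abrupt end of product formation; no mechanistic MGO kinetics are
claimed.  Off-gas is emitted with a fixed molar gas volume of
24.05 L/mol and a CPR/OUR ratio of 0.95.

## Numerical choices and degenerate inputs

* Rank decisions use a 1e-9 singular-value threshold; the stoichiometric
  reduction keeps the first independent rows in model order, so all
  matrices inherit the declared metabolite order.
* The regression declares a row under-determined at Gram-matrix rank
  deficiency (QR tolerance 1e-10) and then adds ridge `1e-6`.
* `rcond < 1e-12` declares the linearized system singular; the error
  names the metabolites dominating the near-null vector.
* Degenerate sampling polytopes (zero chord in 20 random probe
  directions) return the unique point with a warning.
* Concentrations in generated data are floored at 1e-9 mM — a
  quantification floor; extreme lin-log excursions cannot produce
  non-positive measurements.
* Report rankings break ties lexicographically by enzyme id, making
  pipeline outputs byte-reproducible under a fixed seed.

## Problem sizes used in validation

The shipped validation uses the packaged 53-reaction model for the
thermodynamic-consistency and range-nesting checks, the toy four-uptake
network for recovery and coverage (100 replicate experiments × 500 Monte
Carlo cycles), five random ground truths for the finite-difference
cross-check of the analytic control coefficients (relative perturbation
1e-4, agreement to 1e-3), and 100 random stoichiometries for the
summation-theorem property.  The full-scale study configuration (10,000
cycles) is the package default for real analyses.

## Known limitations

* The packaged network is a reconstruction; its 53 reactions are
  faithful to the documented pathway inventory but not guaranteed
  identical to the original model's list.
* Gibbs energies are effective constants; no Legendre re-transforms for
  pH or ionic strength are applied, and transport/exchange reactions are
  exempt from thermodynamic coupling.
* Respiration bounds do not propagate into carbon balances (see above).
* Lin-log kinetics are exact in the generator by construction; with real
  (Michaelis–Menten-like) kinetics the linearization incurs bias that
  the coverage numbers here do not measure.  A mis-specification study
  can be built with the generator's machinery, but is not part of the
  shipped validation.
* The global toxic effect of MGO on the proteome is outside the method's
  scope; the MGO sub-model only emulates the break-off phenomenology.
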