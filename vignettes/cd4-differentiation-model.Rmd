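---
title: "Modeling cytokine-driven CD4+ T cell differentiation and Th17/iTreg plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cytokine-driven CD4+ T cell differentiation and Th17/iTreg plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cd4sim)
```

## The biological question

Naive CD4+ T cells differentiate into effector (Th1, Th2, Th17) or regulatory
(iTreg) phenotypes under the instruction of the surrounding cytokine milieu.
Each lineage is organised around a master-regulator transcription factor —
T-bet (Th1), GATA3 (Th2), RORγt (Th17), FOXP3 (iTreg) — that drives a
signature cytokine (IFN-γ, IL-4, IL-17, TGF-β/IL-10) and represses the
competing programs. The nuclear receptor PPARγ sits on the Th17/iTreg axis:
it restrains RORγt/IL-17 and supports FOXP3, so its activation state tips a
cell between the inflammatory Th17 and the regulatory iTreg program.
`cd4sim` implements this circuit as a deterministic ODE model together with
the in-silico experiments that probe it: lineage induction, agonist dose
scans, loss-of-function, and the Th17→iTreg plasticity switch.

## Model structure

The reference network (`build_reference_model()`) has **93 species, 52
reactions and 60 ODEs**. The 33 species without an ODE are boundary inputs:
eight external cytokines (IFN-γ, IL-12, IL-18, IL-4, IL-6, TGF-β, IL-2,
IL-23), two neutralizing antibodies (αIL-4, αIFN-γ), a PPARγ ligand pool,
twelve constant gene loci and ten constant kinase/phosphatase/cofactor pools
(JAK1-3, TYK2, MyD88, SHP, proteasome, SMRT, RXR, SMAD4). Boundary species
enter reaction rates but are held fixed (or scanned).

The 60 dynamic species are organised in conserved cycles, which mirrors how
flow-cytometry readouts saturate (percent-positive of a fixed pool) and
guarantees bounded, non-negative dynamics:

* **Receptor modules (8 × 3 species).** Each cytokine receptor is two chains
  plus a signaling complex: `ligand + chain1 + chain2 → complex` by mass
  action (the receptor-associated kinase pool enters as a constant catalytic
  factor) and first-order dissociation back to free chains. With unit chain
  pools, the steady complex level saturates in the ligand dose.
* **STAT/SMAD cycles (6 × 2 species).** Phosphorylation is a Hill function
  of the upstream receptor complex applied to the unphosphorylated pool;
  dephosphorylation is mass action through the constant phosphatase pool.
  STAT3 and STAT3-P are distinct species, so phospho-STAT3 is a readout in
  its own right. PPARγ (activated form) is a saturating inhibitor of STAT3
  phosphorylation.
* **Master-regulator cycles (5 × 2 species).** Activation of a precursor
  pool driven by the lineage's STAT (Hill, cooperativity n = 2) with
  multiplicative saturating inhibition `ki/(ki + I)` implementing the
  cross-lineage antagonism: GATA3 ⊣ T-bet, T-bet ⊣ GATA3, and
  {FOXP3, PPARγ, SMRT} ⊣ RORγt; STAT3-P ⊣ FOXP3. Two couplings encode the
  lineage logic rather than simple inhibition: RORγt activation carries
  SMAD3-P as a linear catalytic factor (Th17 requires IL-6 *and* TGF-β),
  and FOXP3 activation carries activated PPARγ as a catalytic factor (PPARγ
  supports FOXP3 induction). PPARγ itself is activated from its apo form by
  a ligand pool with basal tone, giving a naive activated-PPARγ level of
  0.25 a.u.
* **Cytokine cycles (7 × 2 species).** Signature-cytokine production driven
  by the master regulator (IL-17 additionally requires STAT3-P and is
  inhibited by FOXP3, PPARγ and STAT5-P; IFN-γ requires STAT4-P, which
  itself needs the IL-18 receptor complex as a catalyst — the Th1 AND-gate).

Every reaction rate is built from exactly two primitives with exact
semantics, `mass_action_rate()` (`k·Π level^stoich`) and `hill_rate()`
(`vmax·Dⁿ/(Kmⁿ+Dⁿ)·Π ki/(ki+I)`, bounded in `[0, vmax]`, evaluated through
`(D/Km)ⁿ` in log space so large Hill coefficients cannot overflow). A
reaction may additionally declare *catalysts*, species whose levels multiply
the rate linearly; this is the composition of the two primitives (a
unit-stoichiometry mass-action factor on a Hill term) and is the standard
`V·[E]·f(S)` form of COPASI-style kinetic laws. Activation reactions of
conserved cycles always list their substrate as a catalyst, so rates vanish
smoothly as a pool empties and no species can go negative.

## Units, parameters and calibration status

All levels are dimensionless arbitrary units (flow-cytometry-scaled
quantities, not molar concentrations); time is in hours. Pools are unit
sized. The kinetic constants shipped with the model are **package-calibrated**
(metadata tag `calibration = "recalibrated"`): they were chosen once so that
the model reproduces the qualitative stimulus→fate behavior of the
biological system, and the calibration module can re-fit any of them to
data. The important choices:

* Receptor binding/unbinding at 1/h and STAT (de)phosphorylation at ~1–2/h:
  signaling settles within a few hours, fast relative to transcription.
* Master-regulator and cytokine cycles at `vmax` 0.4–0.8/h against
  inactivation rates 0.04–0.1/h: lineage commitment takes tens of hours
  (RORγt reaches 95% of its Th17 plateau near t ≈ 12 h and the network is
  near steady state within the default 100 h horizon with 1000 output
  points).
* Hill coefficients: n = 1 at the signaling level, n = 2 for
  transcription-factor and cytokine induction (cooperative promoter logic).
* Inhibition constants set the circuit logic: STAT3-P ⊣ FOXP3 is strong
  (ki = 0.05) so the Th17 milieu holds FOXP3 low despite TGF-β; the PPARγ
  inhibition constants (0.4–0.5) let the basal tone (0.25 a.u.) restrain but
  not silence the Th17 arm, leaving room for both loss- and gain-of-function
  effects.
* The IL-23 receptor module is included as an input branch without a
  downstream target: the induction recipes never use IL-23, and a terminal
  branch provides a clean "no path to readout" control for the sensitivity
  module.

## In-silico protocols and their semantics

Canonical recipes (`canonical_recipe()`) apply a single saturating dose
(1 a.u.) per cytokine: Th1 = IFN-γ + IL-12 + IL-18 + αIL-4; Th2 = IL-4 +
αIFN-γ; Th17 = IL-6 + TGF-β; iTreg = IL-2 + TGF-β. Neutralizing antibodies
act at input resolution by clamping the effective level of their target
cytokine to zero — the simplest representation of neutralization consistent
with how the antibodies are used, avoiding explicit binding reactions.

Two perturbation semantics needed a decision:

* **Knockout** ("blocking downstream signaling") clamps the target species
  to zero in every rate evaluation and disables reactions it drives. We do
  *not* zero whole reactions in which the target appears as an inhibitor:
  that would delete the host reaction instead of releasing the inhibition
  and would invert the loss-of-function phenotype. Clamping releases
  inhibitions, kills catalytic contributions and zeroes driven Hill terms in
  one rule, and composing a zero-level agonist clamp with a knockout is
  idempotent.
* **Agonist dosing** clamps the activated-PPARγ node itself (the
  concentration that the dose scans vary), at *basal tone + dose*. Dose 0
  therefore reproduces the unperturbed cell exactly — the basal level is the
  model's own naive steady state of activated PPARγ, recomputed from
  whatever model (wild-type or knockout) is being perturbed.

`plasticity_switch()` commits the cell under the Th17 recipe until RORγt
reaches 95% of its plateau (default `t_switch`, ~12.5 h), applies the clamp,
and continues in the unchanged milieu; scans restart from a common state
unless a continue-from state is supplied.

## Phenotype classification

`classify_phenotype()` scores each lineage as the geometric mean of its
markers (master regulator + signature cytokine; FOXP3 alone for iTreg), each
normalized by that marker's level at the endpoint of its own canonical
induction (`classifier_reference()`), which puts markers with different
dynamic ranges on a common "fraction of full induction" scale. The call is
the top-scoring lineage only if it beats the runner-up by the dominance
ratio `r = 2` *and* exceeds a floor of 0.05 (5% of full induction);
otherwise the state is `naive_mixed`. The ratio is not constrained by any
measured quantity, so it is exposed as a threshold; the floor deliberately
breaks scale invariance below the detection limit so that a naive state
(all markers ~0) is never assigned a lineage by the noise ordering of
vanishing scores. For perturbed models the normalization is taken from the
wild-type model, so a knockout that abolishes FOXP3 scores as it should:
near zero.

## Numerical choices

* Integrator: deSolve's `lsoda` (stiff-capable) with `rtol = 1e-8`,
  `atol = 1e-10`; the right-hand side is evaluated by compiled C code from a
  flattened reaction plan, with a plain-R evaluator (`assemble_rhs()`) kept
  as an independent oracle — the two agree to ~1e-12 and the compiled path
  is ~100× faster, which is what makes swarm optimization affordable.
* Steady states are found by chunked integration (250 h chunks) until the
  RHS infinity-norm falls below 1e-8, and agree with long-horizon endpoints
  to 1e-6 on all four induction recipes.
* Sensitivities are central finite differences with step
  `max(delta_factor·|p|, delta_min)` (defaults 1e-4 and 1e-12), normalized
  to control coefficients `(p/y)(∂y/∂p)` on 100 h endpoints; zero-baseline
  readouts are reported unnormalized and flagged rather than divided by
  zero. Central differences are second-order accurate at negligible cost.
* PSO: global-best with inertia 0.729 and cognitive/social weights 1.494,
  reflecting bounds, searched in log10 space because rate constants span
  orders of magnitude. Full-protocol settings are 50 particles × 3000
  iterations; the recovery experiments in the test suite and acceptance
  script use 30 × 300, which on this model recovers four free parameters
  from 5%-noise data to well under 10% median error across seeds.

## What the synthetic generator does and does not emulate

`generate_calibration_dataset()` simulates stimulus-response experiments
(recipes → observed species at stated times) and corrupts them with
multiplicative log-normal noise, `sigma = sqrt(log(1 + CV²))`, median 1 —
unbiased in log space, with replicate CV equal to the requested CV (default
5%, a typical flow-cytometry replicate spread). It emulates the *shape* of a
calibration database: inputs are external doses, readings are
transcription-factor/cytokine levels. It does not emulate event-level
cytometry (gating, spillover, cell-to-cell variability), population
dynamics, or biological batch effects; a passing recovery test therefore
shows identifiability of the kinetics under the stated noise model, not
robustness to real-world measurement artifacts.

## Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` and the acceptance script run: four
100 h inductions (60 ODEs each); a 10-point agonist scan (100 h commitment +
100 h per dose); knockout comparisons for two lineages; the plasticity
switch plus a 4-dose late-time ordering; a full 101-parameter × 3-readout
sensitivity matrix (606 simulations); and five seeds of the 4-parameter PSO
recovery (30 particles × 300 iterations, two 48 h experiments per
evaluation). The whole battery completes in a few minutes on one CPU.

## Known limitations

* The network is a single-cell, instructive-signal model: no TCR-proximal
  signaling, co-stimulation, proliferation, cell-cell competition or
  stochasticity. Plasticity is modeled at the level of one cell's
  transcriptional state.
* Kinetic constants are qualitative re-calibrations, not measurements; all
  shipped behaviors are orderings and directions, and absolute levels should
  not be over-interpreted.
* The SBML reader covers the package's own rate-law grammar plus plain
  mass-action MathML; arbitrary foreign kinetic laws are rejected rather
  than guessed at.
* FOXP3⁺RORγt⁺ double-positive intermediates are visible as transient mixed
  states but are not a discrete classifier output.
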