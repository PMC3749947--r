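---
title: "Modelling HER1-3 dimerization, activation and trafficking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling HER1-3 dimerization, activation and trafficking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdimer)
```

## The model

`herdimer` implements a mass-action ordinary-differential-equation model
of activation of the HER/ErbB receptors HER1 (EGFR), HER2 and HER3 in
cells that co-express them at arbitrary levels.  HER4 is not modelled
(the mammary epithelial system the model targets does not express it).
The model tracks 17 molecular species — the ligands EGF (`E`, binds
HER1) and heregulin (`H`, binds HER3), five monomers (`R1`, `R1E`, `R2`,
`R3`, `R3H`) and ten dimers (`R11E`, `R11EE`, `R12E`, `R13E`, `R13H`,
`R13EH`, `R22`, `R23H`, `R33H`, `R33HH`) — in three compartments: cell
surface, early endosome (EE) and late endosome (LE), for 51 state
variables.  Biochemistry happens at the surface and in the EE; the LE
only accumulates dephosphorylated receptors before degradation, so LE
species contribute to receptor-mass observables but never to
phospho-observables.

Three rules generate the reaction network:

* **Ligand binding** is reversible mass action.  Binding kinetics are
  identical for a receptor alone or inside a dimer, with three
  context-dependent exceptions expressed as exact Kd ratios: EGF binds
  the HER1–HER2 dimer 60% more strongly than monomeric HER1 (Kd/1.6),
  HRG binds the HER2–HER3 dimer 25-fold more strongly than monomeric
  HER3 (Kd/25), and a bound HRG weakens EGF binding in the HER1–HER3
  dimer 3-fold (Kd×3).  We carry these contexts on the *off*-rate (the
  on-rate is diffusion-limited and less context sensitive, and off-rate
  modulation composes correctly with the collapse rule below), so the
  printed ratios hold exactly by construction.
* **Dimerization** is reversible mass action with a single
  diffusion-limited forward rate `kc` shared by all pairs; the ten
  dissociation rates per reactive compartment are free parameters.
  Dimerization requires a ligand-bound partner, with one exception: the
  ligandless HER2 dimerizes constitutively, giving basal `R22` at steady
  state.  Ligand-free HER1/HER3-containing dimers are absent by
  construction — basal pairing of these receptors is weak enough to
  neglect, and permitting it would create species outside the 17-species
  state space.  Loss of the *sole* ligand from a singly-liganded dimer
  destabilizes it instantly; we lump unbinding and collapse into one
  event yielding two free monomers, so unstable ligand-free intermediates
  are never tracked.
* **Phosphorylation** is not mechanistic: dimerization and
  trans-phosphorylation are fast relative to the sampling timescale, so
  each dimer converts to phospho-signal through a lumped, time-invariant
  phosphorylation factor `pf<ijc>` (receptor `i`, partner context `j`,
  compartment `c`).  There are 13 pf values per reactive compartment (26
  free); the HER3 homodimer pf values are identically zero because HER3
  is kinase-dead, so `R33H`/`R33HH` never produce pR3 signal.

**Trafficking.**  Surface species internalize with first-order rates
(`kt` for monomers, `ke` for dimers); EE species are recycled or sorted
onward and LE species degrade.  Given the endosomal exit rate `kx_i` and
recycling fraction `f_i` of species `i` and the sorting parameter
`delta_i` (ratio of LE entry to exit rates),

    kr_i = kx_i f_i (1 + delta_i)
    kl_i = kx_i (1 - f_i)(1 + delta_i)
    kd_i = kx_i (1 - f_i)(1 + delta_i) / delta_i

and because sorting precedes LE incorporation while all LE contents
degrade at one shared rate, every `delta_i` follows from the single free
value `delta_1` (EGFR monomer) through

    1 + 1/delta_i = kx_1 (1 - f_1)(1 + 1/delta_1) / (kx_i (1 - f_i)).

HER3 species traffic like HER2 species, and species containing HER2 or
HER3 use the HER2-class constants (HER2 retards internalization of its
dimers).  EE binding kinetics for HRG equal those of EGF (no separate
low-pH measurements exist).  Free ligand is never pinocytosed: the
extracellular concentration is clamped at the protocol dose, while
ligand released inside the EE re-binds there until it is lost on sorting
(routed to the LE and degraded; it contributes to no observable).  The
late-endosome ligand pools exist in the state vector for layout
regularity; with these rules they are the only states that can stay
identically zero.

The free parameters are exactly the 20 `ku`, the 26 `pf` and `delta1` —
47 in all.  Everything else (binding kinetics, `kc`, trafficking
constants, molecular weights for ng/ml→nM conversion) ships as a fixed,
versioned default configuration chosen from the mammary-epithelial
literature range: EGF–HER1 surface Kd ≈ 2.5 nM, HRG–HER3 surface Kd ≈
2 nM, weaker EE affinity at endosomal pH, `kc = 1e-4
(molecules/cell)^-1 min^-1`, faster internalization and lower recycling
for HER1-class species (`kt = 0.02`, `ke = 0.20`, `kx = 0.15`,
`f = 0.5` min^-1) than for HER2/3-class species (`kt = 0.01`,
`ke = 0.03`, `kx = 0.15`, `f = 0.85`).  No quantitative claim of the
package depends on these defaults beyond their realistic order of
magnitude; structural assertions use only counts and ratios.

## Observables and equilibration

The ELISA-equivalent observables are, per receptor: total phospho
(`pRt`, pf-weighted dimer abundances over surface + EE), internal
phospho (`pRi`, the EE part alone — experimentally isolated by acid
stripping of surface phosphate), and receptor mass (`mRt`, every copy in
every compartment, homodimer members counted twice).

Cells are equilibrated before stimulation: synthesis rates are solved so
each receptor's total copy number at the ligand-free steady state equals
the cell line's expression level.  For HER1 and HER3 this is a linear
three-compartment balance with a closed form.  HER2 homodimerizes
constitutively, so its branch is solved by a damped Newton iteration on
the four unknown pools (surface/EE monomer and dimer), with an
integrate-and-rescale fixed point as fallback.  Observables at t = 0 are
these steady-state values; note that basal `R22` gives a small nonzero
basal pR2 in HER2-expressing lines, which is the model's expected
behaviour for a constitutively dimerizing, kinase-active receptor.

```{r equilibrate}
params <- her_truth_parameters()
eq <- her_equilibrate(her_profile("parental"), params)
eq
```

The pertuzumab (2C4) blocking mode removes a fraction of cellular HER2
from the dimerization-competent pool — initial condition and synthesis
feed — rather than modelling antibody binding kinetics, because the
experimental antibody concentration sits far above its Kd.  Sequestered
HER2 still traffics at monomer rates (a documented assumption; it
affects only `mR2t`) and counts toward receptor mass, never toward
phosphorylation.

## The synthetic-data generator

No deposited measurements exist for this design, so the package ships a
generator that emulates the study layout from known ground truth: four
cell lines (HER2−3−, HER2+3−, HER2−3+, HER2+3+ at 200,000 HER1 and
2,000/600,000 HER2, 2,000/40,000 HER3 molecules per cell), EGF dose
series 0.6–30 ng/ml and HRG series 4–120 ng/ml sampled at 0/10/30/60 min
(total phospho), 2-h time courses at 12 ng/ml EGF and/or 40 ng/ml HRG
for all nine observables, and 95% HER2-block conditions at 10/30 min.
The printed design fixes only the dose ranges; the intermediate doses
(3, 12 / 12, 40) are package choices on a log-ish grid.  Noise is
multiplicative lognormal with mean one and a default CV of 10%,
reflecting typical ELISA replicate scatter, with at least two replicates
per condition and an optional detection floor.  The generator captures
the design's information content but none of the artefacts of real
plates (batch effects, total-protein normalization drift, heteroscedastic
floors), so passing recovery tests demonstrates correctness of the
estimation machinery on this design — not robustness to real-world
nuisance structure.

```{r synthesize}
dat <- her_synthesize(her_design_small("parental"), params, cv = 0, seed = 7)
head(dat, 3)
```

## Parameter estimation

Residuals are `(prediction − data) / scale(type)` with one scale per
measurement type (its maximum observed value), so phospho and mass
series contribute comparably; fit quality is the RMSE of this scaled
vector.  Rates and pf values are optimized in log10 space (their prior
ranges span 3–6 decades: `ku` in [1e-3, 1e3] min^-1, `pf` in [1e-6, 1]),
`delta1` in linear space on [0.1, 10]; the sampling ranges double as box
constraints for bounded Levenberg–Marquardt (`minpack.lm`).  Simulation
failures during a step return a large finite penalty residual (10, an
order of magnitude above any legitimate scaled residual) instead of
raising.  One subtlety matters in practice: the finite-difference
Jacobian step must sit well above integrator noise (`epsfcn = 1e-8`,
i.e. steps of ~1e-4 decades), otherwise Levenberg–Marquardt stalls in
the strongly correlated ku–pf valleys.

The landscape is multimodal — a too-stable dimer with a compensating pf
is a recurring local minimum — so estimation is progressive, and each
stage sees only the cell lines *and measurement types* its parameters
inform (otherwise the scaled residuals of the other receptors' trace
signals bias the stage optimum):

1. **Stage 1**: HER1-related parameters (4 `ku`, 4 `pf`, `delta1`) on
   the parental line's HER1 observables.  Many random candidates are
   screened with a single objective evaluation each, the best are run
   through bounded Levenberg–Marquardt, and the leading few are polished
   with a longer iteration budget — the global basin need not lead after
   capped exploration.
2. **Stage 2**: the R12/R22 block on parental + HER2+3− (HER1/HER2
   observables) and the R13/R33 block on parental + HER2−3+ (HER1/HER3
   observables).  Each new block is explored alone by screened
   multistart with everything else frozen, then polished jointly with
   the HER1 block.
3. **Refinement pass**: the HER1 block is re-explored from scratch with
   the cross blocks now fixed at their stage-2 estimates — its stage-1
   optimum is measurably biased by couplings through the then-unknown
   R12/R13 parameters — and the stage-2 blocks are refit once more.
4. **Stage 3**: each multistart run draws a random HER2–HER3 (R23)
   guess and fits that block on the HER2/HER3 co-expressing line, where
   it carries the most signal; every terminal point is scored on the
   full dataset.  The incumbent then goes through one block-coordinate
   cycle (HER1, R12, R13, R23 in turn, on all lines) before the final
   joint fit of all 47 parameters.  The block cycle matters: a direct
   47-parameter refinement from a merged start can trade one block
   against another along the strongly correlated ku–pf directions and
   strand the fit in a secondary valley, whereas per-block steps cannot.

Before stage 1 every free parameter is reset to the geometric middle of
its bounds, so recovery experiments cannot inherit information from the
template.  All randomness derives from one master seed.

Converged stage-3 solutions within 1.2× of the best RMSE are clustered
by k-means on standardized log-parameters, with k chosen by mean
silhouette width over k = 2–10 and ties broken toward the first maximum;
each cluster is summarized by its minimum-RMSE representative.  The
retention margin and the silhouette criterion are package defaults — the
original analysis did not print either choice.  `summary()` reports the
per-parameter log10 spread across retained solutions: wide spreads are
the expected signature of weakly identifiable parameters (R13-, R23-,
R22- and R33-related `ku`/`pf`), and the pipeline surfaces rather than
hides them.  The complementary, robust quantity is each dimer's phospho
signal (pf × abundance): representatives that disagree by orders of
magnitude in individual `ku`/`pf` still agree closely on per-dimer
phosphorylation.

## Dimer-level analyses

`her_decompose()` splits each receptor's phospho signal into per-dimer
contributions (surface + EE, consistent with the `pRt` definition),
reported at ligand-occupancy resolution and rolled up to receptor pairs.
`her_grid_scan()` maps predictions over a log-spaced HER1 × HER2 grid at
fixed HER3 (default 40,000 copies/cell — the narrow band in which
HER3-expressing lines cluster), and `her_panel_predict()` tabulates a
panel of expression profiles.  The standard evaluation point is t = 60
min after 30 ng/ml EGF + 100 ng/ml HRG co-stimulation: phosphorylation
is essentially stable past one hour, and those doses saturate both
receptors.  The shipped panel is an illustrative synthetic fixture, not
a literature compilation.

The two regression forms tie downstream kinase activation to the model's
outputs: `pT = b0 + Σ b_i pR_i` (receptor mode) and
`pT = b0 + Σ b_iji pR_iji` (dimer mode), fitted by ordinary least
squares.  Predictors are z-scored by default so that importance —
defined here as the absolute standardized coefficient, since the
original criterion is unprinted — is comparable across predictors;
collinearity is reported via the design condition number and
rank-deficient designs fall back to the documented minimum-norm
solution.

## Numerical choices and problem sizes

* Integration: `deSolve::lsoda` over a compiled C right-hand side;
  defaults rtol 1e-8 / atol 1e-10, relaxed to 1e-7 / 1e-9 inside the
  optimizer.  A pure-R stoichiometric-matrix formulation of the same
  network is kept as an independent oracle and cross-checked to 1e-12.
* Equilibration targets a relative steady-state residual below 1e-9 and
  matches expression totals to 0.1% or better (the HER1/HER3 branches
  are closed-form exact).
* Tiny negative trajectory values within 10× atol are clamped to zero.
* Desk-scale defaults keep the full test suite and examples inside
  minutes on a single core: the recovery experiment uses the reduced
  design (two doses per ligand, three five-point time courses, ~1500
  replicate records), 20 stage-3 multistarts and the staged iteration
  caps described above;
  grid scans default to 20×20 but are exercised smaller in tests.  The
  study-scale analogues (999 measurements, 500 multistarts) are reached
  by turning the same knobs up.

## Known limitations

* The fixed-rate defaults are literature-range choices, not fitted
  values; analyses that depend on absolute rate values should refit
  against real data.
* Extracellular ligand depletion, plate artefacts, HER4, pre-formed
  ligand-free HER1/HER3 dimers, membrane microdomains and mechanistic
  downstream signalling are all out of scope.
* Absolute dimer abundances are weakly identifiable from phospho + mass
  data alone; only the per-dimer phospho signals should be interpreted
  quantitatively.
* The 2C4 mode ignores antibody binding kinetics; at sub-saturating
  antibody doses a reversible-binding extension would be needed.
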