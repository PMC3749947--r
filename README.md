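# herdimer

Mechanistic modelling of HER/ErbB receptor dimerization and activation
in cells co-expressing EGFR (HER1), HER2 and HER3.

The HER receptor expression profile of a cell strongly shapes clinical
outcomes — HER2 is amplified in a quarter of breast cancers and HER3
drives resistance to HER-targeted therapy — yet the link from expression
levels to which *dimers* form and signal is not directly measurable.
`herdimer` closes that gap with a mass-action ODE model: ligand binding
(EGF to HER1, heregulin to HER3), combinatorial homo- and
hetero-dimerization of HER1-3, lumped phosphorylation readout, and
three-compartment trafficking (cell surface, early endosome, late
endosome).  It is aimed at systems biologists who want to predict
receptor phosphorylation and per-dimer signal for any HER expression
profile, fit the model to ELISA-style dose-response/time-course data, or
study the practical identifiability of such fits.

## The model in brief

17 species (ligands E and H; monomers R1, R1E, R2, R3, R3H; dimers
R11E, R11EE, R12E, R13E, R13H, R13EH, R22, R23H, R33H, R33HH) in 3
compartments give 51 state variables.  Receptor phosphorylation is a
linear readout over dimer abundances, e.g. at the cell surface

    pR1s = pf11es[R11E] + pf11ees[R11EE] + pf12es[R12E]
         + pf13es[R13E] + pf13hs[R13H] + pf13ehs[R13EH]

with compartment-specific phosphorylation factors `pf`.  Trafficking
rates derive from endosomal exit rates `kx`, recycling fractions `f` and
a sorting parameter `delta`:

    kr = kx f (1+delta),  kl = kx (1-f)(1+delta),  kd = kl / delta

with every species' `delta` tied to the EGFR monomer value `delta1`.
The free parameters are the 20 compartment-specific dimer dissociation
rates, the 26 pf values and `delta1` — 47 in all — estimated by
progressive multistart nonlinear least squares with k-means clustering
of the converged solutions.

## Worked example

```r
library(herdimer)

params <- her_truth_parameters()          # shipped configuration
eq <- her_equilibrate(her_profile("parental"), params)
eq
#> Pre-stimulation steady state for 'parental'
#>   total copies  HER1 200000  HER2 2000  HER3 2000
#>   synthesis (molecules/cell/min)  R1 1764.71  R2 2.99  R3 2.81
#>   relative steady-state residual 2.58e-18 (0 iterations)
```

200,000 HER1 copies per cell is the parental line's expression level;
the synthesis rate of ~1765 receptors/min is what sustains it against
internalization and degradation at steady state.

```r
sim <- her_simulate(params, her_profile("D20"), egf_ng_ml = 12,
                    hrg_ng_ml = 40, times = seq(0, 120, by = 5))
sim
#> HER activation simulation: 'D20', EGF 12 ng/ml, HRG 40 ng/ml
#>   25 sample times in [0, 120] min
#>   at t = 120 min:  pR1t 9.72e+03  pR2t 1.02e+04  pR3t 2.72e+03

head(her_decompose(sim, time = 60, level = "pair"), 6)
#>   receptor dimer      signal    fraction time_min
#> 1      pR1   R11   178.78129 0.016581145       60
#> 2      pR1   R12 10573.24737 0.980620236       60
#> 3      pR1   R13    30.17528 0.002798619       60
#> 4      pR2   R12  4978.78639 0.443661358       60
#> 5      pR2   R22  1712.10198 0.152565993       60
#> 6      pR2   R23  4531.15363 0.403772650       60
```

In the HER2+3+ (D20) line most EGFR phosphorylation comes from the
HER1-HER2 dimer, not the EGFR homodimer — the kind of dimer-level
statement the model exists to make.  Fitting and clustering:

```r
dat <- her_synthesize(her_design_small(), params, cv = 0, seed = 7)
fit <- her_fit(dat, n_starts = 20, seed = 1)   # ~15-20 min on one core
summary(fit)
coef(fit)["pf11ees"]    # recovered phosphorylation factor
```

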