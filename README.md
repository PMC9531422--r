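# fluxcontrol

Where does the control over a production flux sit in a metabolic network?
For an engineered *Escherichia coli* strain secreting L-tryptophan from
glycerol, the question is answered experimentally by briefly deflecting the
culture into a set of new metabolic steady states (parallel reactors, four
substrates, three staged limiting feeds each -> 12 perturbed states plus the
production process itself as the reference) and measuring extracellular
rates and 45 intracellular metabolite concentrations in every state.
`fluxcontrol` implements the complete computational chain that turns those
measurements into flux control coefficients:

1. **Biomass-specific rates** from fed-batch/perturbation time series
   (substrate uptake, product and by-product formation, OUR/CPR from
   off-gas balances, total-amount and dilution bookkeeping).
2. **Thermodynamics-based flux analysis (TFA)** on a packaged 53-reaction,
   59-metabolite reduction of *E. coli* central carbon plus aromatic
   amino-acid metabolism: mass balance `S v = 0`, measured-rate boxes,
   metabolite-concentration bounds, and the coupling
   `sign(v_j) = -sign(dG'_j)` with `dG'_j = dG0'_j + RT * sum_i s_ij ln c_i`,
   solved as a mixed-binary program after a loopless flux variability
   analysis; variability ranges at a 99.9 % optimality fraction and
   hit-and-run sampling of the feasible flux polytope.
3. **Lin-log metabolic control analysis.** With enzyme levels constant
   during the 21-minute analysis, each reaction obeys
   `v/v_ref = 1 + sum_i eps_i ln(c_i/c_ref)`; the scaled elasticities
   `eps` are estimated by weighted least squares across the 12 states, and
   the control matrices follow in closed form:
   `C_S = -(S_R diag(v_ref) eps)^{-1} S_R diag(v_ref)`,
   `C_J = I + eps C_S`.  Both summation theorems (rows of `C_J` sum to 1,
   rows of `C_S` to 0) and the connectivity identity `C_J eps = 0` hold
   exactly by construction.
4. **Monte Carlo uncertainty propagation** (default 10,000 cycles):
   concentrations resampled lognormally, fluxes normally within their TFA
   ranges and re-projected onto the balance space, with elementwise means
   and 2.5/97.5 % percentile intervals.
5. **Synthetic data.** A lin-log ground-truth generator reproduces the
   full experimental design (published feed concentrations and staged
   supply rates; three-phase 15 L fed-batch process with batch,
   exponential feeding at mu = 0.07 1/h, and constant feeding at
   0.2 g glycerol/gCDW/h, optional methylglyoxal break-off sub-model), so
   every step of the pipeline can be validated against analytic control
   coefficients.

The audience is metabolic engineers and systems biologists who want a
tested, scriptable version of this workflow, or a simulation bench for
perturbation-design questions.

## Worked example

```r
library(fluxcontrol)

res <- run_pipeline(run_config(seed = 5, n_cycles = 500,
                               outdir = "demo_run"))
glance(res$control)
#> # A tibble: 1 × 7
#>   n_fluxes n_enzymes max_cj_row_dev max_cs_row_dev condition_number mc_cycles mc_dropped
#>      <int>     <int>          <dbl>          <dbl>            <dbl>     <int>      <int>
#> 1       51        53       3.98e-13       4.39e-12           26707.       500          0

report_run("demo_run", top_n = 2) |> head(4)
#> # A tibble: 4 × 6
#>   flux_id  rank enzyme          fcc         lo       hi
#>   <chr>   <int> <chr>         <dbl>      <dbl>    <dbl>
#> 1 glyk        1 glyc_upt  1.000e+ 0  1.000e+ 0 1   e+ 0
#> 2 glyk        2 pgk      -7.04 e-17 -3.86 e-17 4.66e-17
#> 3 g3pd        1 glyc_upt  1.000e+ 0  1.000e+ 0 1   e+ 0
#> 4 g3pd        2 glyk      1.69 e-17  0         1.11e-16
```

Fifty-one flux rows by 53 enzyme columns of dimensionless control
coefficients; both theorem deviations are at numerical precision, and no
Monte Carlo cycle was singular.  In this simulated run the glycolytic flux
through glycerol kinase is controlled entirely by the glycerol supply
(FCC of 1) and not by the kinase itself — the signature of a feed-limited
process.  `autoplot(res$control)`
draws the FCC heatmap (enzymes by fluxes, red negative / blue positive).

A single quantity from the study's bookkeeping, the fold increase of the
methylglyoxal formation rate between the second and third glycerol feeding
stages:

```r
fold_change(0.002, 0.053)
#> [1] 26.5
```

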