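# grazesev

Hierarchical Bayesian occurrence models and grazing-severity curves for
canopy-gap × ungulate disturbance interactions.

## The problem

In forests with heavy ungulate grazing, canopy gaps do more than admit
light: by triggering germination from the soil seed bank, they expose a
normally protected part of a plant population to grazers. To quantify this
interaction, paired exclosure/grazing surveys record the presence/absence
of each palatable plant species in 1 × 1 m quadrats — both aboveground and
in the germinable seed bank — together with canopy openness (%) and ground
slope (°) per quadrat.

`grazesev` implements the two-step analysis such surveys call for:

**Step 1 — occurrence model.** For species *s* in quadrat *q*,

    y_sq ~ Bernoulli(p_sq)
    logit(p_sq) = β0 + βT·T_q + βO·O_q + βTO·T_q·O_q + βS·S_q
                  + u_pair(q) + v_s

with a treatment indicator `T`, canopy openness `O`, slope `S`, and
crossed random intercepts for site pair and species
(u ~ N(0, r_pair), v ~ N(0, r_sp)). Priors are weakly informative:
N(0, 10⁴) on fixed effects and a uniform hyperprior on each 1/r
(0 to 10⁹). The posterior is sampled by an adaptive Metropolis-within-Gibbs
sampler (C++ core) — by default three chains of 30,000 iterations, thinning
3, final 3,000 thinned draws per chain retained (9,000 pooled draws) —
with Gelman–Rubin convergence diagnostics (pass when all PSRF < 1.1).

**Step 2 — severity curve.** Each retained draw predicts occurrence
probabilities in exclosure and grazing plots along a canopy-openness grid
(default every 1% from 17 to 65), with slope zero and random effects
excluded. The grazing-severity ratio (exclosure ÷ grazing) is summarized
per grid point by its posterior mean and 2.5–97.5 percentile band; the
severity threshold is the smallest openness at which the band's lower
bound exceeds 1.

A synthetic-data generator reproduces the paired-plot study design
(5 pairs × 2 plots × 4 quadrats; 13 palatable seed-bank species,
36 aboveground), so the whole pipeline is testable by simulation and
parameter recovery without field data.

## Worked example

```r
library(grazesev)

# simulate a survey at the default design and generative truth
quadrats <- generate_design(study_design(), seed = 1)
dataset  <- simulate_occurrence(quadrats, true_parameters(),
                                n_species = 13, layer = "seedbank", seed = 2)

# fit the occurrence model (three chains x 30,000 iterations, ~10 s)
arrays <- build_design(dataset, layer = "seedbank")
fit <- run_mcmc(arrays, seed = 3)
fit
#> Hierarchical Bernoulli-logit occurrence model fit
#>   3 chains x 3000 retained draws (thin 3, 30000 iterations)
#>   pooled draws: 9000; max PSRF: 1.005 (converged)
#>  coefficient  median    q2.5   q97.5 significant
#>    intercept -2.7400 -4.7544 -0.9538        TRUE
#>    treatment  2.0565 -0.8384  4.9905       FALSE
#>     openness  0.0200 -0.0256  0.0649       FALSE
#>  interaction -0.0557 -0.1280  0.0152       FALSE
#>        slope -0.0756 -0.1430 -0.0127        TRUE
```

The medians sit near the generative truth (−3.4, 1.95, 0.01, −0.07,
−0.061); with a single 40-quadrat dataset the treatment and interaction
intervals are wide, which is exactly what the credible intervals are for.

```r
curve <- severity_curve(fit)           # 49-point openness grid
curve
#> Grazing-severity curve (exclosure_over_grazing), 49 grid points,
#> 9000 posterior draws
#>   95% CI never clears 1
#>  openness_pct mean_ratio ci_lo ci_hi
#>            17       3.28 0.565 10.72
#>            18       3.09 0.566  9.74
#>            ...
plot_severity(curve)                   # mean line + credible band
```

For file-based runs, `pipeline_simulate()`, `pipeline_fit()` and
`pipeline_severity()` execute the same stages from a YAML/list config
(writing CSVs, figures, logs and a reproducibility manifest), and
`inst/cli/grazesev.R` wraps them as `simulate | fit | severity | recover |
report` subcommands.

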