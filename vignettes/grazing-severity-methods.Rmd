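---
title: "Methods: hierarchical occurrence modelling and grazing-severity curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical occurrence modelling and grazing-severity curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grazesev)
```

## The scientific problem

Canopy gaps and ungulate grazing are two of the commonest disturbances in
temperate forests, and they need not act independently. Gap light triggers
germination from the soil seed bank; once germinated, seedlings of palatable
species are exposed to grazers. The seed bank — normally a refuge that makes
plant populations resilient to grazing — is thereby drained faster wherever
the canopy is open. `grazesev` quantifies this interaction from paired
exclosure/grazing plot surveys: presence/absence of each palatable species in
1 × 1 m quadrats, recorded separately for the standing vegetation
("aboveground") and for seeds germinated from soil cores ("seedbank"), with
canopy openness (%) and ground slope (°) measured per quadrat.

## Step 1: the occurrence model

For species $s$ in quadrat $q$, presence $y_{sq} \in \{0,1\}$ is modelled as

$$
y_{sq} \sim \mathrm{Bernoulli}(p_{sq}), \qquad
\mathrm{logit}(p_{sq}) =
\beta_0 + \beta_T T_q + \beta_O O_q + \beta_{TO} T_q O_q + \beta_S S_q
+ u_{\mathrm{pair}(q)} + v_s ,
$$

where $T_q$ is the treatment indicator (which level carries the 1 is set by
`treatment_coding`), $O_q$ canopy openness in percent, $S_q$ slope in
degrees, and $u_j \sim N(0, r_{\mathrm{pair}})$, $v_s \sim N(0,
r_{\mathrm{sp}})$ are crossed random intercepts for the exclosure/grazing
site pair and the species. Covariates are *not* rescaled, so coefficients
are per percentage point of openness and per degree of slope. The slope
term absorbs the tendency of seeds to wash off steep ground; the
interaction $\beta_{TO}$ is the quantity of scientific interest — it is what
makes grazing impact depend on openness.

Priors are deliberately weak and match common WinBUGS-era practice: each
fixed effect is $N(0, 10^4)$; each random-intercept variance $r$ has
$1/r \sim \mathrm{Uniform}(0, 10^9)$, which implies a density on $r$
proportional to $r^{-2}$ on $(10^{-9}, \infty)$. We implement that
hyperprior literally, truncation included (`prior_spec()`), and
`log_unnormalized_posterior()` is the single reference definition of the
target density, tested against an independent term-by-term summation.

### Sampling

The posterior is sampled by an adaptive Metropolis-within-Gibbs scheme
written for this package (C++ core): scalar random-walk updates for each
fixed effect and each random intercept, and a reflected random walk on
$\log r$ for each variance (reflection at the support floor
$\log 10^{-9}$). Proposal scales adapt toward a 35% acceptance rate during
burn-in only and are frozen afterwards, so the retained draws come from a
fixed, detailed-balance-preserving kernel.

Raw-scale covariates make the posterior strongly correlated (the intercept
with openness, the treatment main effect with the interaction), which cripples
coordinate-wise samplers. Internally the fixed effects are therefore sampled
in an orthogonalized basis: with the thin QR decomposition
$X = Q R$ (scaled so $Q\sqrt{n}$ has unit-scale columns), the chain samples
$\gamma = R\beta$, the Gaussian prior is transformed into that basis exactly
(a correlated Normal with precision $R^{-\top}R^{-1}/10^4$), and every
retained draw is mapped back to $\beta = R^{-1}\gamma$ exactly. This is a
pure reparametrization — the posterior is unchanged — but it raises the
effective sample size of the fixed effects by roughly an order of magnitude
on the default design. `reparam = "none"` disables it.

### Protocol and bookkeeping

Defaults (`mcmc_settings()`): three chains, 30,000 iterations each,
thinning interval 3, the final 3,000 thinned draws per chain retained, so
the pooled posterior holds exactly 9,000 draws and everything before the
retained window (21,000 iterations) serves as burn-in and adaptation
window. The pooled 9,000 draws are what step 2 consumes. Chains start
overdispersed (fixed effects drawn $N(0, \texttt{init\_sd}^2)$ scaled per
covariate magnitude; per-chain seeds recorded in the fit object).

Convergence is judged by the classic Gelman–Rubin potential scale
reduction factor, computed from first principles for every stored
parameter (`gelman_rubin()`); the run passes when every PSRF is below 1.1.
A failure is a warning on the fit and an error in the pipeline (unless
`allow_nonconverged`), never silent. Coefficients are reported as posterior
medians with 2.5/97.5 percentiles (type-7 linear interpolation — the
quantile rule is fixed and documented because different conventions move
the bounds at the third decimal), flagged significant when the interval
excludes zero.

## Step 2: the grazing-severity curve

For each retained draw and each integer openness value on a grid (default
17–65%, 49 points — the observed openness range of the motivating survey),
`severity_curve()` computes predicted occurrence probabilities in the two
treatments with slope set to zero and random intercepts excluded, and takes
the ratio exclosure : grazing. Per grid point it reports the mean of the
ratio across draws (mean-of-ratio, not ratio-of-means) and the 2.5–97.5
percentile band. The severity threshold is the smallest grid openness at
which the band's lower bound exceeds one, i.e. where occurrence is credibly
more probable inside the exclosure; scanning is one-sided by default, with
an optional lower-tail detector (`lower_tail = TRUE`). Draws whose
denominator probability underflows to zero are excluded at that grid point
and counted, not silently lost.

A one-draw sanity anchor: at the fitted seed-bank posterior medians
(intercept −3.4, treatment 1.95, openness 0.01, interaction −0.07), the
treatment contrast $\beta_T + \beta_{TO} x$ vanishes at
$x = 1.95/0.07 \approx 27.9\%$ openness, so a degenerate posterior crosses
ratio 1 exactly there, while a dispersed posterior's *credible-band*
threshold necessarily sits later along the gradient — which is why
band-based thresholds land above the point-estimate crossing.

### The sign question

Under `exclosure_is_1` coding the median coefficients above make the
exclosure *less* occupied at high openness; under `grazing_is_1` the same
magnitudes describe grazing plots emptying as openness grows, which is the
ecological reading (severity ratio rising with openness and clearing 1 in
the mid-30s). Published coefficient tables do not always state the dummy
coding, and the two readings are exact mirror images
($\beta_0' = \beta_0 + \beta_T$, $\beta_T' = -\beta_T$,
$\beta_O' = \beta_O + \beta_{TO}$, $\beta_{TO}' = -\beta_{TO}$, identical
fitted probabilities). The package is therefore coding-agnostic: every
fitting and prediction function takes `treatment_coding`, the default is
`exclosure_is_1`, and tests exercise both readings. We make no attempt to
guess which coding produced any particular published table.

## The synthetic-data generator

`study_design()` / `generate_design()` / `simulate_occurrence()` emulate
the survey that motivates the package: 5 exclosure/grazing plot pairs, each
plot split into 4 quadrats (40 quadrats), canopy openness spanning 17–65%,
and 13 palatable seed-bank species (36 aboveground). Choices the survey
does not pin down are fixed once, as follows:

* **Openness structure.** Adjacent paired plots share canopy, so a
  pair-level mean openness is drawn uniformly on the range and quadrat
  values jitter around it (Normal, SD 5 percentage points, clamped to the
  range).
* **Slope.** Uniform per quadrat on 0–30°, a realistic range for forested
  hill slopes; the survey reports slope only through the model term.
* **Random-intercept SDs.** No fitted variances are available to anchor
  them; the defaults are 1.0 on the logit scale — a moderate, realistic
  between-pair and between-species heterogeneity — and fully configurable.
* **Randomness.** One integer seed per dataset; all draws flow from a
  single stream in a fixed order (pair effects, species effects, then
  outcomes row-major by species then quadrat), so a dataset is reproducible
  byte-for-byte from `(design, truth, seed)`.

The generator deliberately omits spatial autocorrelation beyond the pair
level, temporal dynamics, seed dispersal, and any mechanistic
germination/grazing process. Passing tests on synthetic data therefore
demonstrate that the *inference machinery* is correct under the model's own
assumptions — not that the model is adequate for any particular forest.

## What the tests establish, and at what problem sizes

* The C++ sampler targets exactly the reference density: on one- and
  two-parameter logistic models its posterior means and SDs match
  dense-grid quadrature of `log_unnormalized_posterior()` within Monte
  Carlo error, and with an empty likelihood its fixed-effect draws pass a
  distributional test against the $N(0, 10^4)$ prior.
* The default protocol converges on default synthetic data (all PSRF
  < 1.1, checked end-to-end), retains exactly 9,000 pooled draws and
  produces a 49-point severity grid.
* Parameter recovery is checked over 20 simulated replicates of the
  40-quadrat/13-species design at the generative truth above, with
  credible-interval coverage tallied per fixed effect and posterior
  medians compared against a maximum-likelihood cross-check
  (`lme4::glmer`, test suite only). Recovery fits use the default
  three-chain protocol at a reduced iteration count (15,000 per chain);
  unit tests use smaller designs and shorter chains chosen so the whole
  suite stays interactive.

A caveat worth stating plainly: at the default truth the model operates in
a rare-events regime (occurrence probabilities of a few percent, a handful
of presences per dataset, occasional quasi-separation between treatment
arms). With near-flat priors this is exactly where credible intervals at a
*fixed* truth can deviate from nominal frequentist coverage and where
posterior medians are heavy-tailed. The recovery suite measures this
honestly rather than smoothing it away; the maximum-likelihood cross-check
shows the same instability on the same datasets.

## Numerical choices

* Bernoulli log-likelihood terms use the stable form
  $y\eta - \log(1+e^{\eta})$ with the large-$\eta$ shortcut, so extreme
  linear predictors stay finite.
* The hyperprior support floor ($r > 10^{-9}$) is enforced by proposal
  reflection in $\log r$; the density includes the reciprocal-transform
  Jacobian and its normalizing constant.
* Initial values are redrawn (at most 10 times) if the posterior is not
  finite at the start, then the run aborts with advice to change seeds.
* Degenerate Gelman–Rubin inputs are defined, not NaN: all-equal constant
  chains give PSRF 1 with a warning; constant but disagreeing chains give
  `Inf`.
* Ties and thresholds: the severity threshold requires the band's lower
  bound to *exceed* 1 (strict), and grid endpoints are inclusive.

## Limitations

* The sampler is a general-purpose random-walk scheme; for much larger
  designs (thousands of species) a gradient-based sampler would be more
  efficient. At the survey scale it is comfortable (a full default fit
  takes seconds).
* Variance hyperparameters for factors with few levels (5 pairs) are only
  weakly identified; their posteriors lean on the $r^{-2}$ hyperprior tail
  behaviour.
* The severity curve deliberately zeroes random effects and slope; it is a
  population-level contrast at average site and species, not a prediction
  for any particular quadrat.
* Layers are fitted independently; the package does not model the
  seedbank–aboveground linkage itself.
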