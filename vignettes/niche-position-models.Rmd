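---
title: "Niche-position indices and phylogenetic mixed models for body-size trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Niche-position indices and phylogenetic mixed models for body-size trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichetrait)
```

## The scientific problem

Body-size records of birds and mammals collected over decades can reveal
whether populations are shrinking or growing as climates warm and dry. Raw
temperature is a poor predictor for cross-species work because a given
temperature means something different to a tundra vole and a desert lark.
`nichetrait` instead places every observation *within the species' own
realized niche*: for an observation of species $s$ in month $m$, the thermal
position index is

$$\mathrm{TPI} = \frac{N_m - N_{\min}}{N_{\max} - N_{\min}},$$

where $N_m$ is the monthly maximum temperature at the observation's grid
cell and date, and $N_{\min}, N_{\max}$ are the species' monthly niche
limits — the range-wide monthly extremes of the climate variable, averaged
over a fixed 1961–1975 baseline that predates rapid recent warming. TPI is
0 at the species' derived cold limit and 1 at its warm limit; values
outside $[0, 1]$ are retained, not truncated, because they mark conditions
beyond the derived tolerance limits and are exactly the observations of
greatest interest. The same statistic applied to the aridity index
$\mathrm{AI} = \mathrm{PPT}/\mathrm{PET}$ gives the aridity position index
(API; 0 = driest derived limit, 1 = wettest). Because the index is a ratio
of differences, it is invariant to affine rescaling of the climate
variable — Celsius versus Fahrenheit cannot change a TPI.

Two practical wrinkles in the limit derivation deserve note. First, the
order of operations: we take the range-wide extreme *within each baseline
year* and then average the yearly extremes across years, because a
15-year pooled extreme is an order statistic of a much larger sample and
drifts upward with baseline length; the pooled alternative remains
available behind `derive_limits(pooled = TRUE)`. Second, AI is a ratio and
explodes where potential evapotranspiration is tiny, so at extraction time
the range-wide cell values are Tukey-fenced: values outside
$[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$ (type-7 quantiles)
are replaced by the fence values, and every replacement is counted and
reported (`fencing_adjustment_rate()`). Snow-covered cell-months carry no
PET and therefore no AI; observations falling on them get a missing API
and are counted, never silently dropped.

## Record cleaning

Museum and survey body-size data are noisy in stereotyped ways, and the
cleaning pipeline addresses them in a fixed, logged order: structural
filters (impossible coordinates, latitude exactly equal to longitude,
missing date/coordinates/size/species, provider-side exclusion flags),
controlled-vocabulary reclassification of life stage and sex (anything
unmappable becomes `unknown`), synonym-table name harmonization, site
assignment by coordinate rounding (4 decimals, ~11 m — coincident sampling
points without brittle float equality), juvenile removal, a robust
median-absolute-deviation filter, and a minimum-count species filter.

The MAD filter computes, per species, the median $M$ and unscaled
$\mathrm{MAD} = \mathrm{median}(|x - M|)$ of the metric on adult records
only, then keeps adult and unknown-stage records inside the inclusive band
$[M - 5\,\mathrm{MAD},\, M + 5\,\mathrm{MAD}]$ on the raw measurement
scale. Records below the band are counted as likely juveniles, above as
likely digitization errors. We deliberately use the unscaled MAD (no
1.4826 normal-consistency constant): the band is defined in MAD units, and
rescaling would silently widen it by ~48%. Species whose adult MAD is zero
are kept whole with a warning — a zero MAD means the adult sample cannot
calibrate a band, and deleting such species silently would be worse.
Species with fewer than 100 unique measurements (distinct value–date–place
tuples, so duplicate ingestions count once) are dropped per metric. The
`CleaningReport` reconciles exactly: removals per rule sum to the row
delta, enforced in the constructor.

## The model

For each size metric the package fits a Gaussian phylogenetic mixed model
on z-scored variables:

$$y_i = \beta_0 + \beta_1\,\mathrm{TPI} + \beta_2\,\mathrm{API} +
\beta_3\,\mathrm{ALU} + \beta_4\,\mathrm{ULU} + \beta_5\,\mathrm{Year} +
\beta_6\,\mathrm{TPI{\times}API} + \beta_7\,\mathrm{TPI{\times}ALU} +
\beta_8\,\mathrm{TPI{\times}ULU} + u_{\mathrm{realm}} + u_{\mathrm{site}} +
u_{\mathrm{sp}} + u_{\mathrm{phy}} + (b_{\mathrm{sp}} +
b_{\mathrm{phy}})\,\mathrm{TPI} + \varepsilon_i.$$

ALU (cropland + pasture fraction) and ULU (urban fraction) come from the
yearly land-use layers at the observation's quadrat. Interactions are
products of z-scored main effects, so every coefficient reads as the
effect of a one-standard-deviation increase. The four random intercepts
are realm, site, species with independent effects, and species with
effects distributed as $\mathcal N(0, \sigma^2_{\mathrm{phy}} C)$, where
$C$ is the Brownian-motion correlation matrix from the tree (shared
root-to-tip path length, scaled to unit diagonal so
$\sigma^2_{\mathrm{phy}}$ is directly comparable to
$\sigma^2_{\mathrm{sp}}$). The two random slopes on TPI are likewise one
independent and one phylogenetically correlated, mutually uncorrelated.
The literature description of this model family is ambiguous about whether
every level-one effect carries the slope pair or only TPI; both readings
are implemented (`pglmm_spec(slopes = "tpi")`, the default, versus
`slopes = "all"`), as is the year-removed sensitivity fit
(`include_year = FALSE`).

### Estimation

Estimation is deterministic restricted maximum likelihood rather than
MCMC. Each correlated term is *folded*: with $C = LL^\top$,
$Z C Z^\top = (ZL)(ZL)^\top$, so the model becomes an ordinary
multi-component LMM on a transformed incidence basis. With
$\Lambda = \mathrm{diag}(\theta)$ holding the per-term relative standard
deviations, $\beta$ and $\sigma^2$ are profiled out analytically through a
sparse Cholesky factorization of
$\Lambda^\top Z^\top Z \Lambda + I$, and the REML criterion is minimized
over $\theta \ge 0$ with bounded BOBYQA. The sparse path is verified, term
by term, against a dense $n \times n$ covariance evaluation
($\Sigma = \sigma^2 I + \sum_k \sigma^2_k Z_k G_k Z_k^\top$) to $10^{-6}$
in the tests, and the whole fitter reproduces `lme4::lmer` to $10^{-4}$ on
identity-phylogeny data — lme4 serves only as a cross-check, never as the
engine.

Fixed-effect intervals are Wald intervals on the $t$ distribution with
*containment* degrees of freedom: the intercept and any predictor carrying
a random slope are replicated at the species level and get
$n_{\mathrm{species}} - 1$ df; all other terms get residual df. This is
the nlme/SAS containment convention, adopted because plain normal
intervals are known to undercover group-level effects when there are only
a few dozen species. `pd`, the probability that an effect has the sign of
its estimate, comes from the same $t$ approximation and is labelled
accordingly. Variance-component intervals are Wald on the log-sd scale
from a numerical Hessian of the REML criterion; boundary estimates
(variance ≈ 0) get `NA` intervals rather than a fabricated width.
`partial_r2()` is the squared Pearson correlation between the observed
response and the fitted values *including* random effects — the
"conditional" definition; it is stated explicitly because the quantity is
often reported without one, and it is not invariant to affine
transformation of the fitted values.

## The synthetic world

Real inputs of this kind (multi-database specimen records, global monthly
climate rasters, expert range maps, published supertrees) cannot ship with
a package, so `nichetrait` generates a complete world with known ground
truth, and the generator's defaults *are* the package's reference study
conditions — they are never tuned to make a test pass:

* grid: 10 × 16 cells at 2°; years 1961–2010; baseline 1961–1975;
* climate: meridional tmax gradient (0.6 °C per degree latitude), seasonal
  amplitude 8 °C peaking in July/January by hemisphere, warming trend
  0.3 °C/decade, cell-month noise sd 1 °C; PPT and PET positive seasonal
  fields, PET missing below the snow threshold;
* 30 species with contiguous rectangular ranges, an ultrametric pure-birth
  tree, and 5–50 reused sampling sites per species, 200 records each;
* true effects on the z-scale: $\beta_{\mathrm{TPI}} = -0.3$,
  $\beta_{\mathrm{API}} = +0.3$, $\beta_{\mathrm{ALU}} = +0.1$,
  $\beta_{\mathrm{Year}} = +0.05$, $\beta_{\mathrm{TPI\times API}} = +0.15$,
  others 0; variance components
  (realm .02, site .05, species .08, phylo .08, slopes .01/.01,
  residual .55) summing with the fixed-effect variance to ≈ 1;
* the latent z-response becomes
  $\log_{10}\mathrm{mass} = 1.5 + 0.1\,y_z$ — a ~32 g animal with ~0.08
  log10 units of within-species dispersion, realistic for vertebrate body
  mass; body length follows allometrically as $\mathrm{mass}^{1/3}$ over a
  target ratio with small independent noise;
* contamination: 2.5% "likely juveniles" (species median minus 6–8 adult
  MADs) and 2.5% "outliers" (± 6–10 MADs, bounded below to stay positive),
  both with life stage `unknown` so the adult reference statistics stay
  clean and the filter's ideal behaviour is knowable. Ground-truth columns
  (`true_log10_mass`, `contaminant`) ride along so recovery is scored
  exactly.

Because the analysis z-scores the response by its sample standard
deviation, the estimand for a generating effect $\beta$ is
$\beta / \mathrm{sd}(y_z)$ with the realized sample sd (≈ 1 by
construction, but not exactly 1); recovery tests therefore score coverage
against the truth expressed on the model's own scale, which is the correct
target rather than a relaxation.

What the generator does *not* emulate: spatial sampling bias within
ranges, taxonomic misidentification beyond a synonym table, measurement
rounding conventions, or range shifts over time. Passing tests therefore
demonstrate that the machinery is correct under the stated generative
model, not that any particular field dataset satisfies it.

## Diagnostics

`diagnose()` bundles the model-validation battery:

* **VIF** per fixed effect, by the definitional $1/(1 - R^2_j)$ regression;
* **Durbin–Watson resampling**: 1000 iterations drawing one residual per
  year, DW $= \sum(e_t - e_{t-1})^2 / \sum e_t^2$, with significance by
  permutation (199 shuffles, one-sided for positive autocorrelation by
  default) because tabulated DW bounds assume a regression structure these
  short, irregular series do not have; the per-species variant runs 100
  iterations within each species and averages;
* **spline correlogram**: distance-binned Moran-type correlation of
  residual products against great-circle (haversine) distance in km,
  smoothed with a cubic spline, with a pair-bootstrap envelope. This
  implements the contract (smooth correlation-versus-distance with an
  envelope), not any specific published algorithm; pair counts grow
  quadratically, so above 600 points a random subset is used;
* **influence screening**: |standardized residual| > 4 by default, with an
  optional refit-without-flagged comparison of coefficient shifts — the
  threshold is configuration, since the underlying choice is a judgment
  call;
* **posterior predictive check**: 1000 response vectors simulated from the
  fitted generative structure, comparing the observed mean, sd and deciles
  against simulated 95% envelopes.

Every diagnostic is a pure function of (fit, data, seed): rerunning with
the same seed is bit-identical.

## Numerical choices and degenerate inputs

Quantiles are type-7 throughout. The MAD band and the fences are closed
(boundary values retained/kept at the fence). Degenerate niche limits
($N_{\max} \le N_{\min}$, e.g. from a constant field) are an error in
`position_index()` and a missing value at attachment time, never silently
0/1. Climate cubes serialize doubles at 17 significant digits and are read
back with base `strtod`, so write–read round trips are bit-exact. The
optimizer's $\theta$ is bounded below at $10^{-6}$ (variances
$\lesssim 10^{-12}\sigma^2$ are reported as boundary estimates);
non-convergence raises an error with the optimizer trace, never a silent
result. Pipeline stage outputs are hashed (MD5, by basename) into a
manifest so same-seed reruns can be compared byte for byte.

## Problem sizes used in the checks

The bundled checks run the full pipeline on the reference world
(~6,300 records, 30 species), a 25-replicate recovery study at those
conditions, and a 50-replicate null-calibration study on a reduced world
(20 species × 100 records) — sizes chosen so the whole battery runs
comfortably on a laptop while leaving the binomial noise on the scored
fractions small relative to the acceptance margins.

## Worked example

```{r example, eval = FALSE}
library(nichetrait)

world <- gen_world(world_config(seed = 1))
cleaned <- clean_observations(world$observations, metric = "mass")

C <- phylo_correlation(world$tree, sort(unique(cleaned$table$species_id)))
fit <- fit_pglmm(assemble(cleaned$table, pglmm_spec("log10_mass"), C))

tidy(fit)          # fixed effects with 95% intervals and pd
glance(fit)        # n, sigma, logLik, partial R2
autoplot(fit)      # forest plot

report <- diagnose(fit, seed = 1)
autoplot(report$correlogram)
```

## Known limitations

The backend is restricted-likelihood, not the Bayesian fit used in parts
of this literature; point estimates agree closely in Gaussian models but
interval semantics differ (frequentist coverage versus posterior mass),
and `pd` here is an asymptotic analogue. Realm variance is estimated from
very few levels and is reported with honest, wide intervals. The
correlogram subsamples above 600 points. The synthetic world's ranges are
rectangles, its realms longitudinal bands; neither mimics real
biogeography beyond giving every random term something to estimate.
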