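# paleocarn

Bayesian inference of extinction dynamics from fossil occurrence data, built
around the question of what drove the decline of large carnivores in
Plio-Pleistocene East Africa: climate change, vegetation change, or
hominins. The package is a complete, tested implementation of that analysis
chain for anyone working with occurrence-level fossil data and candidate
environmental or biotic drivers.

## What it computes

**Occurrence-level birth–death inference with preservation.** Species
lifespans $(s_i, e_i)$ are latent; fossils accumulate over each lifespan as
a Poisson process with rate $q$, conditioned on each observed species having
at least one find (the point-process density
$n_i \log q - q d_i - \log(1-e^{-qd_i})$). Lineages originate at rate
$\lambda_0$ and go extinct at rate $\mu(t)$:

$$\log L = B\log\lambda_0 + \sum_{\text{extinct}} \log \mu(e_i)
  - \int N(t)\,(\lambda_0 + \mu(t))\,dt + \log L_{\text{preservation}}$$

Extinction-rate families: constant; piecewise-constant with estimated
shifts (the non-mechanistic null); linear or exponential functions of a
temporal covariate, $\mu_0(1+\gamma\tilde x(t))$ or
$\mu_0 e^{\gamma \tilde x(t)}$; and a threshold variant in which the
covariate acts only more recently than an estimated age $\tau$.

**Predictor curves from dated proxies.** Measurement dates are resampled
within their dating intervals 1000 times; a loess fit per resample is
evaluated on a 0–4 Ma grid and the pointwise median becomes the covariate
curve (temperature, precipitation, water deficit, forest cover, hominin
brain volume).

**Model selection over dating uncertainty.** Marginal likelihoods by
thermodynamic integration (tempered Metropolis–Hastings chains on a
Beta(0.3, 1) temperature schedule, warm-started, trapezoid-integrated),
Bayes factors on the $2\ln BF$ scale, and relative model probabilities,
replicated over uniform re-draws of every occurrence age.

**Contemporary spatial regression and back-casting.** The per-cell fraction
of carnivore species above 21 kg on an equal-area Behrmann grid, regressed
on standardised predictors by OLS and by a SAR-error model
($u = \lambda W u + \varepsilon$, maximum likelihood via the eigenvalue
log-determinant), with the neighbourhood chosen among 40 candidates by AIC;
the fitted coefficients are then projected onto the palaeo curves to ask
whether climate alone could have produced the fossil-derived decline.

**Range-through diversity by geological stage** for inter-continental
comparisons.

All inputs have synthetic generators (`simulate_fossil_record()`,
`simulate_proxy()`, `simulate_spatial_grid()`) so every stage is testable
end to end; the packaged tables under `inst/extdata/` are synthetic
stand-ins (prefixed `synthetic_`) built to the study's bookkeeping.

## Worked example

Rebuild the forest-cover and brain-volume predictor curves and compare
extinction models for the large guild on one age-resampling replicate:

```r
library(paleocarn)
extdata <- function(f) system.file("extdata", f, package = "paleocarn")

occ <- read_occurrences(extdata("synthetic_occurrences.tsv"))
attr(occ, "summary")[c("n_occurrences", "n_species", "n_extant")]
#> $n_occurrences  [1] 279
#> $n_species      [1] 88
#> $n_extant       [1] 9

brain  <- build_predictor(read_proxy(extdata("synthetic_proxy_brain.tsv")),
                          n_resamples = 1000, seed = 1, scale = TRUE)
forest <- build_predictor(read_proxy(extdata("synthetic_proxy_forest.tsv")),
                          n_resamples = 1000, seed = 2)
predictor_r2(brain, forest)
#> [1] 0.8649  # the two candidate drivers are nearly collinear in time

lg <- validate_occurrences(occ[occ$size_class == "large", ])
rep1 <- resample_ages(lg, replicate_id = 1, seed = 21)
mc <- mcmc_config(n_iter = 5000, thin = 10, ti_categories = 8, burnin = 0.25)
s_brain <- thermodynamic_ml(rep1,
             mu_covariate("exponential", 0.3, 0, curve = brain,
                          label = "brain"), mc)
s_const <- thermodynamic_ml(rep1, mu_constant(0.3), mc)
bayes_factor(s_brain, s_const)
#> [1] 34.1  # 2 ln BF: decisive support for brain-driven extinction
```

The number printed by `predictor_r2()` is the squared Pearson correlation
between the two median-loess curves; the Bayes factor is twice the
difference in log marginal likelihoods, on the scale where values above 2
are positive and above 10 very strong support. On the small guild the same
comparison yields a value below 2: a constant extinction rate is not
rejected there, the signature expected of a driver that affects large
carnivores specifically.

The `analysis/` directory holds the numbered workflow
(`01_simulate_data.R` … `06_backcast_diversity.R`) that runs the whole
chain at desk scale and writes its tables under `results/`.

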