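# radshoots

Hierarchical Bayesian analysis of radiocesium activity concentrations in the
growing shoots of coppice hardwoods.

After the Fukushima Daiichi accident, coppice woodlands that supply bed logs
for mushroom cultivation can only be used when the wood's radiocesium
activity concentration stays under 50 Bq kg⁻¹. Because concentrations vary
enormously between forest stands — far more than within them — the practical
questions are: *can the within-stand spread be treated as the same
everywhere?* and *how many shoots must be sampled in a stand to know its
level well enough?* This package implements the statistical machinery for
both questions for anyone planning or analysing vegetation radioactivity
surveys.

## The model

Log concentrations are modelled as normal within stands (concentrations are
log-normal), with stands as random effects:

    log(Y_i) ~ Normal(μ_s[i], σ_s[i]²)
    μ_s   = μ̄ + β·O + ε_M[s] + ε_S[sp]
    ε_M   ~ Normal(0, σ_M²)      (random stand effect on the mean)
    ε_S   ~ Normal(0, σ_S²)      (random species effect)
    σ_s   = σ̄                    (model 1: constant within-stand SD)
    σ_s   = σ̄·exp(ε_V[s]),  ε_V ~ Normal(0, σ_V²)   (model 2)

with `O` the stem origin (0 = coppice sprout, 1 = plantation) and vague /
weakly informative priors (`μ̄, β ~ Normal(0, 100²)`; every SD half-normal
with scale 10). Models are fitted by MCMC (conjugate Gibbs plus slice
sampling), convergence is checked with split-R̂ (< 1.1), and model 1 vs
model 2 is decided by WAIC computed for prediction *in a new stand* (stand
effects marginalised out of the pointwise likelihood).

For survey planning, the conjugate shrinkage formulas give, after `n`
measurements in a new stand with true mean `μ_s`,

    E[μ_n] = (μ̄/σ_M² + n·μ_s/σ̄²) / (1/σ_M² + n/σ̄²)
    sd[y_next] = sqrt(σ̄² + 1/(1/σ_M² + n/σ̄²))

which quantify how fast extra shoots sharpen the stand estimate.

## Worked example

```r
library(radshoots)

# a synthetic survey with the field study's structure:
# 40 stands, 5 species at weights 184:111:86:30:7, 10 shoots per stand
sim <- generate_samples(generator_config(seed = 20161201))
res <- exclude_censored(sim$table)
fit <- fit_model(model_spec("full"), res$table,
                 mcmc_config(seed = 1, test_scale = 16))
subset(summarize_draws(fit),
       parameter %in% c("mu_bar", "beta", "sigma_bar", "sigma_M", "sigma_S"))
#>   parameter  mean    sd  q2.5 q97.5 rhat
#> 1    mu_bar  4.48 0.575  3.35  5.59    1
#> 2      beta -0.41 0.078 -0.56 -0.25    1
#> 3 sigma_bar  0.71 0.026  0.66  0.77    1
#> 4   sigma_M  1.37 0.164  1.09  1.74    1
#> 5   sigma_S  1.00 0.604  0.39  2.69    1
```

The generating values (μ̄ = 4.92, β = −0.39, σ̄ = 0.74, σ_M = 1.32,
σ_S = 0.62) sit inside the credible intervals; the stand SD σ_M dwarfs the
species SD, which is why finding the right *stand* matters more than the
species growing in it.

How many shoots to take in a new stand whose true level is 10 Bq kg⁻¹,
using the survey's population estimates:

```r
hy <- hyperparams(mu_bar = 4.92, sigma_bar = 0.74, sigma_M = 1.33)
sample_size_curve(c(1, 2, 5, 10), log(10), hy)
#>    n expected_mean_log predictive_sd_log lower upper expected_mean_bq
#> 1  1              2.92             0.983  1.65  4.19             18.6
#> 2  2              2.65             0.886  1.70  3.61             14.2
#> 3  5              2.46             0.807  1.83  3.08             11.6
#> 4 10              2.38             0.775  1.93  2.83             10.8

prob_below_threshold(log(10), 0.74, 50)
#> [1] 0.985
```

With one shoot the estimate (expected log mean 2.92, i.e. ≈ 19 Bq kg⁻¹) is
still pulled strongly toward the regional mean; by five shoots it has
dropped to 2.46 (≈ 12 Bq kg⁻¹) and the predictive SD has fallen from 0.98
to 0.81, already close to its floor of σ̄ = 0.74 — the diminishing-returns
point behind a five-shoots-per-stand sampling recommendation. A stand truly
at 10 Bq kg⁻¹ would have ~98.5% of individual stems under the 50 Bq kg⁻¹
bed-log limit.

The same stages are scriptable from a shell via
`inst/scripts/radshoots-cli.R` (`simulate`, `fit`, `select`, `predict`).

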