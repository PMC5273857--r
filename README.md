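# empnull

Estimation of the **empirical null distribution** of genome-wide
association test statistics, and correction of the **bias** and
**inflation** it reveals.

## The problem

In an EWAS or TWAS, hundreds of thousands of features (CpG sites,
genes) are each tested for association with an outcome; under the
theoretical null their z-statistics should follow N(0, 1).  In
practice, unmeasured technical and biological confounding (batch
effects, cellular heterogeneity, population substructure) leaves the
*null* statistics following

    z_null ~ N(bias, inflation^2),

with the mode shifted away from zero (bias) and excess spread
(inflation).  Ignoring either overstates significance and floods the
results with false positives.  The classical genomic-control remedy,
the genomic inflation factor

    lambda = median(w_1, ..., w_p) / 0.456      (chi-square(1) statistics)

(divide z by sqrt(lambda) for z-statistics), ignores bias entirely and
*overestimates* inflation whenever a non-negligible fraction of
features is truly associated — the rule rather than the exception in
EWAS/TWAS — so genomic control is simultaneously anti-conservative
about bias and conservative about inflation.

## The method

`empnull` fits a three-component normal mixture to the observed
statistics by Gibbs sampling:

    f(x) = sum_{j=1,2,3} eps_j * phi(x; mu_j, sigma_j)

Component 1 is the empirical null — its mean is the bias, its standard
deviation the inflation; components 2 and 3 (prior centres -3 and +3)
absorb the negatively and positively associated minority.  Conjugate
priors (normal on means, inverse-gamma IG(1.28, 0.36) on variances,
Dirichlet(90, 5, 5) on proportions) give closed-form conditional draws;
informative prior centres suppress label switching, and the Dirichlet
encodes the core assumption that the null is an unknown *majority*.
The default run is 3000 burn-in plus 2000 retained iterations,
summarised by the posterior mean.  Corrected statistics are

    z' = (z - bias) / inflation,    beta' = beta - bias*se,    se' = inflation*se,

with two-sided standard-normal p-values, so estimates of effect size,
standard error, z, and p stay mutually consistent.  The package also
provides fixed-effect inverse-variance meta-analysis with per-study
correction, the simulation generators used to validate all of the
above, and an FPR/power benchmark harness.

## Worked example

```r
library(empnull)

set.seed(1)
# 2000 statistics: 90% null with bias 0.2 and inflation 1.3,
# 10% associated at +/-4
z <- c(rnorm(1800, 0.2, 1.3), rnorm(100, 4), rnorm(100, -4))

fit <- gibbs_fit(z, config = gibbs_config(seed = 42))
fit
#> Empirical-null mixture fit on 2000 statistics (3000 burn-in + 2000 kept)
#>   bias      =   0.1555
#>   inflation =   1.2292
#>   proportions (null, neg, pos) = 0.822, 0.083, 0.095

genomic_inflation_z(z)   # the genomic inflation factor overshoots:
#> [1] 1.566842            #   it reads the true associations as inflation

head(empirical_null_correct(z, fit$null)$p_value, 3)
#> [1] 0.5311132 0.8177459 0.3967001
```

The fitted null (0.16, 1.23) tracks the generating truth (0.2, 1.3) —
the residual gap is the documented prior shrinkage at p = 2000 plus
tail absorption by the alternative components — while the genomic
inflation factor (1.57) overestimates the spread because 10% of the
features are genuinely associated.  `run_benchmark()` repeats such
experiments; `diagnostic_plots(fit, "fit.png")` draws the histogram
with the fitted mixture and a before/after QQ-plot.

A command-line front end covering `fit`, `correct`, `meta`,
`simulate`, `benchmark`, and `plot` is installed at
`system.file("cli", "empnull.R", package = "empnull")`.

## See also

The methods vignette (`vignettes/empirical-null.Rmd`) documents the
model, the sampler, every tunable parameter, the simulation
calibration, and known limitations.
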