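# tidymr

Two-sample Mendelian randomization (MR) from GWAS summary statistics, in a
tidyverse-native package: tibbles in, tibbles out, broom-style `tidy()` /
`glance()` methods on fitted objects, and `autoplot()` for the standard
figures.

## Who this is for and what it does

Genetic epidemiologists who want to estimate the causal effect of an
exposure on disease outcomes using only published GWAS summary statistics —
for example, whether higher plasma caffeine concentration (instrumented by
variants near *CYP1A2* and *AHR*) lowers adiposity and type 2 diabetes
risk. The package covers the full analysis path:

* **I/O and harmonization** — read tab-separated summary tables with a
  configurable column map, validate records (rejections are kept with
  reasons, never silent), convert standardized z scores to SD units via
  β = z/√(2p(1−p)(n+z²)), pick the strongest signal per locus, and align
  exposure/outcome tables to a common effect allele with strand-complement
  handling and palindromic-SNP frequency rules.
* **Causal estimators** — per-variant Wald ratios θ̂ⱼ = Γ̂ⱼ/γ̂ⱼ with
  first- or second-order standard errors; fixed- and multiplicative
  random-effects inverse-variance weighting (IVW) with Cochran's Q;
  MR-Egger regression (slope = causal effect, intercept = directional
  pleiotropy); weighted-median and weighted-mode estimators with
  seeded parametric-bootstrap standard errors; Bonferroni significance
  classification (significant / suggestive / null).
* **Cross-study meta-analysis** — DerSimonian–Laird random-effects pooling
  with τ², Q and forest-plot export; `or_ci_to_log()` consumes published
  odds ratios with CIs directly.
* **Two-step network mediation** — decomposes a total effect into a
  mediator-borne product β₁·β₂ and a direct remainder, with the proportion
  mediated and a 100,000-iteration parametric bootstrap for its percentile
  interval.
* **A summary-statistic simulator** — two-sample tables with configurable
  causal effect, pleiotropy (balanced/directional, InSIDE-satisfying),
  mediation structure and allele-coding swaps, so every stage is testable
  against known truth without any download.
* **A study orchestrator** — `run_study()` executes a whole multi-outcome
  study from one (YAML-able) config and writes tab-separated reports; a
  thin CLI lives at `inst/scripts/mr_pipeline.R` with subcommands
  `simulate`, `run`, `mediate`, and `meta`.

See `vignettes/two-sample-mr.Rmd` for the models, assumptions, numerical
choices, and limitations.

## Worked example

Two synthetic caffeine-like instruments against two synthetic type 2
diabetes studies (tables shipped under `inst/extdata/`, generated by the
package's own simulator):

```r
library(tidymr)
library(dplyr)

exdir <- system.file("extdata", package = "tidymr")
exposure <- read_gwas_table(file.path(exdir, "synthetic_caffeine_exposure.tsv"))
outcome1 <- read_gwas_table(file.path(exdir, "synthetic_t2d_study1.tsv"))
outcome2 <- read_gwas_table(file.path(exdir, "synthetic_t2d_study2.tsv"))

h1 <- harmonize_pair(exposure, outcome1,
                     exposure_name = "caffeine", outcome_name = "t2d_study1")
est1 <- mr_ivw(wald_ratios(h1))
est1
#> <mr_estimate> method: ivw_fixed
#>   beta = -0.1354 (SE 0.0459), 95% CI [-0.2254, -0.0454], p = 0.00318, n_snps = 2
#>   Cochran Q = 0.438 (p = 0.508)
```

The two-instrument IVW estimate is a log odds ratio per SD of exposure:
exp(−0.135) ≈ 0.87, i.e. a 13% lower odds of disease per SD, with no
within-outcome heterogeneity between the two instruments (Q p = 0.51).
Pool the two studies and classify against the Bonferroni threshold for
eight outcomes (0.05/8 = 0.00625):

```r
est2 <- mr_ivw(wald_ratios(harmonize_pair(exposure, outcome2)))
m <- meta_dl(bind_rows(
  tidy(est1) |> transmute(study = "t2d_study1", beta = estimate, se = std.error),
  tidy(est2) |> transmute(study = "t2d_study2", beta = estimate, se = std.error)
))
m
#> <mr_meta> DerSimonian-Laird random-effects, 2 studies
#>   pooled beta = -0.1953 (SE 0.0599), 95% CI [-0.3127, -0.0779], p = 0.00111
#>   tau^2 = 0.005067, Q = 3.404 on 1 df (p = 0.065)

forest_data(m)
#> # A tibble: 3 × 5
#>   study         or ci_low ci_high pooled
#>   <chr>      <dbl>  <dbl>   <dbl> <lgl>
#> 1 t2d_study1 0.873  0.798   0.956 FALSE
#> 2 t2d_study2 0.775  0.708   0.848 FALSE
#> 3 pooled     0.823  0.731   0.925 TRUE

classify_significance(m$pvalue, n_outcomes = 8)
#> [1] "significant"
```

`autoplot(m)` draws the forest plot; `autoplot(h1)` the instrument
scatter. Both tables were simulated with a true odds ratio of 0.81 per SD,
which the pooled interval comfortably covers.

Published study-level results can be pooled directly, without variant-level
data — e.g. two consortium odds ratios of 0.77 (0.70–0.85) and 0.84
(0.78–0.91):

```r
meta_dl(bind_rows(
  mutate(or_ci_to_log(0.77, 0.70, 0.85), study = "FinnGen"),
  mutate(or_ci_to_log(0.84, 0.78, 0.91), study = "DIAMANTE")
))
#> <mr_meta> DerSimonian-Laird random-effects, 2 studies
#>   pooled beta = -0.2126 (SE 0.0432), 95% CI [-0.2973, -0.1280], p = 8.51e-07
#>   tau^2 = 0.001786, Q = 1.893 on 1 df (p = 0.169)
```

exp(−0.2126) = 0.81: the combined odds ratio per SD of exposure. The same
pooling is available from the shell:

```sh
Rscript inst/scripts/mr_pipeline.R meta --or 0.77,0.70,0.85 --or 0.84,0.78,0.91
```

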