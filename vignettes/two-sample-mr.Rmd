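---
title: "Two-sample Mendelian randomization with tidymr: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with tidymr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidymr)
library(dplyr)
```

# The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure (here, the running
example is plasma caffeine concentration in SD units) on an outcome (body
composition traits, type 2 diabetes, cardiovascular disease) from GWAS
summary statistics alone. The two-sample design takes the
variant–exposure associations $\hat\gamma_j \pm \sigma_{\gamma j}$ from
one study and the variant–outcome associations
$\hat\Gamma_j \pm \sigma_{\Gamma j}$ from another, non-overlapping study.
Valid instruments must be (i) strongly associated with the exposure,
(ii) independent of confounders, and (iii) affect the outcome only
through the exposure. tidymr implements the full analysis path: reading
and harmonizing summary tables, per-variant and combined causal
estimates, heterogeneity statistics, cross-study meta-analysis,
pleiotropy-robust estimators, and a two-step mediation decomposition —
plus a summary-statistic simulator so every stage can be validated
against known truth.

# Input standardization and harmonization

`read_gwas_table()` ingests tab-separated tables with a configurable
column map. Rows violating record-level invariants (non-positive SE,
allele frequency outside $[0,1]$, identical alleles, p-value outside
$(0,1]$, a `z` score contradicting the sign of `beta`) are never silently
dropped: they are collected with a reason and retrievable with
`rejected_records()`.

When the exposure GWAS reports standardized $z$ scores rather than
SD-unit effects, `standardize_from_z()` converts via

$$\hat\beta_{SD} = \frac{z}{\sqrt{2p(1-p)(n+z^2)}},\qquad
  \mathrm{se}_{SD} = \frac{1}{\sqrt{2p(1-p)(n+z^2)}},$$

with $p$ the effect-allele frequency and $n$ the sample size. This is the
standard summary-data conversion; the ratio $\hat\beta_{SD}/\mathrm{se}_{SD}$
reproduces $z$ exactly, so downstream Wald ratios are invariant to whether
the conversion was applied upstream. The allele frequencies entering the
conversion must be supplied explicitly (they are a column of the input
table); no default frequency is assumed.

`select_strongest_per_locus()` thins correlated signals to one instrument
per locus — the smallest p-value, with exact ties broken by the
lexicographically smallest variant id so the choice is deterministic.
This mirrors instrument selection when a linkage-disequilibrium reference
panel is unavailable and loci are annotated (for the caffeine exposure:
the *CYP1A2* and *AHR* regions, one instrument each).

`harmonize_pair()` aligns each outcome record to the exposure's effect
allele. An outcome effect reported on the opposite allele (directly or as
its strand complement) has its sign flipped and its frequency replaced by
$1-\mathrm{eaf}$. Palindromic variants (A/T, C/G) cannot be oriented from
allele letters; they are aligned by allele frequency when informative and
dropped as ambiguous when either study's frequency lies within a window
of 0.5. The window defaults to 0.08 (frequencies in $[0.42, 0.58]$ are
ambiguous), a conventional choice; neither caffeine instrument is
palindromic, so the default matters only for general reuse.
Irreconcilable allele pairs are dropped with reason `allele mismatch` —
never sign-guessed. Harmonization is idempotent, and the harmonized set is
invariant to recoding the raw outcome rows to the opposite allele.

# Causal estimators

**Wald ratio.** Per variant, $\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$.
The default first-order standard error is
$\sigma_{\Gamma j}/|\hat\gamma_j|$; the second-order (full delta-method)
error $\sqrt{\sigma_{\Gamma j}^2/\hat\gamma_j^2 +
\hat\Gamma_j^2\sigma_{\gamma j}^2/\hat\gamma_j^4}$ is available with
`order = "second"`. First order is the package default: with strong
instruments the exposure-side term is negligible, and second-order
*weights* couple to the outcome noise, which we found introduces its own
small-sample bias in the inverse-variance weighted combination (see
Limitations).

**Inverse-variance weighting (IVW).** With weights
$w_j = \mathrm{se}(\hat\theta_j)^{-2}$,
$\hat\theta = \sum_j w_j\hat\theta_j / \sum_j w_j$, which is identical to
a weighted through-origin regression of $\hat\Gamma$ on $\hat\gamma$ with
weights $\sigma_{\Gamma j}^{-2}$. The fixed-effect standard error is
$(\sum_j w_j)^{-1/2}$; the multiplicative random-effects model
(`model = "random"`) inflates it by $\max\{1, \sqrt{Q/(k-1)}\}$. Cochran's
$Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$ and its $\chi^2_{k-1}$
p-value are attached whenever $k \ge 2$. Fixed-effect is the default for
combining the two caffeine instruments within an outcome; the cross-study
pooling is where random effects enter (below).

**MR-Egger.** After orienting each pair so $\hat\gamma_j \ge 0$, a
weighted regression of $\hat\Gamma$ on $\hat\gamma$ *with intercept*
estimates the causal effect (slope) and the average directional
pleiotropy (intercept). Standard errors use the weighted residual
standard deviation bounded below by 1, so over-dispersion widens the
intervals but chance under-dispersion never narrows them. The estimator
requires at least three instruments; with only two (the caffeine
analysis) the package raises an instrument-count error rather than
silently degenerating — this is why pleiotropy-robust sensitivity
analyses are only available for the many-instrument mediator leg.
Normal-rule intervals are the default everywhere for consistency; a
t-distribution option (`t_dist = TRUE`, $k-2$ df) is provided.

**Weighted median.** Order the ratios, form cumulative weight midpoints
$p_j = \sum_{k\le j} w'_k - w'_j/2$ (normalized weights $w'$), and
linearly interpolate $\theta$ at $p = 0.5$. Consistent when valid
instruments carry more than half the weight. The standard error is a
parametric bootstrap: each $\hat\theta_j$ is resampled from
$N(\hat\theta_j, \mathrm{se}_j^2)$ and the weighted median recomputed;
`n_boot` defaults to 1000 and every stochastic call takes an explicit
seed.

**Weighted mode.** The argmax of a weighted normal-kernel density over
the ratios, bandwidth equal to `bandwidth_factor` (default 1) times the
modified Silverman rule
$0.9\,\min\{s, \mathrm{IQR}/1.349\}\,k^{-1/5}$, evaluated on a 512-point
grid spanning the ratio range extended by three bandwidths. When all
ratios coincide the point mass is returned directly. The same parametric
bootstrap provides the standard error.

**Significance classification.** With $k$ outcomes tested at family level
$\alpha$, the Bonferroni threshold is $t = \alpha/k$ (for eight outcomes
at $\alpha = 0.05$, $t = 0.00625$, printed as 0.006): $p < t$ is
*significant*, $t \le p < \alpha$ *suggestive*, and $p \ge \alpha$
*null*, with strict inequalities so boundary values fall in the weaker
class.

# Cross-study meta-analysis

`meta_dl()` pools per-study estimates with the DerSimonian–Laird
moment estimator:
$\tau^2 = \max\{0, (Q - (k-1))/(\sum w - \sum w^2/\sum w)\}$ with
fixed-effect weights $w_i = \mathrm{se}_i^{-2}$, then random-effects
weights $w_i^* = (\mathrm{se}_i^2 + \tau^2)^{-1}$. When $Q \le k-1$ the
truncation makes the result exactly the fixed-effect one. Heterogeneity
is always reported alongside the pooled estimate and never used to
suppress pooling. `or_ci_to_log()` converts printed odds ratios with 95%
CIs back to the log scale using the conventional 1.96 (not the exact
97.5% normal quantile) — the difference is far below printed rounding,
and the round trip then reproduces log-symmetric intervals exactly.

Pooling the two published type 2 diabetes odds ratios illustrates the
desk-scale reproduction the acceptance script performs:

```{r meta-example}
studies <- bind_rows(
  mutate(or_ci_to_log(0.77, 0.70, 0.85), study = "FinnGen"),
  mutate(or_ci_to_log(0.84, 0.78, 0.91), study = "DIAMANTE")
)
pooled <- meta_dl(studies)
pooled
exp(c(pooled$pooled_beta, pooled$ci_low, pooled$ci_high))
```

A note on heterogeneity from printed inputs: recomputing Cochran's $Q$
from the rounded published CIs gives $Q \approx 1.89$, whereas the source
analysis quotes $Q = 2.39$ (P = 0.12) from its unrounded internal
estimates. The rounded inputs cannot recover the unrounded statistic, so
the package's tests assert only the homogeneity conclusion
(p-value > 0.05), never equality on $Q$.

# Two-step network mediation

The mediated (indirect) effect of exposure on outcome through a mediator
is the product of the exposure→mediator effect $\beta_1$ (estimated by
IVW over the exposure instruments) and the mediator→outcome effect
$\beta_2$ (estimated by the weighted median over the mediator's
instrument set — the default because, with hundreds of mediator
instruments, IVW heterogeneity typically signals pleiotropy and the
weighted median is both efficient and robust). The proportion mediated is
$\beta_1\beta_2 / \theta_{total}$. Both quantities keep the scale of
their inputs: log-odds for binary outcome legs, SD units for continuous
legs.

Uncertainty comes from a parametric bootstrap (`bootstrap_mediation()`,
default 100,000 iterations): the three legs are drawn as independent
normals around their estimates — independence is the working assumption,
justified when the three legs come from non-overlapping two-sample
contributions, as in the simulator's construction. The indirect-effect SE
is the SD of the product draws; the proportion interval is the
2.5th/97.5th percentile of the ratio draws. Percentile intervals were
chosen over the normal approximation because the ratio is right-skewed
whenever the total-effect draws approach zero; a normal-approximation
interval remains available (`ci_type = "normal"`). Draws with
$|\theta_{total}| < 10^{-10}$ would make the ratio numerically unstable;
they are rejected, redrawn and counted (`n_rejected`). Because the
percentile interval inherits the ratio's skew, its upper bound is
sensitive to the total effect's precision — intervals computed from
published study-level inputs can therefore have a visibly higher upper
bound than intervals quoted from unrounded internal estimates with
possibly correlated draws.

```{r mediation-example}
med <- bootstrap_mediation(
  total = list(beta = pooled$pooled_beta, se = pooled$pooled_se),
  step1 = list(beta = -0.08, se = 0.0102),   # exposure -> mediator, SD units
  step2 = list(beta = 1.18, se = 0.14),      # mediator -> outcome, log odds
  n_boot = 10000, seed = 1
)
med
```

# The simulator: what it emulates, and what it does not

`sim_config()` + `simulate_two_sample()` generate the two-sample layout
directly at the summary-statistic level: true instrument effects
$\gamma_j \sim N(\mu_\gamma, \sigma_\gamma^2)$; observed exposure effects
$\hat\gamma_j = \gamma_j + N(0, \mathrm{se}_\gamma^2)$; outcome effects
$\hat\Gamma_j = \theta\gamma_j + \alpha_j + N(0, \mathrm{se}_\Gamma^2)$.
Pleiotropic effects $\alpha_j$ are drawn independently of $\gamma_j$, so
the InSIDE condition holds by construction: `balanced` draws
$N(0, \mathrm{mag}^2)$, `directional` draws
$N(\mathrm{mag}, (\mathrm{mag}/2)^2)$ (the spread relative to the mean is
the package's choice; only the nonzero mean is essential to the
scenario), and `pleiotropy_frac` controls the fraction of instruments
affected. Alleles are sampled from non-palindromic pairs so harmonization
never discards simulated instruments, and a configurable fraction of
outcome rows is emitted on the swapped allele so harmonization is
genuinely exercised. Exposure and outcome noise use separate seeded
streams, matching the non-overlapping-samples assumption; identical
configurations produce byte-identical tables.

The generic defaults model a well-powered exposure GWAS (mean per-allele
effect 0.15 SD, reported SE 0.005, instrument F around 900) — the
strong-instrument regime in which the first-order standard errors the
estimators report are well calibrated. `sim_config_caffeine()` is the
two-instrument preset for the running example: mean effect 0.14 SD with
SE 0.016 (F around 80, matching a metabolite GWAS of roughly 10,000
individuals), a binary outcome on the log-odds scale with true odds ratio
0.81 per SD, and a mediation block ($\beta_1 = -0.08$ SD,
$\beta_2 = 1.18$ log-odds per mediator SD, direct effect making up the
remainder, hence a true proportion mediated of about 0.45).
`simulate_mediation_network()` emits the three internally consistent
table pairs for the two-step analysis, with the mediator GWAS given 483
instruments by default (the scale of a large anthropometric-trait
instrument set).

The simulator deliberately omits: linkage disequilibrium between
instruments (instruments are independent), winner's-curse selection of
instruments, sample overlap between the two studies, allele-frequency
estimation error, and case-control ascertainment effects on the log-odds
scale. Passing tests therefore demonstrate the estimators' correctness
under the stated generating model, not robustness to these additional
features of real data.

# Numerical choices and degenerate inputs

* All confidence intervals use the conventional $\pm 1.96$ and two-sided
  normal p-values, including MR-Egger by default, matching
  epidemiological reporting practice; MR-Egger offers a t-option.
* Reported p-values in simulated tables are floored at the smallest
  normalized double, since $z$ statistics above ~38 underflow
  `2*pnorm(-z)` to zero, which would violate the $p \in (0,1]$ record
  invariant.
* A zero exposure effect makes the Wald ratio undefined: a typed
  weak-instrument error, never an Inf. Fewer than three instruments for
  Egger/median/mode: a typed instrument-count error — surfaced, not
  silenced, because a two-instrument analysis genuinely cannot run them.
* Weighted-median ties and ordering: cumulative midpoints are
  interpolated with ordered ties; estimates are invariant to permuting
  the inputs.
* Weighted-mode degenerate spread: identical ratios return the point mass
  directly; the Silverman bandwidth falls back to the SD when the IQR is
  zero.
* The mediation bootstrap rejects and redraws total-effect draws within
  $10^{-10}$ of zero, logging the count.
* Every stochastic routine takes an explicit integer seed; the pipeline
  derives all stream seeds from the single configured seed, so reports
  are bit-identical across runs.

# Validation strategy and problem sizes

The test suite validates each estimator against an independent oracle
(hand-computed weighted means, a matrix-algebra weighted least-squares
solve for Egger, a brute-force fine-grid density scan for the mode, the
`metafor` DL implementation for the meta-analysis) and checks the
statistical guarantees by simulation: IVW interval coverage over 200
simulated 100-instrument studies, weighted-median robustness with 30% of
instruments carrying directional pleiotropy (averaged over 20 replicates
of 30 instruments, because the estimator's finite-sample deviation under
one-sided contamination sits near the decision line for a single run),
and mediation-interval coverage over 500 replicates of the caffeine-like
network with 5,000 bootstrap iterations each. These sizes keep the whole
suite within a few minutes on one CPU while holding the Monte-Carlo error
of each coverage estimate near one percentage point; estimator bootstrap
sizes inside tests (200–500) are smaller than the interactive defaults
(1,000) and the mediation default (100,000) for the same reason.

# Known limitations

* **First-order intervals at modest instrument strength.** The default
  Wald standard error ignores exposure-side noise. For instrument
  strength $F = (\gamma/\mathrm{se}_\gamma)^2$, the neglected relative
  variance is of order $\theta^2/F$ per instrument, and the inverse
  relationship between $\hat\gamma$ noise and the ratio induces a
  dilution bias of order $-\theta/F$. At $F \approx 80$ (the caffeine
  preset) this produces mild undercoverage of nominal 95% intervals in
  many-instrument simulations; at $F$ in the hundreds it is negligible.
  The second-order option repairs the variance but its weights couple to
  the outcome noise and bias the IVW mean — it is therefore offered for
  per-ratio uncertainty (and used for the mediation legs, where the
  mediator-side precision is high relative to the exposure GWAS), not as
  a default.
* **Percentile proportion intervals are skew-faithful**, hence their
  upper bound grows quickly as the total effect's signal-to-noise drops;
  see the mediation section.
* **No LD, overlap or selection modelling** in the simulator (above).
* **Two instruments limit sensitivity analyses**: Egger, median and mode
  all require at least three instruments, so for a two-instrument
  exposure they apply only to the many-instrument mediator leg of the
  mediation analysis.
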