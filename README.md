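# gxetradeoff

Tools for a question that comes up whenever genome-wide association study
(GWAS) data span two contexts — sexes, diets, environments, age bands:
**when is it worth estimating context-specific (GxE) allelic effects, and
when should you pool?** The package is aimed at statistical geneticists
working with two-context GWAS summary statistics or simulation studies of
polygenic gene-by-environment interaction.

## The model and the decision rule

For a biallelic variant with allele counts `g ∈ {0,1,2}` and a continuous
trait measured in contexts A (n individuals) and B (m individuals),

    y_i ~ N(α_A + β_A g_i, σ_A²)  for i in A
    y_i ~ N(α_B + β_B g_i, σ_B²)  for i in B,

the stratified (GxE) estimator of β_A is unbiased with sampling variance
V_A, while the pooled (additive) estimator is an exact weighted combination
of the stratified slopes, `β̂_pool = ω_A β̂_A + ω_B β̂_B`, with weights given
by per-context genotype sums of squares (ω_A ∝ n·H_A for heterozygosity
H = 2f(1−f)). Comparing mean squared errors for β_A gives the decision
rule at the core of the package — prefer the GxE estimator iff

    ((ω_A − 1) β_A + ω_B β_B)² + ω_A² V_A + ω_B² V_B  >  V_A,

i.e. iff the pooled estimator's bias² + variance exceeds the stratified
estimator's variance. Equivalent signal-to-noise and sd-units forms, a
never-additive noise-ratio threshold, and a plug-in screen for summary
statistics (with a moment correction for the noise in the squared effect
difference) are exported alongside.

Around the rule, the package implements the two simulation studies that
motivate joint (polygenic) treatment of GxE:

* **GxDiet amplification with "top hits" classification** (`run_flysim()`):
  effects on longevity under control/high-sugar diets, perfectly correlated
  but 1.4× amplified under high sugar, pushed through per-diet Z-tests,
  Storey q-values and the four-category shared/diet-specific classification.
* **Polygenic-score strategy comparison** (`run_strategy_grid()`):
  additive, stratified, and empirical-Bayes multivariate-shrinkage scoring
  (`gxe_shrink()`, a fixed-grid mixture of zero-centered bivariate normal
  priors fit by EM) evaluated by out-of-sample Pearson correlation in each
  context.

## Worked example

Screening a variant for which context-specific estimation pays off: the
focal context A holds a quarter of the heterozygosity-weighted sample
(ω_A = 0.25), the effect differs substantially between contexts, and A is
noisier than B.

```r
library(gxetradeoff)

w <- approx_weights(n_A = 5000, n_B = 15000, het_A = 0.32, het_B = 0.32)
d <- decision_inputs(beta_A = 0.08, beta_B = 0.02,
                     var_A = 4e-4, var_B = 1.3e-4, weights = w)
evaluate_mse(d)
#> mse_additive      mse_gxe
#>  0.002123125  0.000400000
prefer_gxe(d)
#> [1] "GXE"
never_additive_threshold(0.25)
#> [1] 0.6
```

The pooled estimator's MSE for β_A (bias² + variance ≈ 0.0021) is five
times the stratified estimator's variance (0.0004), so the GxE estimator
is preferred. The threshold says that at ω_A = 0.25, whenever
V_A/V_B < 0.6 the additive estimator is *never* preferable in context A —
here V_A/V_B ≈ 3, so the preference is driven by the large effect
difference, not by the noise ratio alone.

The amplification simulation shows why classifying variants one at a time
misleads. No variant in this model is diet-specific (all non-null effects
are present in both diets, amplified under high sugar), yet:

```r
cfg <- flysim_config(pi_null = flysim_presets[["methods_preset"]], p = 20000)
sim <- run_flysim(cfg, seed = 42)
s <- summarize_classification(sim$label)
s$n_significant
#> [1] 201
round(s$significant_fractions, 3)
#>    control_specific high_sugar_specific              shared
#>               0.085               0.637               0.279
```

About 1% of variants reach per-diet significance, and the majority of
those are classified "high-sugar specific" — an artifact of sub-significant
control-diet associations, not of any true diet-specific biology.

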