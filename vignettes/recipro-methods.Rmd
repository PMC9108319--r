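---
title: "Methods: reciprocal-transplant analysis of local adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reciprocal-transplant analysis of local adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recipro)
```

## The experiment the package models

`recipro` analyses elevational reciprocal-transplant experiments with maize
landraces. The reference design comprises four populations — Mexican
Highland, Mexican Lowland, South American Highland and South American
Lowland — of 30 accessions each, where every highland accession is paired
with a lowland accession collected in the same 1-degree latitude bin
(accessions between 1000 m and 2000 m are excluded by design, which is why
the passport validator treats mid-elevation origins as errors). All 120
accessions are grown in two Mexican common gardens, a Pacific-coast lowland
site at 54 m and a central-plateau highland site at 2852 m, each laid out as
two complete blocks of one 15-seed row per accession, with two tagged plants
per row providing the plant-level measurements.

Local adaptation is assessed four ways:

1. **Reaction norms and G×E contrasts** — crossing fitness reaction norms
   between populations across gardens are the graphical signature of
   "Foreign vs. Local" home-site advantage.
2. **Q~ST~ vs F~ST~** — trait differentiation in excess of neutral marker
   differentiation indicates divergent selection.
3. **Environmental-distance decay** — fitness should fall as the garden's
   environment departs from the accession's natal environment.
4. **Garden-specific trait correlations** — putatively highland-adaptive
   traits (anthocyanin pigmentation, macrohair density, water use
   efficiency) should correlate more positively with fitness in the
   highland garden.

## Derived traits

From raw Table-style trait codes the package derives, per row,
barrenness `BRN = 1 − PE/STD` (undefined when the stand count is zero) and
the anthesis–silking interval `ASI = DTS − DTA` (negative values are
preserved: silks emerging slightly before pollen shed is biologically
meaningful, not an error). Per plant it derives the two adjusted fitness
metrics

$$\mathrm{FITplant} = \frac{PE}{15}\,\sqrt{EN}\;EW, \qquad
  \mathrm{FITplantveg} = \frac{PE}{15}\,\sqrt{EN},$$

where the row-level ear-producing stand count `PE` is shared by both tagged
plants of the row while `EN` and `EW` come from the plant itself. The square
root damps the diminishing returns of second and later ears; dividing `PE`
by the 15 planted seeds converts it to survival-to-reproduction. `FITplant`
is missing whenever `EW` is missing (unharvested rows), while `FITplantveg`
remains defined — the reason it is the fitness measure used by the
environmental-distance and correlation analyses. `EN` at the plant level
(rather than a row mean) is used under the square root. Carbon isotope
composition is computed against the Vienna Pee Dee Belemnite standard,
$\delta^{13}C = (R_{sample}/R_{standard} - 1) \times 1000$ (per mil).

## Mixed models

The G×E model for each trait is

```
TRAIT ~ GARDEN * CONTINENT * ELEVATION + GARDEN:BLOCK + (1|LATPAIR) + (1|LATPAIR:GARDEN)
```

fitted by REML (lme4/lmerTest). `LATPAIR` is the latitude-pair identifier;
the nesting `GARDEN/BLOCK` is expanded as the fixed `GARDEN:BLOCK` cell
term, and the latitude grouping enters as two independent random
intercepts. Treatment effects are differences of estimated marginal means
over the `GARDEN × CONTINENT × ELEVATION` grid (averaging over block with
equal weights), with Satterthwaite degrees of freedom. Twelve contrast
columns are reported per trait: the garden effect within each of the four
populations, the continent effect within each garden × elevation cell, and
the elevation (population) effect within each garden × continent cell.
Within each of those three four-member families the Bonferroni-corrected
per-test level is $0.05/4 = 0.0125$. Ordinal 0–4 scores are analysed as
numeric responses.

The Q~ST~ variance partition uses

```
TRAIT ~ 1 + (1|POPULATION) + (1|LINE) + (1|GARDEN) + (1|GARDEN:BLOCK)
```

fitted on the subset of accessions in each contrast, with the two contrast
sides as the `POPULATION` grouping (pooled contrasts union the constituent
populations). Then

$$Q_{ST} = \frac{\sigma^2_{GB}}{\sigma^2_{GB} + 2\sigma^2_{GW}},$$

with $\sigma^2_{GB}$ the population component and $\sigma^2_{GW}$ the
accession-line component taken as-is (broad-sense, $h^2 = 1$; a
heritability scaling argument exists but defaults off). A trait/contrast is
flagged when $Q_{ST}$ exceeds the mean of the per-SNP Hudson F~ST~
distribution by more than two of its standard deviations — a point
comparison, with no parametric sampling distribution for Q~ST~.

Variance components are estimated with lme4's REML machinery — the standard
tool for exactly these random-intercept models — behind the
`fit_lmm_reml()` interface; boundary (zero-variance) fits are legitimate
converged results. Analytic standard errors of variance components are not
reported (`se` is NA); recovery checks in the test-suite use
replicate-based Monte Carlo standard errors instead, which is both simpler
and more honest about the skewed small-sample distribution of variance
estimates.

## Hudson F~ST~

Per SNP, with sample alternate-allele frequencies $p_1, p_2$ and allele
counts $n_1, n_2$ (twice the genotyped individuals, missing calls excluded
marker-wise),

$$F_{ST} = \frac{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)}
               {p_1(1-p_2) + p_2(1-p_1)}.$$

Negative estimates are retained, monomorphic markers are dropped as
undefined, and no minor-allele-frequency filter is applied by default. The
2-SD rule needs the **per-SNP distribution**, so the scan summarises the
mean and SD of per-SNP values rather than forming the ratio-of-averages
estimator. A consequence worth knowing: under the Balding–Nichols model at
parameter $F = 0.10$ the mean of per-SNP ratios sits slightly below $F$
(about 0.08–0.09 at the default sizes) because averaging ratios is not the
same as the ratio of averages; the acceptance checks measure exactly this
quantity.

## Environmental distance

For each environmental variable, `DISTANCE = Value_GARDEN − Value_ORIGIN`
(the formula is implemented exactly with this sign convention). Stage 1
regresses mean accession-by-garden `FITplantveg` linearly on distance,
absorbing unequal mean fitness between gardens; stage 2 fits the stage-1
residuals with `e ~ DISTANCE + DISTANCE²` and reports the quadratic
coefficient, its two-sided t and p, and the stage-2 R². Because stage-1
residuals are orthogonal to the intercept and the linear term, the stage-2
t-statistic coincides with the textbook quadratic-term test, so the null
distribution is exact under Gaussian errors. Variables are tested
independently with per-variable p-values; a `p_adjust` option exists but
defaults off.

Garden-specific Pearson correlations use pairwise-complete observations.
Significance defaults to the t-test on r (`t = r\sqrt{(n-2)/(1-r^2)}`, the
test `cor.test` performs); a Fisher-z normal test is available via
`method = "z"` because the two are often conflated in field descriptions.
Trait clusters come from average-linkage hierarchical clustering on
`1 − r`, cut at `k = 5` by default. δ¹³C is conventionally excluded from
both the correlation matrix and the clustering because of its restricted
sampling.

## The synthetic-data generator

`sim_config()` defaults *are* the study conditions: 4 populations × 30
latitude-paired accessions, 2 gardens (54 m / 2852 m) × 2 blocks × 15-seed
rows, 2 tagged plants per row, and Balding–Nichols markers (ancestral
frequencies uniform on (0.05, 0.95), per-population Beta draws at the
target F, Hardy–Weinberg dosages, 2% missing calls). The marker count
defaults to 2000 — scaled down from the ~67k of the genotyping platform —
so that a full pipeline run is interactive; the marker count only tightens
the F~ST~ summary, it does not change any estimator.

Continuous traits follow the generative mirror of the G×E model: a trait
mean plus garden and population offsets, plus latitude-pair,
latitude-pair × garden, block-within-garden, line and residual Gaussian
effects whose variances are set relative to the trait's residual variance
(`variance_spec`). Trait baselines encode the study system's qualitative
biology (slower flowering and shorter plants at altitude, Mexican-highland
macrohair density, more negative δ¹³C in highland material) so that
synthetic outputs read sensibly; they are fixed constants, not fitted
quantities.

Three generator choices deserve comment:

* **Variance-exact group effects.** Population, latitude and line effects
  are rescaled so their realized sample variance equals the configured
  value exactly (the `mvrnorm(empirical = TRUE)` convention). With only
  two to four populations, raw draws would realize a variance distributed
  as $\sigma^2\chi^2_{k-1}/(k-1)$ — "simulated $\sigma^2_{GB} = 2$" would
  then be a lottery, not a condition. Rescaling makes parameter-recovery
  statements well-posed; residuals stay i.i.d.
* **Fitness cascade.** Stand count is Binomial(15, p~surv~) and
  ear-producing count Binomial(STD, p~ear~); the logits carry the
  `gxe_matrix` population × garden offsets, and the probabilities decay by
  `env_decay` per squared kilometre of elevational transplant distance
  (default −0.04, i.e. a foreign transplant across the full ~2.8 km
  elevation gap loses roughly 30 percentage points of survival — a strong
  but realistic home-site advantage). Probabilities pushed outside [0, 1]
  are clipped with a warning. Ear number is 1 + Poisson and ear weight
  log-normal with population × garden location shifts, so the derived
  fitness metrics inherit the crossing structure.
* **Ordinal scores** threshold a latent Gaussian at its empirical
  {0.2, 0.4, 0.6, 0.8} quantiles, giving uniform category usage; the
  percent-extent scores map the same five categories to {0, 25, ..., 100}.

Named RNG sub-streams (one per trait family, derived from the single seed
by a string hash kept below 2³¹) make outputs bit-reproducible and mean
that adding a trait to the generator does not perturb any other trait's
draws. Markers are independent — no linkage disequilibrium — and origins
have no spatial autocorrelation beyond the latitude pairing; bioclim-style
variables are affine functions of elevation plus noise, which reproduces
the collinearity of real bioclim layers but not their geographic texture.
Passing tests therefore demonstrate the *estimators'* correctness and
calibration, not robustness to LD, spatial confounding, non-Gaussian trait
errors, or genotype-environment covariance in real landrace panels.

## Numerical and design notes

* REML convergence and boundary handling are delegated to lme4; fits that
  end on the variance boundary are reported with the component at 0.
  Singular-fit messages during scans over many traits are expected and
  harmless.
* The Hudson estimator requires at least two genotyped individuals per
  group at a marker; markers failing that, or monomorphic across both
  groups, yield NA and are excluded from the mean + 2 SD summary.
* PCA mean-imputes missing dosages per marker, centres always, and scales
  optionally (off by default, the common dosage-PCA practice).
* Problem sizes used by the test-suite and the acceptance script (e.g.
  2000 markers × 400 lines for the F~ST~ consistency check, 50 replicates
  for Q~ST~ recovery, 2000 replicates for the environmental-distance
  type-I rate, 100 replicates for scan calibration) were chosen so the
  Monte-Carlo error is comfortably below each tolerance while a complete
  run stays interactive on a single core.
* The four predefined populations are a continent × elevation convenience
  partition and need not coincide with population-genetic structure; the
  Q~ST~/F~ST~ scan should be read with that caveat, which is why the
  pipeline also reports genotype PCA for an unsupervised view.

## Limitations

The pipeline deliberately excludes admixture estimation (sNMF-style),
geographic interpolation of ancestry, and raster extraction of climate
layers; a pre-extracted environment table is the input contract. The
two-year lowland planting of the original design is represented as a
single lowland site label — multi-year random effects are out of scope.
Heritability is not estimated: Q~ST~ uses line variance directly, which
overstates Q~ST~ when within-population heritability is below one.
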