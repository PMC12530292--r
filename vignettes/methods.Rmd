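---
title: "Methods: from diet metabarcoding to causal path analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from diet metabarcoding to causal path analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(trophvar)
```

trophvar quantifies how much individuals of a predator population differ
in what they eat, and asks whether that variation is driven by the
biotic and abiotic "ecological opportunity" of the sampling campaign.
This vignette documents each methodological decision the package makes,
especially where a convention had to be chosen.

## 1. Diet quantification: the MNI rule

Validated metabarcoding detections are rows of
`(sample_id, individual_id, campaign_id, variant_id, taxon_id)`. The
Minimal Number of Individuals (MNI) for a prey taxon in one faecal
sample is the number of *distinct* sequence variants of that taxon
detected in the sample: two different Baetis genotypes in one faeces
prove at least two Baetis individuals were eaten.

```{r}
det <- data.frame(sample_id = "S1", individual_id = "f1",
                  campaign_id = "c1",
                  variant_id = c("v1", "v2", "v3"),
                  taxon_id = c("Baetis", "Baetis", "Gammarus"))
compute_mni(det)
```

MNI is a lower bound: it saturates at the number of genotypes present
in the local prey population, which the synthetic generator reproduces
through finite per-taxon genotype pools.

## 2. Trophic traits

For individual $i$ with diet proportions $p_{ij}$ and campaign
population diet $q_j$:

* **INW** (individual niche width) is the Shannon diversity
  $-\sum_j p_{ij}\ln p_{ij}$ (natural log).
* **BIC** (between-individual component) is the V index,
  $V_i = 1 - \sum_j \min(p_{ij}, q_j)
        = \tfrac{1}{2}\sum_j |p_{ij} - q_j|$,
  i.e. one minus the proportional similarity of the individual to the
  population.

Two conventions exist for $q_j$ and both are exposed:

* `convention = "sum"` (default): pool all MNI counts of the campaign
  and normalise the column sums. Individuals with more prey items weigh
  more.
* `convention = "average"`: average the individual proportion vectors,
  giving each individual equal weight.

The two agree exactly when all individuals have the same diet total;
`campaign_traits()` takes the switch so results can be checked under
both.

**Size variability** is the mean pairwise Euclidean distance between
individuals in the plane of z-scored fork length and weight. The
z-scoring uses the *population* (divide by $n$) standard deviation,
the convention of classical multivariate ordination software; with
this choice two symmetric individuals sit at $z = \pm 1$ and their
distance is exactly $2\sqrt{2}$. With the sample ($n-1$) SD the same
configuration would yield $2$, so the choice is observable and is
therefore documented and pinned by tests.

## 3. Ecological opportunity

Campaign-level estimators from Surber point surveys:

* per-point prey **richness** and Shannon **diversity**, averaged;
* per-taxon mean densities, with the two focal mayfly taxa split at 5 mm
  into total and `*5sup` (>= 5 mm, inclusive) cohorts;
* spatial heterogeneity as the **CV** ($100\,s/\bar x$, sample SD) of
  each estimator across points and mean pairwise **Bray–Curtis**
  dissimilarity between point communities (pairs of two empty points are
  excluded rather than scored 0);
* abiotic summaries (means and CVs) of the habitat variables.

Campaigns differ in the number of points sampled (45–90), which biases
richness-like estimators. `opportunity_summary()` therefore
standardises every estimator by permutation: the mean of the estimator
over 1000 random subsamples of 45 points (`n_sub`, `iters`
configurable). A campaign with exactly 45 points returns its plain
estimate.

## 4. Electivity null models

`run_electivity()` tests, per campaign and prey taxon, whether consumption
deviates from availability-proportional feeding. Each simulation keeps
every individual's total MNI fixed and redistributes it by a multinomial
draw with probabilities proportional to surveyed availability. The
observed statistic is compared to the 95% envelope (2.5% and 97.5%
empirical quantiles) of 1000 simulations; values inside or on the
envelope are neutral. Taxa consumed but absent from the survey receive a
pseudo-availability of half the smallest nonzero availability, with a
warning. Calibration under the null itself classifies ~5% of taxa as
non-neutral (see the acceptance tests).

## 5. Confirmatory path analysis

The causal question — does ecological opportunity shape trait variation
directly or through prey availability? — is answered by piecewise path
models:

1. **Variable pruning.** `prune_correlated()` removes one variable of
   every pair with $|r| > 0.70$ (preferring to drop the CV member, then
   the alphabetically later name); `vif_prune()` then sequentially drops
   the predictor with the largest variance inflation factor until all
   VIF $\le$ 5. VIF here is computed from fixed-effects regressions of
   each predictor on the others, $1/(1-R^2_j)$.
2. **Local models.** Every structural equation is a linear mixed model
   with crossed site and year random intercepts
   (`fit_lmm()`, REML, lme4), fitted at the grain of its response:
   individual for the trait, campaign for prey/habitat summaries.
   Prey densities are ln(x+1) transformed first.
3. **d-separation.** The basis set contains every non-adjacent variable
   pair, conditioned on the union of both parent sets, with the
   causally downstream variable as the response. Independence claims
   between two exogenous variables are left free by default
   (`free_exogenous = TRUE`) — habitat variables correlate for
   non-causal reasons. Claim p-values combine into Fisher's
   $C = -2\sum\ln p \sim \chi^2_{2k}$; the model is rejected when
   $C$ is improbable.
4. **Selection.** `select_model()` applies a four-step simplification:
   (i) drop non-significant free covariances, (ii) sequentially drop the
   least significant path into the trait, refitting each time,
   (iii) drop prey/size nodes left without a path to the trait,
   (iv) sequentially drop non-significant habitat-to-prey paths. Ties
   are broken alphabetically.
5. **Reporting.** `standardized_estimates()` scales coefficients by
   $SD(x)/SD(y)$; `effect_decomposition()` splits each habitat
   variable's standardized effect into direct and prey-mediated
   (product of path coefficients) parts; `r2_mixed()` reports marginal
   (fixed-effects) and conditional (fixed + random) variance shares.

## 6. Seasonal contrasts

Variables retained in the final path models are compared between
seasons with `season_model()` (value ~ season + (1|site) + (1|year))
and `pairwise_seasons()`, Tukey-style multivariate-t adjusted contrasts
of estimated marginal means (emmeans).

## 7. Synthetic studies and ground truth

Two generators serve different purposes:

* `simulate_study()` is **mechanistic**: habitat fields drive
  negative-binomial prey counts; each fish forages on a local patch
  (`patch_radius`), with per-individual log-normal preference jitter
  (`heterogeneity`); diets are multinomial draws and detections sample
  finite genotype pools. Its planted quantities (preference weights,
  habitat–prey coefficients) are *mechanistic*, so standardized path
  coefficients are emergent, not planted. It is used for pipeline-level,
  electivity and monotonicity tests (campaign-mean BIC rises with
  heterogeneity and with more local foraging over heterogeneous prey).
* `simulate_path_study()` is a **linear structural** generator with
  exactly planted standardized coefficients (default direct habitat
  effect 0.3, habitat-to-prey 0.5, prey-to-trait 0.4, hence indirect
  0.2), unit trait variance, and site/year random intercepts. It is the
  oracle for d-separation calibration and path-coefficient recovery.

Test and calibration runs use reduced problem sizes (for example 30
campaigns of 10 individuals for the d-separation calibration) chosen so
the suite stays fast; these sizes are this package's own choices.

## 8. Limitations

* MNI underestimates consumption of abundant prey once genotype pools
  saturate; all diet proportions inherit that bias.
* The d-separation machinery assumes linear additive effects and
  Gaussian residuals; p-values for mixed models use the normal
  approximation to t-ratios.
* Campaign-level estimators enter individual-level models as repeated
  values; random intercepts absorb part of that pseudo-replication but
  standard errors for campaign-grain paths are computed at campaign
  grain.
* Electivity conclusions depend on the availability survey measuring
  what the predator can actually reach.

## 9. One-call pipeline

```{r, eval = FALSE}
study <- simulate_study(generator_config(seed = 1))
res <- run_pipeline(study$detections, study$fish, study$survey,
                    study$habitat, run_config(seed = 1), "run_out")
```

The same stages are exposed on the command line by
`inst/scripts/trophvar-cli.R`.
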