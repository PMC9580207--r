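# mirmark

Biomarker discovery for subtype-labelled expression cohorts with survival
follow-up, built for the five-class breast-cancer setting (Luminal A,
Luminal B, HER2-enriched, Basal-like, control) with miRNA features.

The procedure:

1. **Stratified split search.** 80% of each subtype is sampled into a
   training set (round half up per stratum; subtype sizes 86/39/24/41/41
   give 185 train / 46 test). Candidate split seeds are ranked by held-out
   ensemble accuracy, ties broken by floored cross-entropy.
2. **Bootstrap ensemble of elastic-net multinomial logistic regression.**
   M models, each fit on a per-subtype bootstrap resample of the training
   set, each with its own (α, λ) chosen from the grid
   α ∈ {0.05, 0.2, 0.4, 0.6, 0.8, 0.95} by seeded 10-fold CV on
   multinomial deviance (`glmnet` backend). Prediction is by majority
   vote; vote fractions act as class probabilities with loss
   (1/n) Σ −ln max(p_true, 0.001).
3. **Stability feature selection.** Per feature k and class j, count the
   models with a nonzero coefficient; keep features selected in at least
   half of the models per subtype (D_j), then keep features participating
   in ≥ 3 of the 5 subtypes (the panel D*).
4. **Cox promotion.** One multivariate Cox proportional-hazards fit over
   the panel (Efron ties, Wald p-values); features with |β| > 0.2 and
   p < 0.05 are flagged as biomarkers, reported with hazard ratios
   exp(β). Kaplan–Meier / log-rank and Wilcoxon expression contrasts
   support interpretation, and a shared-split harness compares
   classifiers (penalized MLR variants, RF, SVM, naive Bayes) across
   competing feature sets.

A seeded synthetic-cohort generator (`generate_cohort()`) emulates the
target data structure — five subtypes at the study's sample sizes,
log2-scale expression with planted subtype-specific and cross-subtype
markers, exponential survival driven by planted Cox effects with tuned
censoring — and returns the ground truth so every stage's recovery is
measurable without any data download.

## Worked example

```r
library(mirmark)

g <- generate_cohort(simulation_config(seed = 7))
g$cohort
#> <expression_cohort> 231 samples x 296 features (log2 scale)
#>   subtypes: LA=86 LB=39 H2=24 BL=41 control=41
#>   survival: 136 events, 41.1% censored

split <- stratified_split(g$cohort$labels, train_frac = 0.8, seed = 28)
split$per_subtype_train_counts
#>      LA      LB      H2      BL control
#>      69      31      19      33      33

ens <- train_ensemble(g$cohort, split, M = 10,
                      config = penalty_config(lambda_path_length = 50),
                      seed = 1)
pred <- vote_predict(ens, g$cohort$values[split$test_indices, ])
mean(pred$labels == g$cohort$labels[split$test_indices])
#> [1] 1

panel <- select_features(
  select_per_subtype(count_frequencies(ens), threshold = 5),
  min_subtypes = 1)
report <- filter_biomarkers(fit_cox(g$cohort, g$truth$multisubtype_features))
head(report[report$is_biomarker, c("feature_id", "beta",
                                   "hazard_ratio", "p_value")], 3)
#>   feature_id       beta hazard_ratio      p_value
#> 1    mir-290  0.8881431    2.4306120 6.169026e-14
#> 2    mir-121  0.7023194    2.0184287 1.869904e-12
#> 3    mir-093 -0.6814577    0.5058791 1.732120e-10
```

The split counts reproduce the published stratified-sampling arithmetic
exactly; the ensemble separates the planted subtype signal perfectly at
these settings (the generator's default effect size is deliberately
strong); and the Cox filter flags the planted prognostic features among
the cross-subtype markers, with hazard ratios above 1 for risk-increasing
and below 1 for protective expression.

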