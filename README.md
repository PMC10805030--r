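# polyomics

Poly-omic risk scores for multi-omic disease prediction.

Complex diseases such as inflammatory bowel disease (IBD) leave signatures
across many layers of the gut ecosystem at once: which microbes are present
(metagenomics, **MGN**), what they transcribe (metatranscriptomics,
**MTS**), which viruses co-occur (viromics, **VRM**), and which small
molecules accumulate (metabolomics, **MBL**). `polyomics` implements a
polygenic-risk-score-style framework for such data: within each omic layer
a sparse set of features is selected and weighted, each sample receives a
weighted-sum risk score, scores are averaged over an individual's
longitudinal samples, and the per-layer scores are finally combined in one
multi-omic model. The framework makes the *relative* predictive value of
each omic layer directly comparable.

## The model

For each omic layer, features pass layer-specific preprocessing:

* compositional count layers (MGN, MTS, VRM) are centered-log-ratio (CLR)
  transformed, `clr(x)_j = ln((x_j + c) / g(x + c))` with `g` the row
  geometric mean;
* metabolite intensities (MBL) are log10 transformed;
* sparsity filters remove features found in fewer than 5% of samples
  (VRM) or keep only compounds present in >99% of samples (MBL); one of
  any two features with Pearson |r| > 0.95 is removed at random (MTS,
  MBL); features with post-transform SD below 1 (MGN, MTS) or 0.1 (VRM,
  MBL) are dropped.

Feature selection then fits an L1-penalized mixed-effects logistic
regression on the training samples,

```
y = mu + sum_i beta_i feature_i + beta age + beta sex + beta race
      + beta antibiotic_use + (1|site) + (1|participant)
```

across a descending grid of penalty weights lambda; the lambda at the
elbow of the selected-feature-count curve is kept. The selected features
are re-fitted *unpenalized* in the same mixed-model structure
(`lme4::glmer`), so the feature weights are estimated while age, sex,
race, antibiotic use, study site and repeated sampling per participant are
accounted for. A sample's risk score is the covariate-free weighted sum

```
score_i = beta_1 feature_1i + ... + beta_n feature_ni
```

standardized against the training scores and averaged per participant.
Evaluation on held-out participants reports AUC with DeLong 95% CI, the
odds ratio per SD of score (Wald CI) and Nagelkerke's pseudo R²; the
combined model `y ~ MGN + MTS + VRM + MBL + age + sex` quantifies what the
layers contribute jointly, including a leave-one-omic-out decomposition.

A bundled synthetic-cohort generator (`simulate_cohort()`,
`hmp2_like_design()`) emulates a 130-participant, 5-site longitudinal IBD
cohort with four omic layers, realistic per-layer sparsity and missingness
and planted feature effects, so the whole pipeline is testable end to end
with known ground truth. A small KEGG-orthology module
(`classify_origins()`) classifies selected metabolites as host-derived,
microbially derived, or neither, from plain-text KO sets and
compound-to-KO maps.

## Worked example

```r
library(polyomics)

run <- run_polyomic(hmp2_like_design(seed = 1),
                    config = polyomic_config(seed = 1))
run$manifest$layer_summary
#>   layer features_raw features_qc n_selected pct_selected lambda
#> 1 MGN            578         308         30         9.74  1.28
#> 2 MTS            421         208         43        20.7   1.20
#> 3 VRM            239          25         18        72     0.317
#> 4 MBL            596         324         51        15.7   4.55

ev <- tidy(run)
ev[ev$mode == "adjusted", c("layer","auc","auc_lo","auc_hi","or","r2")]
#>   layer   auc auc_lo auc_hi      or     r2
#> 1   MGN 0.535  0.316  0.753   0.954 0.0700
#> 2   MTS 0.500  0.251  0.749   0.878 0.0707
#> 3   VRM 0.861  0.617  1.000 131.473 0.5973
#> 4   MBL 0.965  0.907  1.000 205.208 0.7299

glance(run)
#>   n_participants n_samples n_validation validation_pct combined_r2 combined_auc
#> 1            130      1690           30             23       1.000            1
```

Reading the output: each layer's feature table is filtered (e.g. the
highly sparse virome collapses from 239 to 25 usable features), the
penalty path selects a sparse model per layer, and validation-set
participants are scored. In this simulated cohort the planted effects are
strong in the metabolomic and viromic layers and weak in metagenomics and
metatranscriptomics, and the evaluation recovers exactly that ordering:
MBL and VRM discriminate IBD cases from controls well (AUC 0.97 and 0.86,
large ORs per SD), while MGN and MTS sit near chance. The combined model
on the 30 held-out participants separates the classes completely here
(R² ~ 1), which the collinearity/separation warnings flag as an
artefact of the small validation set. `plot_scores(run)`,
`autoplot(run$layers$MBL$path)` and `autoplot(run$combined)` draw the
score-by-diagnosis, penalty-path and OR forest figures.

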