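# ldapanel

Two-stage linear-discriminant selection of minimal metabolite panels for
multi-class clinical discrimination.

## The problem

Targeted metabolomics assays report the concentration (µM) of a few hundred
small molecules per sample. In small clinical cohorts — here the motivating
setting is an aqueous-humour cohort of healthy controls, open-angle glaucoma
patients and type-2 diabetes patients — no single metabolite separates all
groups, but a small *combination* of metabolites often can. The practical
questions are: which metabolites, how few of them, and does a non-linear
combination of their concentrations do better than the raw levels?

`ldapanel` answers these with a two-step "hidden layer" built on linear
discriminant analysis (LDA):

1. **Stage 1 — metabolite subset search.** For every panel size *k*, find
   the metabolite subset maximizing leave-one-out (LOO) classification
   accuracy, and stop at the plateau where adding metabolites no longer
   helps.
2. **Stage 2 — monomial term search.** Over the winning panel, build every
   monomial of total degree ≤ 3 (levels, squares, cubes, double and triple
   products — `choose(m+3, 3) − 1` terms for *m* metabolites) and repeat the
   subset search over these variables, so that class structure visible only
   in products like C3·Ac-Orn can be exploited.

## The model

For classes *k = 1…K* with mean vectors μₖ and a pooled within-class
covariance S = Σₖ(nₖ−1)Sₖ/(n−K), a subject with feature vector x is scored
by the Mahalanobis distance d²ₖ = (x−μₖ)ᵀS⁻¹(x−μₖ) and classified by the
Bayes posterior

  P(k | x) ∝ πₖ · exp(−d²ₖ/2),

with priors πₖ either the class sample shares (default) or equal. With equal
priors this is assignment to the Mahalanobis-nearest centroid. Discriminant
axes LD1, LD2 (at most K−1 of them) are the eigenvectors of the
within⁻¹·between scatter problem, scaled to unit pooled within-class
variance; they support a 2-D map in which the decision regions are the
"cake-slice" nearest-centroid partitions. Every accuracy the package reports
is leave-one-out: the model is refit from scratch on n−1 subjects and the
held-out subject is classified, for each subject in turn.

Because the real cohorts behind such studies are rarely deposited, the
package ships a synthetic-cohort generator (`synthetic_config()`,
`generate_cohort()`) producing log-normal concentration tables with planted
class-shifted markers, correlated metabolite blocks, an optional
product-only (non-linear) class signal, and group-specific ages — so every
stage of the pipeline is testable against known ground truth.

## Worked example

A 46-subject synthetic cohort (31 controls, 8 glaucoma, 7 diabetes) with two
planted markers among 18 noise metabolites:

```r
library(ldapanel)

cfg <- synthetic_config(
  n_per_group = c(31, 8, 7), n_metabolites = 20,
  class_names = c("Control", "Glaucoma", "Diabetes"),
  metabolite_names = c(sprintf("M%03d", 1:18), "Ac-Orn", "PC aa C42:6"),
  markers = list(list(index = 19, shift = c(1, 1.3, 4.0)),
                 list(index = 20, shift = c(1, 4.0, 1.2))),
  correlation_blocks = list(list(indices = c(19, 20), rho = 0.45)),
  noise_sigma = 0.4, seed = 42)
tab <- generate_cohort(cfg)

head(single_feature_ranking(tab)$ranking, 3)
#>    metabolite  accuracy
#> 1 PC aa C42:6 0.7608696
#> 2      Ac-Orn 0.7391304
#> 3        M009 0.6956522
```

Both planted markers top the single-metabolite ranking: `PC aa C42:6`
(shifted 4-fold in glaucoma) alone classifies 76% of subjects. Stage 1 then
grows the panel:

```r
s1 <- stage1_search(tab, max_k = 4, strategy = "forward")
s1
#> Best-subset search (forward): 74 leave-one-out evaluations
#>   k=1  acc=0.7609  cum=0.7609  {PC aa C42:6}
#>   k=2  acc=0.8261  cum=0.8261  {Ac-Orn, PC aa C42:6}
#>   k=3  acc=0.8478  cum=0.8478  {M009, Ac-Orn, PC aa C42:6}
#>   k=4  acc=0.8696  cum=0.8696  {M001, M009, Ac-Orn, PC aa C42:6}
#> selected: k=4 {M001, M009, Ac-Orn, PC aa C42:6}, accuracy 0.8696
```

Stage 2 expands the winning panel into its 34 degree-≤3 monomials and
searches again; interaction and power terms lift the LOO accuracy from 87%
to 91%:

```r
terms <- expand_terms(s1$selected_names, max_degree = 3)
s2 <- stage2_search(tab, terms, max_vars = 4, strategy = "beam")
s2
#> Best-subset search (beam): 1606 leave-one-out evaluations
#>   k=1  acc=0.7609  cum=0.7609  {PC aa C42:6}
#>   k=2  acc=0.8478  cum=0.8478  {PC aa C42:6, M001*Ac-Orn}
#>   k=3  acc=0.8913  cum=0.8913  {Ac-Orn, PC aa C42:6, Ac-Orn^2}
#>   k=4  acc=0.9130  cum=0.9130  {M009, Ac-Orn, PC aa C42:6, M001*Ac-Orn^2}
#> selected: k=4 {M009, Ac-Orn, PC aa C42:6, M001*Ac-Orn^2}, accuracy 0.9130

design <- build_design(tab, terms)[, s2$selected_features, drop = FALSE]
loo <- loo_evaluate(design, groups = tab$group, ids = tab$subject_id)
loo$report
#> Confusion matrix (rows = real class, columns = predicted class):
#>           predicted
#> real       Control Glaucoma Diabetes
#>   Control       31        0        0
#>   Glaucoma       3        5        0
#>   Diabetes       1        0        6
#> Overall accuracy: 0.9130 (n = 46)
#>          sensitivity specificity    ppv    npv
#> Control       1.0000      0.7333 0.8857 1.0000
#> Glaucoma      0.6250      1.0000 1.0000 0.9268
#> Diabetes      0.8571      1.0000 1.0000 0.9750
```

All 31 controls are recovered; 42 of the 46 subjects have a posterior above
0.5 for their true class (`posterior_table()`). The whole
simulate → stage 1 → stage 2 → evaluate → map sequence, with TSV/JSON
artifacts and a reproducibility manifest, is available as one call through
`pipeline_config()` + `run_pipeline()`; `region_grid()` draws the LD1/LD2
decision regions, and `classification_report()`, `pearson_cor()`,
`correlation_matrix()`, `anova_oneway()`, `summarize_by_group()` and
`age_filter()` cover the surrounding descriptive statistics (including an
age-matched reanalysis after filtering young controls).

See `vignettes/panel-selection.Rmd` for the full account of the model,
the synthetic-data design and the numerical choices.

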