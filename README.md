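# pathcomorbid

Multi-modal integration of disease genetics, real-world comorbidity and
expression data at the level of biological pathways, with Alzheimer's
disease (AD) as the anchor phenotype.

The package implements, as tested R functions over plain-text interchange
formats, a four-stage analysis:

1. **Pathway-space disease overlap.** From a disease–gene association
   catalog (top 25 genes per disease, diseases with ≥ 25 genes) and a
   KEGG-style gene-set annotation, build the gene × gene matrix
   n(α, β) = number of pathways shared by genes α and β, and test every
   disease pair with a one-tailed Wilcoxon rank-sum comparison of
   S+ = {n(α, β) : α ∈ A, β ∈ B} against S− = {n(α, β) : exactly one of
   α ∈ A, β ∈ B}, Bonferroni-corrected over all pairs. Self-pairs are
   excluded so shared genes cannot masquerade as shared pathways.
2. **Pathway load vs AD comorbidity.** Per disease A and pathway p,
   load(A, p) = m(A, p) / Σ_ρ m(A, ρ), the fraction of A's gene–pathway
   membership incidences on p. From hospital-discharge-style records,
   select AD cases (ICD-9-CM 331.0, age > 60), match one control per case
   exactly on sex, age, race and survey year, and form
   ratioAD(A) = (cases carrying A) / (matched controls carrying A) for
   diseases with > 15 carriers. Per pathway, Pearson-correlate loads with
   ratios across diseases.
3. **Pathway expression dysregulation.** Per gene, a logistic model of AD
   status on expression adjusted for age, sex and centre; pathway-level
   evidence from the exact binomial tail P(X ≥ k | n, p0 = 0.05) for k
   significant genes of n measured; Spearman concordance of per-gene
   p-values across studies; sample-wise merging of studies on shared genes.
4. **qPCR quantification.** 2^−ΔΔCT fold changes against housekeeping
   genes (Hprt, Actb), calibrated to the control group, with equal-variance
   t-tests on the ΔΔCT scale.

A synthetic-data generator (`sim_config()` + `simulate_*`) emulates all
inputs — association catalog, GMT pathways, 50,000-patient discharge
cohort, expression studies, qPCR plates — with plantable effects (a disease
pair sharing pathway-linked genes, a comorbidity-driving pathway, a
dysregulated 47-gene pathway, known fold changes), so every stage has null-
calibration and parameter-recovery tests without any external download.

## Worked example

Plant a pair of diseases sharing 20 pathway-linked genes, scan all pairs,
and quantify a qPCR plate with a planted two-fold induction:

```r
library(pathcomorbid)

cfg <- sim_config(n_diseases = 10,
                  planted_disease_pairs = list(list("D01", "D02", 20)),
                  seed = 7)
sim     <- simulate_catalog_and_pathways(cfg)
catalog <- retain_catalog(sim$catalog)
mat     <- build_shared_matrix(catalog, sim$annotation)
all_pairs_overlap(catalog, mat)
#> overlap_scan: 45 pairs, 2 significant at adjusted alpha = 0.05 (bonferroni)

pathway_binomial_test(15, 47, 0.05)   # 15 of 47 pathway genes significant
#> [1] 4.960138e-09

plate <- simulate_qpcr_plate(c(Jak1 = 2), seed = 11)
ddct_fold_changes(plate, "Jak1", c("Hprt", "Actb"))
#> fold_change_result Jak1 (calibrator: PBS )
#>       mean_fold   sem
#> Abeta      1.99 0.031
#> PBS        1.00 0.008
```

The scan's top pair is the planted one (`D01 ~ D02`, Bonferroni-adjusted
p ≈ 0); the binomial tail says 15 significant genes out of 47 is far more
than the ~2.4 expected by chance; the recovered fold of 1.99 ± 0.03 matches
the planted two-fold induction (the control group's mean fold is 1 by
construction of the calibrator).

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic data
with planted effects, writing inputs under `results/data/` and result
tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # catalog, GMT, cohort, expression, qPCR
Rscript analysis/02_overlap.R      # all-pairs scan; finds the planted pair
Rscript analysis/03_comorbidity.R  # matching, ratios, load-ratio correlation
Rscript analysis/04_expression.R   # per-gene GLM, binomial enrichment, concordance
Rscript analysis/05_qpcr.R         # 2^-ddCT folds and t-tests
```

On the default seed, stage 3 prints (the planted pathway ranking first and
surviving Bonferroni):

```
1614 AD cases; 1614 matched 1:1 (0 dropped, no exact twin)
20 diseases pass the >15-patient filter; 198 pathways correlated
top pathway: P109 (r = 0.852, p = 1.83e-06, Bonferroni 0.000362) -- the planted pathway
```

`run_pipeline()` chains the same stages programmatically and returns a
deterministic JSON-serialisable report.

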