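---
title: "Methods: pathway-space disease overlap, comorbidity and expression dysregulation"
author: "pathcomorbid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway-space disease overlap, comorbidity and expression dysregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcomorbid)
```

`pathcomorbid` chains four analyses that together ask whether a molecular
pathway links a disease's genetics to its clinical co-occurrence with other
diseases, using Alzheimer's disease (AD) as the anchor phenotype. Each stage
is an ordinary, well-understood statistic; the package's contribution is the
pipeline that connects them and a synthetic-data generator that plants known
effects, so that every stage carries a parameter-recovery test instead of
depending on external data snapshots.

## 1. Disease overlap in pathway space

The genetic input is a catalog of disease-gene associations in the style of
GWAS summary catalogs: `(disease, gene, p-value)` triples. Only diseases
with at least `min_genes` (default 25) associated genes enter, and per
disease only the `top_k` (default 25) genes with the smallest association
p-values are retained (`retain_catalog()`). Ties in p-value are broken by
input order, then gene symbol, so retention is deterministic.

For any two genes $\alpha, \beta$ in the retained universe,
$n(\alpha,\beta)$ counts the pathways (KEGG-style gene sets, carried in GMT
format) that annotate both genes; `build_shared_matrix()` assembles the
symmetric gene-by-gene matrix, whose diagonal holds each gene's own
membership count and whose rows are zero for unannotated genes.

To ask whether diseases $A$ and $B$ overlap in pathway space more than
chance, `overlap_test()` compares two samples of shared-pathway counts:

* $S_+$ — counts $n(\alpha,\beta)$ over unordered gene pairs with one gene
  in $A$'s retained set and the other in $B$'s;
* $S_-$ — counts over pairs where exactly one gene belongs to the
  corresponding disease set, the partner ranging over the whole retained
  universe.

A one-tailed Wilcoxon rank-sum test asks whether $S_+$ is stochastically
greater than $S_-$. Three conventions matter and are fixed as follows:

* **Self-pairs are excluded.** A gene paired with itself contributes its
  own membership count, which reflects shared *genes*, not shared
  *pathways*; the whole diagonal is excluded from both samples so that a
  gene associated with both diseases cannot drive the test by itself.
* **Unordered pairs enter once.** Counting $(\alpha,\beta)$ and
  $(\beta,\alpha)$ separately would double both sample sizes without adding
  information and overstate significance. (This also makes the test exactly
  symmetric in $A$ and $B$, which the suite asserts.)
* **Cross-pairs of shared genes go to $S_+$ only.** A pair with one end in
  both diseases satisfies the $S_+$ membership rule, and the
  exactly-one-membership rule for $S_-$ is applied literally.

All disease pairs are tested by `all_pairs_overlap()`, with Bonferroni
correction over the number of pairs (Benjamini-Hochberg behind a flag). No
clustering algorithm is imposed on the results: the output is the
significance graph — adjacency, connected components, per-disease counts of
significant partners, and significant-pair counts within any user-supplied
disease subset — which supports "k of the m pairs in this group" summaries
without committing to a cluster definition.

### Numerical behaviour of the rank-sum test

Shared-pathway counts are small integers, so ties dominate. The test uses
midranks throughout. When both samples have at most 8 elements the p-value
is computed by exhaustive enumeration of all $\binom{n+m}{n}$ assignments
of the pooled values, which is exact under ties; the suite checks this path
against an independently coded enumeration oracle at tolerance $10^{-10}$
for every size pair up to $8 \times 8$. Larger samples use the normal
approximation with tie-corrected variance and a continuity correction,
which the suite cross-checks against `stats::wilcox.test` and against the
exact path at the cutoff size. If the pooled sample is constant the
variance is zero and the p-value is 1. Pairs where either sample has fewer
than 3 gene pairs are flagged and given p = 1 rather than a fragile
estimate.

## 2. Pathway load and comorbidity

For disease $A$ and pathway $p$, $m(A,p)$ counts $A$'s retained genes
annotated to $p$, and the pathway load is

$$\mathrm{load}(A,p) = \frac{m(A,p)}{\sum_{\rho} m(A,\rho)},$$

where the denominator runs over all of $A$'s gene-pathway membership
incidences (a gene in three pathways contributes three). The normalisation
controls for diseases whose genes are more densely annotated; loads sum to
one within each disease, which the suite asserts as an invariant.

The clinical input is a hospital-discharge-style table of patient records
with demographics and ICD-9-CM diagnosis code lists. AD cases are records
carrying code 331.0 and aged strictly over 60 (late-onset disease).
`match_controls()` pairs each case with one control — a patient without the
AD code — matched exactly on sex, age in integer years, race and survey
year, without replacement. The matching algorithm is randomised exact
matching: cases are processed in a seed-shuffled order and each draws a
uniformly random unused control from its stratum; cases with no exact twin
left are dropped and reported. Exact matching guarantees the matched
controls reproduce the cases' joint key distribution as a multiset
(asserted in the suite). Age matching is exact by default because nothing
in the design demands a caliper; a `caliper` argument widens the age window
if a cohort is too sparse.

For each disease code, the comorbidity ratio is

$$\mathrm{ratio}_{AD}(A) = \frac{\#\{\text{matched cases carrying } A\}}
{\#\{\text{matched controls carrying } A\}},$$

computed only for diseases with strictly more than `min_patients` (default
15) carriers among cases and controls combined, and undefined (excluded,
with a warning) when the control count is zero. Code matching is by prefix,
following the ICD-9-CM hierarchy ("250" matches "250.1"), with exact
matching available. Finally `correlate_load_vs_ratio()` computes, per
pathway, Pearson's correlation between the diseases' loads and their
comorbidity ratios, Bonferroni-corrected over the pathways tested; diseases
without a load entry for a pathway contribute load 0, and pathways with a
constant load vector are skipped. A disease-subset filter expresses
analyses restricted to, say, inflammatory diseases, without hard-coding any
disease class.

## 3. Expression dysregulation

Expression studies are genes-by-samples matrices (assumed log-scale and
pre-normalised) with a sample sheet carrying diagnosis (AD / MCI /
control), age, sex and centre. `per_gene_glm()` fits, per gene, a logistic
regression of case status on the gene's expression adjusted for age, sex
and centre (terms dropped automatically when single-valued), and reports
the Wald p-value of the expression term. Expression is standardised per
gene before fitting — p-values are invariant to this affine transform, and
it stabilises the optimiser. Genes with zero variance, non-converged or
separated fits are flagged with `NA` p-values rather than silently dropped;
samples with missing covariates are removed once, globally, with the count
recorded. The Wald test is the default (a likelihood-ratio variant would be
a one-line change) because at the sample sizes involved the two are
practically indistinguishable and Wald preserves the per-term reporting
convention.

Pathway-level evidence is the exact binomial tail: if $k$ of a pathway's
$n$ measured genes are individually significant, the enrichment p-value is
$P(X \ge k)$ for $X \sim \mathrm{Binomial}(n, p_0)$, computed by direct
summation of the mass function — no normal approximation, as the suite's
$10^{-12}$ oracle comparison requires. The chance level is fixed at
$p_0 = 0.05$, the nominal per-gene significance level, *regardless* of the
multiplicity rule used to call genes significant. This convention is
deliberately kept even when gene-level calls use Bonferroni or FDR
adjustment: mixing an adjusted call rate with a matching adjusted $p_0$
would make the enrichment test's meaning depend on the gene universe, and
the fixed-$p_0$ form is the one whose worked examples
($P(X\ge15\,|\,47) \approx 5\times10^{-9}$,
$P(X\ge6\,|\,47) \approx 0.03$, $P(X\ge10\,|\,47) \approx 9\times10^{-5}$,
$P(X\ge8\,|\,32) \approx 10^{-4}$) the test suite reproduces. The
inconsistency between this convention and corrected gene-level calls is
documented rather than resolved.

`significance_rule()` implements the raw, Bonferroni (family = genes
tested) and Benjamini-Hochberg rules; `cross_dataset_concordance()`
computes the Spearman correlation of per-gene p-values over the gene
intersection of two studies; `merge_studies()` concatenates studies on
their shared genes, labelling the centre covariate with the study of origin
so the model absorbs between-study shifts like any other batch term. One
practical note: a rank correlation of p-values is only informative when the
tested genes are heterogeneous — over a set of genes that are all strongly
and equally dysregulated, the ranks are noise. The concordance default is
therefore best applied to a mixed gene set (e.g. pathway genes plus
unaffected genes, or all measured genes).

## 4. qPCR quantification

`ddct_fold_changes()` implements relative quantification by
$2^{-\Delta\Delta C_T}$: technical replicates are averaged to one crossing
threshold per sample and gene; the normaliser is the arithmetic mean of the
housekeeping genes' mean CTs (arithmetic on the cycle scale = geometric on
the linear scale; with the default two housekeeping genes their order is
irrelevant, asserted in the suite); $\Delta C_T$ is target minus
normaliser; the calibrator is the control group's mean $\Delta C_T$; and
the fold change is $2^{-\Delta\Delta C_T}$. Two identities follow by
construction and are asserted as invariants: the control group's mean
$\Delta\Delta C_T$ is exactly zero (equivalently, its geometric mean fold
is 1), and folds are invariant to adding a constant to every CT on the
plate (RNA-input and plate shifts cancel). Group comparison uses the
equal-variance two-sample t-test on the $\Delta\Delta C_T$ scale: folds are
log-normal, so the cycle scale is the one matching the t-test's
assumptions; a `on = "fold"` flag tests the fold scale for users who want
the mimicry. Samples missing a housekeeping measurement are excluded with a
warning, and identical groups return p = 1.

## 5. The synthetic-data generator

All inputs are generated by `simulate_*` functions driven by a single
validated `sim_config()`; every stage derives its own stream from the one
seed (`split_seed()`), so identical configurations give byte-identical
outputs and stages can be regenerated independently.

The defaults define the reference conditions used across the test-suite:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 500 | matches the retained universe of 20 diseases x 25 genes |
| `n_pathways`, `pathway_size_range` | 200, 5-10 | about 3 memberships per gene, a KEGG-like density that produces realistic tie structure in $n(\alpha,\beta)$ |
| `n_diseases`, `genes_per_disease` | 20, 25 | the catalog retention size |
| `n_patients` | 50,000 | enough for ~1,500 AD cases at 5% prevalence over age 60 |
| `ad_prevalence`, `disease_prevalence` | 0.05, 0.02 | hospital-discharge-scale rates giving >15 carriers per disease after matching |
| `n_samples_per_group` | 100 | the blood-cohort scale |
| `effect_size` | 0 (1 when planted) | standardised mean shift in case samples |
| `noise_sd` | 1 | per-gene Gaussian residual scale |

Planted structure is what makes recovery testable. A planted disease pair
adds the stated number of genes from each disease to a small set of shared
"carrier" pathways, raising $n(\alpha,\beta)$ for cross-disease gene pairs.
A planted comorbidity pathway (`plant_comorbidity_effects()`) sets each
disease's relative risk among AD cases to rise linearly with its load on
that pathway, up to 3 — the same magnitude as the generator's own
relative-risk recovery example. A planted expression effect shifts the
pathway's genes by `effect_size * noise_sd` in AD samples (half in MCI,
treated as an intermediate phenotype). qPCR plates lower the treated
group's target CT by $\log_2(\text{fold})$ and add a per-sample RNA-input
shift that normalisation must remove.

What the generator does *not* emulate, deliberately: survey design
(hospital strata, sampling weights), real pathway topology or inter-pathway
correlation beyond random co-membership, expression heteroskedasticity,
probe-level artefacts, or qPCR amplification-efficiency differences.
Passing recovery tests therefore show that the pipeline's statistics detect
the effects they were designed for at realistic scales — not that the
pipeline is robust to every failure mode of real catalogs, discharge
records or microarrays.

## 6. Calibration checks and their design

The suite's null-calibration checks simulate 100 unplanted datasets at the
reference conditions and verify that each downstream test's rejection rate
at $\alpha = 0.05$ falls inside the exact binomial 95% band. One test per
seed is used deliberately: tests within one dataset (different disease
pairs, different pathways) are mutually correlated, and pooling them would
invalidate the binomial band. For the load-ratio check, the pathway tested
is the one with the widest load spread — a choice made from the loads
alone, which under the null is independent of the ratios, so calibration is
preserved while guaranteeing a testable (non-constant) load vector.

Two caveats are worth knowing. First, the gene-pair samples $S_+$ and
$S_-$ share genes, so the rank-sum test's independence assumption holds
only approximately and its null rejection rate can sit slightly above the
nominal level (the acceptance script measures and reports it). This is a
property of the method's definition, not of the implementation (which
matches exact enumeration), and it is inherited by any analysis built on
this statistic. Second, the binomial enrichment test is discrete: at
$n = 47$ genes it rejects only when $k \ge 6$, an event of probability
0.03 under the null, so it runs conservative — also visible in the
calibration numbers.

## 7. Problem sizes

Simulation scales were chosen to make every suite run informative at
desk scale: 100-seed calibrations and recoveries at 20 diseases x 200
pathways, 50,000-patient cohorts, 100 samples per expression group, and
10-disease scans for the planted-pair recovery (45 pairs per seed). The
whole suite and the acceptance script each complete in a few minutes on a
single CPU; all scales are configuration arguments, so larger studies are
one `sim_config()` call away.

## 8. Interfaces

Every stage reads and writes plain-text interchange formats: GMT for
pathways, TSV for the catalog, loads and all results tables, CSV for the
cohort (semicolon-joined diagnosis codes) and qPCR plates. Writers stamp a
`#`-prefixed header with the package version, seed and a configuration
hash; readers skip comment lines and reject malformed records (wrong column
sets, non-numeric p-values or CTs, empty code lists, duplicate pathway ids)
rather than coercing them. `run_pipeline()` chains the stages over one
configuration and emits a deterministic JSON report; the numbered scripts
under `analysis/` drive the same functions as a narrated workflow, and
`scripts/acceptance.R` recomputes the headline quantities from scratch.
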