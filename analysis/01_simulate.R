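#!/usr/bin/env Rscript
# Stage 1: generate every pipeline input with known planted structure.
#
# Plants three effects so the downstream stages have something to find:
#   * diseases D01 and D02 share 20 pathway-linked susceptibility genes;
#   * one pathway (the one whose load varies most across diseases) drives
#     AD comorbidity, with relative risks up to 3;
#   * a 47-gene pathway is shifted by 1 SD in AD samples of the expression
#     study, mirroring the blood-cohort design (plus a second, independent
#     replication study);
#   * qPCR folds of 2 for Jak1/Jak2/Tyk2 and 1 for Jak3 over 5+5 samples.
#
# Writes all inputs under results/data/ in their interchange formats.

suppressPackageStartupMessages(library(pathcomorbid))
seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(planted_disease_pairs = list(list("D01", "D02", 20)),
                  seed = seed)
sim <- simulate_catalog_and_pathways(cfg)
write_catalog_tsv(sim$catalog, file.path(out, "catalog.tsv"), seed, cfg)
write_gmt(sim$annotation, file.path(out, "pathways.gmt"))
message("catalog: ", length(unique(sim$catalog$disease)), " diseases x ",
        cfg$genes_per_disease, " genes; ", length(sim$annotation$sets),
        " pathways")

# plant the comorbidity effect on the most identifiable pathway, avoiding
# the carrier pathways of the disease-pair plant (their loads are mutually
# correlated, which would blur which pathway was planted)
loads <- pathway_load(retain_catalog(sim$catalog), sim$annotation)
carriers <- utils::tail(names(sim$annotation$sets), cfg$n_planted_pathways)
W <- load_matrix(loads)
W <- W[, setdiff(colnames(W), carriers), drop = FALSE]
pw <- colnames(W)[which.max(apply(W, 2, sd))]
rr <- plant_comorbidity_effects(loads, pathway = pw, max_rr = 3)
writeLines(attr(rr, "pathway"), file.path(out, "planted_pathway.txt"))
cfg_cohort <- sim_config(planted_disease_pairs = list(list("D01", "D02", 20)),
                         comorbidity_effects = rr, seed = seed)
cohort <- simulate_discharge_cohort(cfg_cohort)
write_cohort_csv(cohort, file.path(out, "cohort.csv"), seed, cfg_cohort)
message("cohort: ", nrow(cohort), " patients; planted comorbidity pathway: ",
        attr(rr, "pathway"))

# expression studies: a 47-gene dysregulated pathway, two independent cohorts
cfg_expr <- sim_config(n_genes = 300, n_pathways = 50,
                       pathway_size_range = c(47, 47),
                       dysregulated_pathway = "P001", effect_size = 1,
                       seed = seed)
ann_expr <- simulate_catalog_and_pathways(cfg_expr)$annotation
write_gmt(ann_expr, file.path(out, "expression_pathways.gmt"))
for (nm in c("study1", "study2")) {
  cfg_i <- cfg_expr
  cfg_i$seed <- split_seed(seed, match(nm, c("study1", "study2")) + 10L)
  study <- simulate_expression_study(cfg_i, ann_expr)
  write_expression_tsv(study,
                       file.path(out, paste0(nm, "_expression.tsv")),
                       file.path(out, paste0(nm, "_samples.tsv")),
                       cfg_i$seed, cfg_i)
  message(nm, ": ", nrow(study$expr), " genes x ", ncol(study$expr),
          " samples")
}

plate <- simulate_qpcr_plate(c(Jak1 = 2, Jak2 = 2, Jak3 = 1, Tyk2 = 2),
                             seed = seed)
write_qpcr_csv(plate, file.path(out, "qpcr_plate.csv"), seed)
message("qPCR plate: ", length(unique(plate$sample)), " samples x ",
        length(unique(plate$gene)), " genes, triplicates")
message("inputs written to ", out)
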