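#!/usr/bin/env Rscript
# Stage 4: pathway expression dysregulation.
#
# For each of the two expression studies: per-gene logistic model of AD
# status on expression adjusted for age, sex and centre over the 47 genes
# of the dysregulated pathway, count of significant genes (raw p < 0.05),
# and the exact binomial enrichment p against a 5% chance level. Then the
# Spearman concordance of per-gene p-values between the studies, and the
# same enrichment analysis on the merged studies.

suppressPackageStartupMessages(library(pathcomorbid))
data_dir <- "results/data"
out <- "results"
pathway <- "P001"

annotation <- read_gmt(file.path(data_dir, "expression_pathways.gmt"))
studies <- lapply(c(study1 = "study1", study2 = "study2"), function(nm) {
  read_expression_tsv(file.path(data_dir, paste0(nm, "_expression.tsv")),
                      file.path(data_dir, paste0(nm, "_samples.tsv")))
})

rows <- list(); glms <- list()
for (nm in names(studies)) {
  enr <- pathway_enrichment(studies[[nm]], annotation, pathway,
                            method = "raw", alpha = 0.05, p0 = 0.05)
  glms[[nm]] <- enr$glm_results
  rows[[nm]] <- data.frame(study = nm, n_measured = enr$n_measured,
                           k_significant = enr$k,
                           p_binomial = enr$p_binomial)
  message(nm, ": ", enr$k, " of ", enr$n_measured,
          " pathway genes dysregulated (binomial p = ",
          signif(enr$p_binomial, 2), ")")
}

# concordance over all measured genes: the shared signal is which genes
# carry the effect, so the rank correlation needs affected and unaffected
# genes together (over pathway genes alone, all of which are shifted
# equally by construction, ranks would be pure noise)
all_glms <- lapply(studies, per_gene_glm)
cc <- cross_dataset_concordance(all_glms$study1, all_glms$study2)
message("between-study concordance of per-gene p-values: rho = ",
        signif(cc$rho, 3), " (p = ", signif(cc$p, 2), ", ", cc$n, " genes)")

merged <- merge_studies(studies)
enr_m <- pathway_enrichment(merged, annotation, pathway)
rows$merged <- data.frame(study = "merged", n_measured = enr_m$n_measured,
                          k_significant = enr_m$k,
                          p_binomial = enr_m$p_binomial)
message("merged: ", enr_m$k, " of ", enr_m$n_measured,
        " genes dysregulated (binomial p = ", signif(enr_m$p_binomial, 2), ")")

enrich <- do.call(rbind, rows)
write.table(enrich, file.path(out, "expression_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, glms), file.path(out, "expression_per_gene.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
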