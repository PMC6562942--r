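#!/usr/bin/env Rscript
# Stage 3: pathway load versus AD comorbidity.
#
# Computes per-disease pathway loads from the catalog, selects AD cases
# (code 331.0, age > 60) from the discharge cohort, matches one control per
# case on sex, age, race and survey year, forms comorbidity ratios for the
# diseases with enough patients, and correlates each pathway's loads with
# the ratios. The planted pathway should rank first and survive Bonferroni.

suppressPackageStartupMessages(library(pathcomorbid))
seed <- 1L
data_dir <- "results/data"
out <- "results"

catalog <- retain_catalog(read_catalog_tsv(file.path(data_dir, "catalog.tsv")))
annotation <- read_gmt(file.path(data_dir, "pathways.gmt"))
cohort <- read_cohort_csv(file.path(data_dir, "cohort.csv"))
planted <- readLines(file.path(data_dir, "planted_pathway.txt"))

loads <- pathway_load(catalog, annotation)
cases <- select_ad_cases(cohort)
matched <- match_controls(cases, cohort, seed = seed)
message(nrow(cases), " AD cases; ", nrow(matched$cases), " matched 1:1 (",
        length(matched$dropped), " dropped, no exact twin)")

ratios <- comorbidity_ratios(matched, sort(unique(catalog$disease)))
corr <- suppressWarnings(correlate_load_vs_ratio(loads, ratios))

write.table(loads, file.path(out, "pathway_loads.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ratios, file.path(out, "comorbidity_ratios.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(corr, file.path(out, "load_ratio_correlations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(nrow(ratios), " diseases pass the >15-patient filter; ",
        nrow(corr), " pathways correlated")
message("top pathway: ", corr$pathway[1], " (r = ", signif(corr$r[1], 3),
        ", p = ", signif(corr$p[1], 3), ", Bonferroni ",
        signif(corr$p_bonferroni[1], 3), ")",
        if (corr$pathway[1] == planted) " -- the planted pathway" else "")
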