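#!/usr/bin/env Rscript
# Stage 5: qPCR relative quantification.
#
# 2^-ddCT fold changes for the four Janus-kinase targets against the Hprt +
# Actb housekeeping pair, calibrated to the PBS control group, with
# equal-variance t-tests on the ddCT scale. Planted folds: Jak1 = Jak2 =
# Tyk2 = 2, Jak3 = 1.

suppressPackageStartupMessages(library(pathcomorbid))
plate <- read_qpcr_csv("results/data/qpcr_plate.csv")
res <- qpcr_analysis(plate, c("Jak1", "Jak2", "Jak3", "Tyk2"),
                     housekeeping = c("Hprt", "Actb"),
                     control_group = "PBS")
write.table(res, "results/qpcr_results.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(res)))
  message(sprintf("%s: fold %.2f +/- %.2f (t-test p = %.3g)%s",
                  res$gene[i], res$mean_fold[i], res$sem[i], res$p[i],
                  if (res$p[i] < 0.05) " *" else ""))
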