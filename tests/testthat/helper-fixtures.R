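# Independent Mann-Whitney oracle. The U statistic is computed directly from
# the data values (pairwise comparisons, ties counted half), never from
# ranks, and the one-sided p-value by exhaustive reassignment of the pooled
# sample to the two groups.
mw_u_oracle <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

rank_sum_p_oracle <- function(x, y) {
  pool <- c(x, y)
  n <- length(x)
  obs <- mw_u_oracle(x, y)
  cmb <- utils::combn(length(pool), n)
  hits <- apply(cmb, 2, function(ix) {
    mw_u_oracle(pool[ix], pool[-ix]) >= obs - 1e-9
  })
  mean(hits)
}

# hand-rolled annotation/catalog fixtures -----------------------------------

toy_annotation <- function() {
  pathway_annotation(list(
    P1 = c("g1", "g2", "g3"),
    P2 = c("g2", "g3", "g4"),
    P3 = c("g4", "g5"),
    P4 = c("g1", "g5", "g6")))
}

toy_catalog <- function(diseases) {
  # diseases: named list disease -> gene vector; p-values increasing in order
  out <- do.call(rbind, lapply(names(diseases), function(d) {
    g <- diseases[[d]]
    data.frame(disease = d, gene = g,
               p_value = seq_along(g) * 1e-6,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

retained <- function(catalog, top_k = 25L, min_genes = 1L) {
  retain_catalog(catalog, top_k = top_k, min_genes = min_genes)
}

# small deterministic cohort builder ----------------------------------------

toy_cohort <- function(age, sex, race = "white", survey_year = 2003, dx) {
  n <- length(age)
  out <- data.frame(patient_id = sprintf("PT%03d", seq_len(n)),
                    age = age,
                    sex = rep_len(sex, n),
                    race = rep_len(race, n),
                    survey_year = rep_len(survey_year, n),
                    stringsAsFactors = FALSE)
  out$dx <- dx
  class(out) <- c("discharge_cohort", "data.frame")
  out
}

# noiseless qPCR plate from per-sample dCT shifts ---------------------------

toy_plate <- function(target_dct, groups, target = "Jak1",
                      housekeeping = c("Hprt", "Actb"), replicates = 3) {
  n <- length(target_dct)
  samples <- sprintf("R%02d", seq_len(n))
  rows <- list()
  for (i in seq_len(n)) {
    for (g in c(target, housekeeping)) {
      base <- if (g == target) 25 + target_dct[i] else 25
      for (r in seq_len(replicates)) {
        rows[[length(rows) + 1]] <- data.frame(
          sample = samples[i], group = groups[i], gene = g,
          replicate = r, ct = base, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("qpcr_plate", "data.frame")
  out
}
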