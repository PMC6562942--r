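test_that("exact binomial enrichment test agrees with an independent tail oracle", {
  set.seed(2)
  for (r in 1:40) {
    n <- sample(500, 1)
    k <- sample.int(n, 1)
    p0 <- runif(1, 0.01, 0.5)
    expect_equal(pathway_binomial_test(k, n, p0),
                 stats::pbinom(k - 1, n, p0, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_equal(pathway_binomial_test(0, 47), 1)
  expect_equal(pathway_binomial_test(47, 47), 0.05^47)
})

test_that("per-gene logistic model flags degenerate genes and detects planted shifts", {
  set.seed(8)
  n <- 100
  samples <- data.frame(sample = sprintf("S%03d", 1:(2 * n)),
                        diagnosis = rep(c("AD", "control"), each = n),
                        age = round(rnorm(2 * n, 75, 6)),
                        sex = sample(c("F", "M"), 2 * n, TRUE),
                        centre = sample(c("C1", "C2"), 2 * n, TRUE),
                        stringsAsFactors = FALSE)
  y <- as.integer(samples$diagnosis == "AD")
  expr <- rbind(flat = rep(3, 2 * n),                 # zero variance
                shifted = rnorm(2 * n) + 1.2 * y,     # strong case shift
                null = rnorm(2 * n))
  colnames(expr) <- samples$sample
  study <- expression_study(expr, samples)
  res <- per_gene_glm(study)
  expect_equal(res$flag[res$gene == "flat"], "zero_variance")
  expect_true(is.na(res$p[res$gene == "flat"]))
  expect_lt(res$p[res$gene == "shifted"], 1e-4)
  expect_gt(res$p[res$gene == "null"], 0.01)
})

test_that("covariate adjustment absorbs age-driven expression differences", {
  set.seed(15)
  n <- 120
  # cases are systematically older and expression tracks age only
  age <- c(round(rnorm(n, 80, 4)), round(rnorm(n, 70, 4)))
  samples <- data.frame(sample = sprintf("S%03d", 1:(2 * n)),
                        diagnosis = rep(c("AD", "control"), each = n),
                        age = age, sex = "F", centre = "C1",
                        stringsAsFactors = FALSE)
  expr <- matrix(0.1 * age + rnorm(2 * n, 0, 0.2), 1,
                 dimnames = list("agegene", samples$sample))
  study <- expression_study(expr, samples)
  # unadjusted, the gene separates the groups decisively
  expect_lt(t.test(expr[1, 1:n], expr[1, (n + 1):(2 * n)])$p.value, 1e-10)
  # the model's expression term, adjusted for age, shows no effect
  expect_gt(per_gene_glm(study)$p[1], 0.05)
})

test_that("per-gene p-values are approximately uniform under the global null", {
  cfg <- sim_config(n_genes = 200, n_pathways = 50, n_samples_per_group = 200,
                    seed = 31)
  sim <- simulate_catalog_and_pathways(cfg)
  study <- simulate_expression_study(cfg, sim$annotation)
  res <- per_gene_glm(study)
  p <- res$p[!is.na(res$p)]
  expect_gt(length(p), 190)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("significance rules match hand-computed Bonferroni and BH oracles", {
  res <- data.frame(gene = sprintf("g%d", 1:5),
                    estimate = 0, se = 1,
                    p = c(0.001, 0.01, 0.02, 0.04, NA),
                    flag = c("", "", "", "", "zero_variance"))
  # Bonferroni over the 4 tested genes
  bon <- significance_rule(res, "bonferroni")
  expect_equal(unname(bon$p_adj[1:4]), c(0.004, 0.04, 0.08, 0.16))
  expect_identical(bon$genes, c("g1", "g2"))
  expect_equal(bon$n, 4)
  # BH step-up by hand: p * n / rank, cumulative minimum from the largest
  p <- c(0.001, 0.01, 0.02, 0.04)
  bh_hand <- rev(cummin(rev(p * 4 / seq_len(4))))
  bh <- significance_rule(res, "bh_fdr")
  expect_equal(unname(bh$p_adj[1:4]), bh_hand)
  # 47 genes, one raw p of 0.001: Bonferroni-adjusted 0.047, significant
  res47 <- data.frame(gene = sprintf("g%d", 1:47), estimate = 0, se = 1,
                      p = c(0.001, rep(0.5, 46)), flag = "")
  bon47 <- significance_rule(res47, "bonferroni")
  expect_equal(unname(bon47$p_adj[1]), 0.047)
  expect_identical(bon47$genes, "g1")
  # all p = 1: empty set under any rule
  res1 <- data.frame(gene = "g", estimate = 0, se = 1, p = 1, flag = "")
  expect_length(significance_rule(res1, "raw")$genes, 0)
})

test_that("cross-dataset concordance is 1 for monotone transforms and recovers shared signal", {
  a <- data.frame(gene = sprintf("g%d", 1:20), estimate = 0, se = 1,
                  p = seq(0.001, 0.9, length.out = 20), flag = "")
  b <- a
  b$p <- a$p^2  # monotone transform
  cc <- cross_dataset_concordance(a, b)
  expect_equal(cc$rho, 1)
  expect_equal(cc$n, 20)

  # two studies sharing a planted pathway correlate positively
  base <- sim_config(n_genes = 150, n_pathways = 30,
                     pathway_size_range = c(40, 40),
                     n_samples_per_group = 60,
                     dysregulated_pathway = "P001", effect_size = 1.2)
  sim <- simulate_catalog_and_pathways(base)
  # mix of truly dysregulated and null genes: the shared signal is which
  # genes carry the effect, visible to a rank correlation of p-values
  genes <- c(sim$annotation$sets[["P001"]][1:20],
             setdiff(rownames(simulate_expression_study(base, sim$annotation)$expr),
                     sim$annotation$sets[["P001"]])[1:20])
  mk <- function(s) {
    cfg <- base; cfg$seed <- s
    simulate_expression_study(cfg, sim$annotation)
  }
  ra <- per_gene_glm(mk(101), genes = genes)
  rb <- per_gene_glm(mk(202), genes = genes)
  cc2 <- cross_dataset_concordance(ra, rb)
  expect_gt(cc2$rho, 0.3)
  expect_lt(cc2$p, 0.01)
})

test_that("merging studies concatenates samples on the gene intersection with study-labelled centres", {
  cfg <- sim_config(n_genes = 50, n_pathways = 10, n_samples_per_group = 20,
                    seed = 12)
  sim <- simulate_catalog_and_pathways(cfg)
  s1 <- simulate_expression_study(cfg, sim$annotation)
  merged <- merge_studies(list(blood1 = s1, blood2 = s1))
  expect_equal(ncol(merged$expr), 2 * ncol(s1$expr))
  expect_equal(unname(table(merged$samples$diagnosis)["AD"]),
               2 * sum(s1$samples$diagnosis == "AD"))
  expect_true(all(grepl("^(blood1|blood2)\\.", merged$samples$centre)))

  # partial gene overlap: merged gene set is the intersection
  s2 <- s1
  s2$expr <- s1$expr[1:30, , drop = FALSE]
  merged2 <- merge_studies(list(a = s1, b = s2))
  expect_identical(rownames(merged2$expr), rownames(s1$expr)[1:30])
  # the merged per-gene model still runs and stays calibrated on null data
  res <- per_gene_glm(merged2, genes = rownames(merged2$expr)[1:10])
  expect_true(all(res$p[!is.na(res$p)] > 1e-4))
})

test_that("pathway enrichment pipeline ties the model, rule and binomial test together", {
  cfg <- sim_config(n_genes = 120, n_pathways = 20,
                    pathway_size_range = c(40, 45), n_samples_per_group = 80,
                    dysregulated_pathway = "P005", effect_size = 1, seed = 44)
  sim <- simulate_catalog_and_pathways(cfg)
  study <- simulate_expression_study(cfg, sim$annotation)
  enr <- pathway_enrichment(study, sim$annotation, "P005")
  expect_equal(enr$n_measured,
               length(intersect(sim$annotation$sets[["P005"]],
                                rownames(study$expr))))
  expect_lt(enr$p_binomial, 0.05)
  expect_equal(enr$p_binomial,
               pathway_binomial_test(enr$k, enr$n_measured, 0.05))
})
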