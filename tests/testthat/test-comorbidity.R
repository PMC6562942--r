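test_that("pathway load counts membership incidences and sums to one per disease", {
  ann <- toy_annotation()
  # disease A: g1 only annotated to {P1,P4}; g6 only to {P4}
  loads <- pathway_load(retained(toy_catalog(list(A = c("g1", "g6")))), ann)
  # incidences: P1 x1, P4 x2 -> loads 1/3 and 2/3
  expect_equal(loads$load[loads$pathway == "P4"], 2 / 3)
  expect_equal(loads$load[loads$pathway == "P1"], 1 / 3)

  # a disease whose genes annotate a single pathway has load 1 there
  single <- pathway_annotation(list(P = c("x1", "x2")))
  l1 <- pathway_load(retained(toy_catalog(list(B = c("x1", "x2")))), single)
  expect_equal(l1$load, 1)

  # conservation on a random instance, against a brute-force incidence count
  set.seed(1)
  cfg <- sim_config(n_genes = 150, n_pathways = 50, n_diseases = 6,
                    genes_per_disease = 20, seed = 3)
  sim <- simulate_catalog_and_pathways(cfg)
  cat <- retained(sim$catalog, top_k = 20, min_genes = 20)
  loads <- pathway_load(cat, sim$annotation)
  sums <- tapply(loads$load, loads$disease, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)))
  for (i in sample(nrow(loads), 10)) {
    d <- loads$disease[i]; p <- loads$pathway[i]
    genes <- cat$gene[cat$disease == d]
    expect_equal(loads$m[i], sum(genes %in% sim$annotation$sets[[p]]))
  }
})

test_that("diseases with no annotated gene are excluded with a warning", {
  ann <- pathway_annotation(list(P = "x1"))
  cat <- retained(toy_catalog(list(A = "x1", B = "zz")))
  expect_warning(loads <- pathway_load(cat, ann), "excluded")
  expect_false("B" %in% loads$disease)
})

test_that("AD case selection uses the exact code and a strict age cutoff", {
  coh <- toy_cohort(age = c(60, 61, 75, 80), sex = "F",
                    dx = list("331.0", "331.0", c("250", "331.0"), "428"))
  cases <- select_ad_cases(coh)
  # age 60 exactly is excluded; 331.0 among several codes is included;
  # no AD code is excluded
  expect_identical(cases$patient_id, c("PT002", "PT003"))

  # brute-force filter oracle on a simulated cohort
  cfg <- sim_config(n_patients = 5000, seed = 4)
  coh2 <- simulate_discharge_cohort(cfg)
  brute <- sum(mapply(function(a, d) a > 60 && "331.0" %in% d,
                      coh2$age, coh2$dx))
  expect_equal(nrow(select_ad_cases(coh2)), brute)
})

test_that("matching is exact, without replacement, and preserves the key multiset", {
  # every case has an exact twin: nothing dropped
  coh <- toy_cohort(age = c(70, 70, 80, 80), sex = c("F", "F", "M", "M"),
                    dx = list("331.0", "250", "331.0", "401"))
  cases <- select_ad_cases(coh)
  mc <- match_controls(cases, coh, seed = 1)
  expect_length(mc$dropped, 0)
  expect_identical(mc$controls$patient_id, c("PT002", "PT004"))

  # two cases compete for one control: exactly one matched, deterministically
  coh2 <- toy_cohort(age = c(70, 70, 70), sex = "F",
                     dx = list("331.0", "331.0", "250"))
  cases2 <- select_ad_cases(coh2)
  mc2 <- match_controls(cases2, coh2, seed = 1)
  expect_equal(nrow(mc2$cases), 1)
  expect_length(mc2$dropped, 1)
  expect_identical(mc2, match_controls(cases2, coh2, seed = 1))

  # key multiset equality on a full-scale simulated cohort
  cfg <- sim_config(n_patients = 20000, seed = 6)
  coh3 <- simulate_discharge_cohort(cfg)
  mc3 <- match_controls(select_ad_cases(coh3), coh3, seed = 6)
  key <- function(d) sort(paste(d$sex, d$age, d$race, d$survey_year))
  expect_identical(key(mc3$cases), key(mc3$controls))
  # controls never carry the AD code
  expect_false(any(vapply(mc3$controls$dx, function(d) "331.0" %in% d,
                          logical(1))))
})

test_that("comorbidity ratios apply the strict power filter and prefix code matching", {
  cases <- toy_cohort(age = rep(75, 28), sex = "F",
                      dx = c(rep(list(c("331.0", "250.1")), 20),
                             rep(list("331.0"), 8)))
  ctls <- toy_cohort(age = rep(75, 28), sex = "F",
                     dx = c(rep(list("250.0"), 10), rep(list("401")),
                            rep(list("780.9"), 17)))
  mc <- structure(list(cases = cases, controls = ctls, dropped = character(0),
                       keys = "age"), class = "matched_cohort")
  # disease 250: 20 cases (prefix match on 250.1) vs 10 controls (250.0)
  r <- comorbidity_ratios(mc, c("250", "401"))
  expect_equal(r$ratio[r$disease == "250"], 2.0)
  expect_equal(r$n_total[r$disease == "250"], 30)
  # disease 401: 0 + 1 = 1 patient, excluded by the > 15 filter
  expect_false("401" %in% r$disease)

  # boundary: total of exactly 15 is excluded (strictly greater required)
  cases2 <- toy_cohort(age = rep(75, 8), sex = "F",
                       dx = rep(list(c("331.0", "X1")), 8))
  ctls2 <- toy_cohort(age = rep(75, 8), sex = "F",
                      dx = c(rep(list("X1"), 7), list("780.9")))
  mc2 <- structure(list(cases = cases2, controls = ctls2,
                        dropped = character(0), keys = "age"),
                   class = "matched_cohort")
  expect_equal(nrow(comorbidity_ratios(mc2, "X1")), 0)
})

test_that("ratios are invariant to duplicating the whole cohort", {
  coh <- toy_cohort(age = rep(c(70, 70, 80, 80), 10),
                    sex = "F",
                    dx = rep(list(c("331.0", "250"), "250", "331.0", "780.9"),
                             10))
  dup <- coh[rep(seq_len(nrow(coh)), 2), ]
  dup$patient_id <- sprintf("PT%03d", seq_len(nrow(dup)))
  class(dup) <- class(coh)
  r1 <- comorbidity_ratios(match_controls(select_ad_cases(coh), coh, seed = 2),
                           "250", min_patients = 5)
  r2 <- comorbidity_ratios(match_controls(select_ad_cases(dup), dup, seed = 2),
                           "250", min_patients = 5)
  expect_equal(r2$ratio, r1$ratio)
  expect_equal(r2$n_total, 2 * r1$n_total)
})

test_that("load-ratio correlation finds exact linear relationships and skips constant loads", {
  loads <- data.frame(disease = rep(c("A", "B", "C", "D"), each = 2),
                      pathway = rep(c("P1", "P2"), 4),
                      m = 1L,
                      load = c(0.1, 0.9, 0.2, 0.8, 0.3, 0.7, 0.4, 0.6))
  class(loads) <- c("pathway_load", "data.frame")
  ratios <- data.frame(disease = c("A", "B", "C", "D"),
                       n_cases = 1, n_controls = 1, n_total = 2,
                       ratio = c(1.1, 1.9, 2.3, 3.4))
  res <- correlate_load_vs_ratio(loads, ratios)
  # loads on P1 increase linearly-ish with ratio; P2 is its mirror image
  expect_equal(abs(res$r), rep(cor(c(.1, .2, .3, .4), ratios$ratio), 2))
  expect_equal(res$p_bonferroni, pmin(1, res$p * 2))

  # exactly proportional loads give r = 1
  loads2 <- loads[loads$pathway == "P1", ]
  loads2$load <- ratios$ratio / 10
  class(loads2) <- c("pathway_load", "data.frame")
  expect_equal(correlate_load_vs_ratio(loads2, ratios,
                                       pathways = "P1")$r, 1)

  # constant load vector: skipped with a warning
  loads3 <- loads
  loads3$load[loads3$pathway == "P2"] <- 0.5
  expect_warning(res3 <- correlate_load_vs_ratio(loads3, ratios),
                 "constant load")
  expect_false("P2" %in% res3$pathway)
})

test_that("correlation p-values are roughly uniform under label permutation", {
  cfg <- sim_config(seed = 21)
  sim <- simulate_catalog_and_pathways(cfg)
  cat <- retained(sim$catalog)
  loads <- pathway_load(cat, sim$annotation)
  coh <- simulate_discharge_cohort(cfg)
  mc <- match_controls(select_ad_cases(coh), coh, seed = 21)
  ratios <- comorbidity_ratios(mc, sprintf("D%02d", 1:20))
  set.seed(99)
  ps <- replicate(40, {
    perm <- ratios
    perm$ratio <- sample(perm$ratio)
    suppressWarnings(correlate_load_vs_ratio(loads, perm,
                                             pathways = "P001"))$p
  })
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
  expect_lte(mean(ps < 0.05), 0.2)
})

test_that("plant_comorbidity_effects maps loads linearly onto relative risks", {
  loads <- data.frame(disease = c("A", "B", "C"), pathway = "P1",
                      m = 1L, load = c(0, 0.5, 1))
  class(loads) <- c("pathway_load", "data.frame")
  rr <- plant_comorbidity_effects(loads, "P1", max_rr = 3)
  expect_equal(unname(rr), c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(attr(rr, "pathway"), "P1")
})
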