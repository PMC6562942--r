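#' Run the full pathway-comorbidity pipeline on synthetic data
#'
#' Executes the end-to-end sequence -- simulate inputs, disease-pair overlap
#' scan, pathway loads, case-control matching and comorbidity ratios,
#' load-ratio correlation, pathway expression dysregulation, qPCR
#' quantification -- and collects a single reproducible run report. Every
#' stage derives its randomness from `config$seed`, so two runs with the
#' same configuration produce identical reports; when `out_dir` is given,
#' each intermediate table is also written there with a provenance header.
#'
#' @param config A [sim_config()]. For a planted run, set
#'   `planted_disease_pairs`, `comorbidity_effects`,
#'   `dysregulated_pathway` / `effect_size` as desired.
#' @param out_dir Optional directory for intermediate files.
#' @param stages Character vector choosing stages among
#'   `c("overlap", "comorbidity", "expression", "qpcr")`; simulation always
#'   runs for the stages that need it.
#' @param top_k,min_genes Catalog retention thresholds.
#' @param alpha Significance level used throughout.
#' @param correction Pair-level correction, see [all_pairs_overlap()].
#' @param min_patients Comorbidity power filter.
#' @param p0 Null proportion of the pathway binomial test.
#' @param enrichment_pathway Pathway tested for expression dysregulation
#'   (default: `config$dysregulated_pathway`, else the first pathway).
#' @param qpcr_folds Named fold changes for the simulated qPCR plate.
#' @return List of class `pipeline_report` with per-stage summaries.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         stages = c("overlap", "comorbidity", "expression",
                                    "qpcr"),
                         top_k = 25L, min_genes = 25L, alpha = 0.05,
                         correction = "bonferroni", min_patients = 15,
                         p0 = 0.05, enrichment_pathway = NULL,
                         qpcr_folds = c(Jak1 = 2, Jak2 = 2, Jak3 = 1,
                                        Tyk2 = 2)) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  save <- function(writer, obj, name, ...) {
    if (!is.null(out_dir))
      writer(obj, file.path(out_dir, name), seed = config$seed,
             config = config, ...)
  }
  report <- list(seed = config$seed, config_hash = config_hash(config),
                 version = pkg_version(), stages = stages)

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sim <- run_stage("simulate", function()
    simulate_catalog_and_pathways(config))
  catalog <- retain_catalog(sim$catalog, top_k, min_genes)
  save(write_catalog_tsv, sim$catalog, "catalog.tsv")
  if (!is.null(out_dir))
    write_gmt(sim$annotation, file.path(out_dir, "pathways.gmt"))
  report$simulate <- list(n_diseases = length(unique(catalog$disease)),
                          n_genes = length(unique(catalog$gene)),
                          n_pathways = length(sim$annotation$sets))

  if ("overlap" %in% stages) {
    mat <- run_stage("overlap", function()
      build_shared_matrix(catalog, sim$annotation))
    scan <- run_stage("overlap", function()
      all_pairs_overlap(catalog, mat, alpha = alpha, correction = correction))
    save(write_with_header, scan$results, "overlap_pairs.tsv", sep = "\t")
    top <- scan$results[1, ]
    report$overlap <- list(
      n_pairs = scan$n_pairs,
      n_significant = sum(scan$results$significant),
      top_pair = paste(top$disease_a, top$disease_b, sep = "~"),
      top_p = top$p, top_p_adj = top$p_adj)
  }

  loads <- NULL
  if (any(c("comorbidity", "expression") %in% stages))
    loads <- run_stage("loads", function()
      pathway_load(catalog, sim$annotation))

  if ("comorbidity" %in% stages) {
    cohort <- run_stage("comorbidity", function()
      simulate_discharge_cohort(config))
    save(write_cohort_csv, cohort, "cohort.csv")
    cases <- select_ad_cases(cohort)
    matched <- run_stage("comorbidity", function()
      match_controls(cases, cohort, seed = config$seed))
    codes <- sprintf("D%02d", seq_len(config$n_diseases))
    ratios <- run_stage("comorbidity", function()
      comorbidity_ratios(matched, codes, min_patients = min_patients))
    corr <- run_stage("comorbidity", function()
      correlate_load_vs_ratio(loads, ratios))
    save(write_with_header, loads, "pathway_loads.tsv", sep = "\t")
    save(write_with_header, ratios, "comorbidity_ratios.tsv", sep = "\t")
    save(write_with_header, corr, "load_ratio_correlations.tsv", sep = "\t")
    report$comorbidity <- list(
      n_cases = nrow(cases), n_matched = nrow(matched$cases),
      n_dropped = length(matched$dropped),
      n_diseases_powered = nrow(ratios),
      top_pathway = corr$pathway[1], top_r = corr$r[1], top_p = corr$p[1],
      top_p_bonferroni = corr$p_bonferroni[1])
  }

  if ("expression" %in% stages) {
    study <- run_stage("expression", function()
      simulate_expression_study(config, sim$annotation))
    save(function(obj, path, ...) write_expression_tsv(
      obj, path, sub("\\.tsv$", "_samples.tsv", path), ...),
      study, "expression.tsv")
    pw <- enrichment_pathway %||% config$dysregulated_pathway %||%
      names(sim$annotation$sets)[1]
    enr <- run_stage("expression", function()
      pathway_enrichment(study, sim$annotation, pw, alpha = alpha, p0 = p0))
    report$expression <- list(pathway = pw, n_measured = enr$n_measured,
                              k_significant = enr$k,
                              p_binomial = enr$p_binomial)
  }

  if ("qpcr" %in% stages) {
    plate <- run_stage("qpcr", function()
      simulate_qpcr_plate(qpcr_folds, seed = config$seed))
    save(write_qpcr_csv, plate, "qpcr_plate.csv")
    qres <- run_stage("qpcr", function()
      qpcr_analysis(plate, names(qpcr_folds), c("Hprt", "Actb")))
    save(write_with_header, qres, "qpcr_results.tsv", sep = "\t")
    report$qpcr <- list(
      genes = qres$gene,
      mean_fold = stats::setNames(qres$mean_fold, qres$gene),
      p = stats::setNames(qres$p, qres$gene))
  }

  class(report) <- "pipeline_report"
  if (!is.null(out_dir))
    writeLines(format_report(report), file.path(out_dir, "report.json"))
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a pipeline report as JSON text
#'
#' Deterministic (no timestamps), so identical runs give byte-identical
#' reports.
#'
#' @param report A `pipeline_report`.
#' @return A JSON character scalar.
#' @export
format_report <- function(report) {
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                   pretty = TRUE)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(format_report(x), "\n")
  invisible(x)
}
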