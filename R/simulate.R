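#' Simulate a disease-gene catalog and pathway annotation
#'
#' Generates the two genetic inputs of the pipeline with known planted
#' structure. Pathway sizes are drawn uniformly from
#' `config$pathway_size_range` and members sampled uniformly from the gene
#' universe, giving an average of about
#' `n_pathways * mean(size) / n_genes` pathway memberships per gene
#' (about 3 at the defaults). Each disease receives exactly
#' `genes_per_disease` distinct genes with strictly increasing synthetic
#' association p-values. For every planted pair `(a, b, k)`, `k` genes from
#' each of the two diseases are added to a common set of
#' `n_planted_pathways` carrier pathways, so that cross-disease gene pairs
#' share those pathways; all other disease pairs draw genes whose pathway
#' memberships are independent.
#'
#' @param config A [sim_config()].
#' @return List with elements `catalog` (data.frame `disease`, `gene`,
#'   `p_value`, sorted by p within disease) and `annotation`
#'   (a [pathway_annotation()]).
#' @export
simulate_catalog_and_pathways <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(split_seed(config$seed, 1L))
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  path_ids <- sprintf("P%03d", seq_len(config$n_pathways))
  size_range <- seq(config$pathway_size_range[1], config$pathway_size_range[2])
  # index into the range: sample() would misread a length-1 range as 1:n
  sizes <- size_range[sample.int(length(size_range), config$n_pathways,
                                 replace = TRUE)]
  sets <- lapply(sizes, function(s) sample(genes, s))
  names(sets) <- path_ids

  diseases <- sprintf("D%02d", seq_len(config$n_diseases))
  disease_genes <- lapply(diseases, function(d)
    sample(genes, config$genes_per_disease))
  names(disease_genes) <- diseases

  if (length(config$planted_disease_pairs) > 0) {
    carriers <- utils::tail(path_ids, config$n_planted_pathways)
    for (pp in config$planted_disease_pairs) {
      a <- as.character(pp[[1]]); b <- as.character(pp[[2]])
      k <- as.integer(pp[[3]])
      if (!a %in% diseases || !b %in% diseases)
        stop("planted pair refers to unknown disease: ", a, "/", b)
      if (k > config$genes_per_disease)
        stop("planted pair requests more shared genes (", k,
             ") than genes_per_disease (", config$genes_per_disease, ")")
      linked <- c(sample(disease_genes[[a]], k), sample(disease_genes[[b]], k))
      for (cp in carriers) sets[[cp]] <- unique(c(sets[[cp]], linked))
    }
  }

  catalog <- do.call(rbind, lapply(diseases, function(d) {
    data.frame(disease = d,
               gene = disease_genes[[d]],
               p_value = sort(stats::runif(config$genes_per_disease,
                                           1e-12, 1e-5)),
               stringsAsFactors = FALSE)
  }))
  rownames(catalog) <- NULL
  list(catalog = catalog, annotation = pathway_annotation(sets))
}

#' Simulate a hospital-discharge cohort with ICD-9-CM-style codes
#'
#' Emulates the statistical structure of discharge records used for the
#' comorbidity analysis: demographics (age with most mass above 60, sex,
#' race, survey year), an Alzheimer's disease code ("331.0") assigned with
#' probability `ad_prevalence` to patients older than 60, and one synthetic
#' code per catalog disease assigned with baseline probability
#' `disease_prevalence` -- multiplied, for AD patients over 60, by the
#' disease's relative risk from `config$comorbidity_effects`. Patients with
#' no drawn diagnosis receive the filler code "780.9" so every record has a
#' non-empty code list.
#'
#' @param config A [sim_config()].
#' @return A data.frame of class `discharge_cohort` with columns
#'   `patient_id`, `age`, `sex`, `race`, `survey_year` and a list-column
#'   `dx` of diagnosis codes.
#' @export
simulate_discharge_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(split_seed(config$seed, 2L))
  n <- config$n_patients
  age <- sample(20:99, n, replace = TRUE, prob = c(rep(1, 40), rep(2, 40)))
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.55, 0.45))
  race <- sample(c("white", "black", "other"), n, replace = TRUE,
                 prob = c(0.60, 0.25, 0.15))
  survey_year <- sample(2000:2006, n, replace = TRUE)

  eligible <- age > 60
  if (sum(eligible) * config$ad_prevalence < 1)
    warning("cohort too small to expect any AD case at the configured prevalence")
  ad <- eligible & stats::runif(n) < config$ad_prevalence

  codes <- sprintf("D%02d", seq_len(config$n_diseases))
  rr <- stats::setNames(rep(1, config$n_diseases), codes)
  if (!is.null(config$comorbidity_effects)) {
    unknown <- setdiff(names(config$comorbidity_effects), codes)
    if (length(unknown))
      stop("comorbidity_effects names not in the synthetic code list: ",
           paste(unknown, collapse = ", "))
    rr[names(config$comorbidity_effects)] <- config$comorbidity_effects
  }
  # n x n_diseases Bernoulli draws; relative risk applies to AD cases > 60
  p <- outer(rep(config$disease_prevalence, n), rep(1, config$n_diseases))
  p[ad, ] <- sweep(p[ad, , drop = FALSE], 2, rr, "*")
  hits <- matrix(stats::runif(n * config$n_diseases), n) < p

  w <- which(hits, arr.ind = TRUE)
  dx <- vector("list", n)
  if (nrow(w)) {
    by_patient <- split(codes[w[, 2]], w[, 1])
    dx[as.integer(names(by_patient))] <- by_patient
  }
  dx[ad] <- lapply(dx[ad], function(d) c("331.0", d))
  empty <- vapply(dx, is.null, logical(1))
  dx[empty] <- list("780.9")

  out <- data.frame(patient_id = sprintf("PT%06d", seq_len(n)),
                    age = age, sex = sex, race = race,
                    survey_year = survey_year, stringsAsFactors = FALSE)
  out$dx <- dx
  class(out) <- c("discharge_cohort", "data.frame")
  out
}

#' Simulate an expression study with a dysregulated pathway
#'
#' Generates a genes x samples log-scale expression matrix with Gaussian
#' per-gene noise, per-sample covariates (age, sex, centre) independent of
#' diagnosis, and, if `config$dysregulated_pathway` is set, a mean shift of
#' `effect_size * noise_sd` in AD samples (half that shift in MCI samples,
#' mimicking an intermediate phenotype) for every universe gene annotated
#' to that pathway.
#'
#' @param config A [sim_config()].
#' @param annotation A [pathway_annotation()], used to resolve the
#'   dysregulated pathway's genes.
#' @param groups Diagnostic groups to simulate (subset of
#'   `c("AD", "MCI", "control")`).
#' @return An [expression_study()].
#' @export
simulate_expression_study <- function(config, annotation,
                                      groups = c("AD", "control")) {
  stopifnot(inherits(config, "sim_config"),
            inherits(annotation, "pathway_annotation"))
  groups <- match.arg(groups, c("AD", "MCI", "control"), several.ok = TRUE)
  set.seed(split_seed(config$seed, 3L))
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  n <- config$n_samples_per_group
  ns <- n * length(groups)
  samples <- data.frame(
    sample = sprintf("S%04d", seq_len(ns)),
    diagnosis = rep(groups, each = n),
    age = pmin(95, pmax(55, round(stats::rnorm(ns, 75, 7)))),
    sex = sample(c("F", "M"), ns, replace = TRUE),
    centre = sample(c("C1", "C2"), ns, replace = TRUE),
    stringsAsFactors = FALSE)

  mu <- stats::rnorm(config$n_genes, 8, 2)
  expr <- mu + matrix(stats::rnorm(config$n_genes * ns, 0, config$noise_sd),
                      config$n_genes, ns)
  dimnames(expr) <- list(genes, samples$sample)

  dp <- config$dysregulated_pathway
  if (!is.null(dp) && config$effect_size > 0) {
    if (!dp %in% names(annotation$sets))
      stop("dysregulated_pathway not found in annotation: ", dp)
    target <- intersect(annotation$sets[[dp]], genes)
    shift <- config$effect_size * config$noise_sd
    expr[target, samples$diagnosis == "AD"] <-
      expr[target, samples$diagnosis == "AD"] + shift
    expr[target, samples$diagnosis == "MCI"] <-
      expr[target, samples$diagnosis == "MCI"] + shift / 2
  }
  expression_study(expr, samples)
}

#' Simulate a qPCR plate with known fold changes
#'
#' Builds crossing-threshold (CT) records for target and housekeeping genes
#' over a treated and a control sample group, with technical replicates.
#' Each sample carries a random RNA-input shift applied to all its genes
#' (which housekeeping normalisation removes), and treated samples have the
#' target CT lowered by `log2(fold)` so that the expected 2^-ddCT equals
#' the requested fold change. Housekeeping genes are unaffected by the
#' requested folds (their fold change is 1 by construction).
#'
#' @param fold_changes Named positive numeric vector (target gene -> fold).
#' @param n_replicates Technical replicates per sample and gene.
#' @param seed Integer seed.
#' @param n_samples_per_group Biological replicates per group.
#' @param housekeeping Housekeeping gene names.
#' @param noise_sd Per-replicate CT noise (cycles).
#' @param groups Named character vector `c(control = ..., treated = ...)`
#'   giving the group labels.
#' @return A data.frame of class `qpcr_plate` with columns `sample`,
#'   `group`, `gene`, `replicate`, `ct`.
#' @export
simulate_qpcr_plate <- function(fold_changes, n_replicates = 3L, seed = 1L,
                                n_samples_per_group = 5L,
                                housekeeping = c("Hprt", "Actb"),
                                noise_sd = 0.1,
                                groups = c(control = "PBS", treated = "Abeta")) {
  if (is.null(names(fold_changes)) || any(fold_changes <= 0))
    stop("fold_changes must be a named positive numeric vector")
  if (any(names(fold_changes) %in% housekeeping))
    stop("housekeeping genes cannot carry a planted fold change")
  set.seed(split_seed(seed, 4L))
  targets <- names(fold_changes)
  genes <- c(targets, housekeeping)
  base_ct <- stats::setNames(
    c(stats::runif(length(targets), 24, 27),
      stats::runif(length(housekeeping), 18, 20)), genes)

  ns <- 2L * n_samples_per_group
  samp <- data.frame(
    sample = sprintf("R%02d", seq_len(ns)),
    group = rep(unname(groups[c("control", "treated")]),
                each = n_samples_per_group),
    stringsAsFactors = FALSE)
  input_shift <- stats::setNames(stats::rnorm(ns, 0, 0.3), samp$sample)

  grid <- expand.grid(sample = samp$sample, gene = genes,
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$group <- samp$group[match(grid$sample, samp$sample)]
  treated <- grid$group == groups[["treated"]] & grid$gene %in% targets
  delta <- ifelse(treated, -log2(fold_changes[grid$gene]), 0)
  grid$ct <- base_ct[grid$gene] + input_shift[grid$sample] + delta +
    stats::rnorm(nrow(grid), 0, noise_sd)
  out <- grid[, c("sample", "group", "gene", "replicate", "ct")]
  rownames(out) <- NULL
  class(out) <- c("qpcr_plate", "data.frame")
  out
}
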