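#' Simulation configuration for the synthetic pipeline inputs
#'
#' Bundles every knob of the synthetic-data generator into a single validated
#' object. The defaults define the reference study conditions used throughout
#' the test-suite: a catalog of 20 diseases with 25 susceptibility genes each,
#' 200 pathways of 5--10 genes over a 500-gene universe (about 3 pathway
#' memberships per gene, a typical KEGG-like density), a 50,000-patient
#' discharge cohort, and expression studies of 100 samples per diagnostic
#' group.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_pathways Number of pathways.
#' @param pathway_size_range Integer vector `c(min, max)`: pathway sizes are
#'   drawn uniformly from this range.
#' @param n_diseases Number of diseases in the catalog.
#' @param genes_per_disease Susceptibility genes per disease (the catalog is
#'   generated already at the retained size).
#' @param planted_disease_pairs List of `list(a, b, n_shared)` entries. For
#'   each entry, `n_shared` genes of disease `a` and `n_shared` genes of
#'   disease `b` are added to a common set of "carrier" pathways, planting a
#'   pathway-space overlap between the two diseases.
#' @param n_planted_pathways Number of carrier pathways used for planting.
#' @param n_patients Discharge-cohort size.
#' @param ad_prevalence Probability of an Alzheimer's disease (code 331.0)
#'   diagnosis among patients older than 60.
#' @param disease_prevalence Baseline probability of each synthetic disease
#'   code per patient.
#' @param comorbidity_effects Named numeric vector mapping disease codes to a
#'   relative risk among AD cases aged over 60 (default: all 1).
#' @param n_samples_per_group Samples per diagnostic group in simulated
#'   expression studies.
#' @param dysregulated_pathway Pathway id whose genes are shifted in cases.
#' @param effect_size Standardised mean shift (in units of `noise_sd`)
#'   applied to genes of `dysregulated_pathway` in AD samples.
#' @param noise_sd Residual standard deviation of simulated expression.
#' @param seed Integer seed; all generator stages derive their own stream
#'   from it, so identical configurations give identical outputs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 500L,
                       n_pathways = 200L,
                       pathway_size_range = c(5L, 10L),
                       n_diseases = 20L,
                       genes_per_disease = 25L,
                       planted_disease_pairs = list(),
                       n_planted_pathways = 3L,
                       n_patients = 50000L,
                       ad_prevalence = 0.05,
                       disease_prevalence = 0.02,
                       comorbidity_effects = NULL,
                       n_samples_per_group = 100L,
                       dysregulated_pathway = NULL,
                       effect_size = 0,
                       noise_sd = 1,
                       seed = 1L) {
  counts <- c(n_genes = n_genes, n_pathways = n_pathways,
              n_diseases = n_diseases, genes_per_disease = genes_per_disease,
              n_patients = n_patients, n_samples_per_group = n_samples_per_group,
              n_planted_pathways = n_planted_pathways)
  if (any(counts < 1) || any(counts != floor(counts)))
    stop("all counts must be positive integers")
  if (length(pathway_size_range) != 2L ||
      pathway_size_range[1] > pathway_size_range[2] ||
      pathway_size_range[1] < 1)
    stop("pathway_size_range must be c(min, max) with 1 <= min <= max")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (ad_prevalence <= 0 || ad_prevalence > 1)
    stop("ad_prevalence must be in (0, 1]")
  if (disease_prevalence <= 0 || disease_prevalence > 1)
    stop("disease_prevalence must be in (0, 1]")
  for (pp in planted_disease_pairs) {
    if (length(pp) < 3L) stop("planted pairs must be list(a, b, n_shared)")
    if (pp[[3]] > genes_per_disease)
      stop("planted pair requests more shared genes (", pp[[3]],
           ") than genes_per_disease (", genes_per_disease, ")")
  }
  if (!is.null(comorbidity_effects)) {
    if (is.null(names(comorbidity_effects)) || any(comorbidity_effects < 0))
      stop("comorbidity_effects must be a named non-negative numeric vector")
    if (any(comorbidity_effects * disease_prevalence > 1))
      stop("relative risk times baseline prevalence exceeds 1")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    n_diseases = as.integer(n_diseases),
    genes_per_disease = as.integer(genes_per_disease),
    planted_disease_pairs = planted_disease_pairs,
    n_planted_pathways = as.integer(n_planted_pathways),
    n_patients = as.integer(n_patients),
    ad_prevalence = ad_prevalence,
    disease_prevalence = disease_prevalence,
    comorbidity_effects = comorbidity_effects,
    n_samples_per_group = as.integer(n_samples_per_group),
    dysregulated_pathway = dysregulated_pathway,
    effect_size = effect_size,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Derive a stage-specific sub-seed from a master seed
#'
#' Deterministic Lehmer-style split so each generator stage gets its own
#' reproducible stream and stages can be regenerated independently.
#'
#' @param seed Master integer seed.
#' @param stage Small integer identifying the stage.
#' @return An integer below 2^31 - 1.
#' @export
split_seed <- function(seed, stage) {
  as.integer((abs(as.numeric(seed)) * 48271 + 7907 * stage) %% 2147483647)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_diseases, "diseases x", x$genes_per_disease,
      "genes;", x$n_pathways, "pathways over", x$n_genes, "genes;",
      x$n_patients, "patients;", x$n_samples_per_group,
      "samples/group; seed", x$seed, "\n")
  invisible(x)
}

# short stable hash of an R object, used in output-file headers
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = " ")
  b <- utf8ToInt(s)
  h <- 0
  for (v in b) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}
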