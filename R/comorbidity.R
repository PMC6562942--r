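#' Per-disease pathway load
#'
#' For each disease A and pathway p, counts m(A, p) = number of A's retained
#' genes annotated to p and normalises by the disease's total number of
#' gene-pathway membership incidences (a gene belonging to three pathways
#' contributes three to the denominator). Loads therefore sum to one within
#' each disease, which controls for diseases whose genes are annotated more
#' densely. Diseases with no annotated gene are excluded with a warning.
#'
#' @param catalog Retained catalog (see [retain_catalog()]).
#' @param annotation A [pathway_annotation()].
#' @return data.frame of class `pathway_load` with columns `disease`,
#'   `pathway`, `m`, `load` (only nonzero rows).
#' @export
pathway_load <- function(catalog, annotation) {
  if (is.null(attr(catalog, "retained"))) catalog <- retain_catalog(catalog)
  parts <- split(catalog$gene, catalog$disease)
  rows <- lapply(names(parts), function(d) {
    paths <- unlist(lapply(parts[[d]], gene_pathways, annotation = annotation),
                    use.names = FALSE)
    if (length(paths) == 0) return(NULL)
    tab <- table(paths)
    data.frame(disease = d, pathway = names(tab),
               m = as.integer(tab), load = as.integer(tab) / sum(tab),
               stringsAsFactors = FALSE)
  })
  dropped <- names(parts)[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    warning("diseases with no pathway-annotated gene excluded: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no disease has any pathway-annotated gene")
  rownames(out) <- NULL
  class(out) <- c("pathway_load", "data.frame")
  out
}

#' Spread a pathway-load table into a diseases x pathways matrix
#'
#' Missing (disease, pathway) combinations get load 0.
#'
#' @param loads Output of [pathway_load()].
#' @param pathways Column universe (default: pathways present in `loads`).
#' @return Numeric matrix, rows diseases, columns pathways.
#' @export
load_matrix <- function(loads, pathways = sort(unique(loads$pathway))) {
  diseases <- sort(unique(loads$disease))
  W <- matrix(0, length(diseases), length(pathways),
              dimnames = list(diseases, pathways))
  keep <- loads$pathway %in% pathways
  W[cbind(loads$disease[keep], loads$pathway[keep])] <- loads$load[keep]
  W
}

# does any code of each record match `code` (prefix or exact)?
has_code <- function(dx, code, prefix = TRUE) {
  if (prefix)
    vapply(dx, function(d) any(startsWith(d, code)), logical(1))
  else
    vapply(dx, function(d) code %in% d, logical(1))
}

#' Select Alzheimer's disease cases from a discharge cohort
#'
#' Cases are patients carrying the AD diagnosis code (exact match) and aged
#' strictly above `min_age` years, focusing the analysis on late-onset AD.
#'
#' @param cohort A `discharge_cohort` data.frame (list-column `dx`).
#' @param ad_code Diagnosis code defining AD; default ICD-9-CM "331.0".
#' @param min_age Strict lower age bound in years.
#' @return The case subset of `cohort`.
#' @export
select_ad_cases <- function(cohort, ad_code = "331.0", min_age = 60) {
  keep <- cohort$age > min_age & has_code(cohort$dx, ad_code, prefix = FALSE)
  cohort[keep, , drop = FALSE]
}

#' Match one control per case on exact demographic keys
#'
#' Performs 1:1 exact matching without replacement on the given keys.
#' Controls are all cohort members without the AD code. Cases are processed
#' in a seed-shuffled order and each receives a uniformly random eligible
#' unused control; cases with no exact match left are dropped and reported.
#' With `caliper > 0`, age may differ by up to `caliper` years while the
#' other keys stay exact.
#'
#' @param cases Output of [select_ad_cases()].
#' @param cohort The full `discharge_cohort`.
#' @param keys Matching keys; default sex, age, race and survey year.
#' @param seed Integer seed making the matching deterministic.
#' @param ad_code Code excluding a patient from the control pool.
#' @param caliper Maximum age difference in years (0 = exact age).
#' @return List of class `matched_cohort`: `cases`, `controls` (row i of
#'   each is a matched pair), `dropped` (unmatched case ids), `keys`.
#' @export
match_controls <- function(cases, cohort,
                           keys = c("sex", "age", "race", "survey_year"),
                           seed = 1L, ad_code = "331.0", caliper = 0) {
  if (nrow(cases) == 0) stop("no cases to match")
  pool <- cohort[!has_code(cohort$dx, ad_code, prefix = FALSE), , drop = FALSE]
  set.seed(split_seed(seed, 5L))
  case_order <- sample.int(nrow(cases))

  if (caliper == 0) {
    key_of <- function(d) do.call(paste, c(d[keys], sep = "\r"))
    ck <- key_of(cases)[case_order]
    pk <- key_of(pool)
    pool_by_key <- split(seq_len(nrow(pool)), pk)
    case_by_key <- split(seq_along(ck), ck)   # positions in shuffled order
    matched_case <- integer(0); matched_ctrl <- integer(0)
    for (k in names(case_by_key)) {
      ctl <- pool_by_key[[k]]
      if (is.null(ctl)) next
      pos <- sort(case_by_key[[k]])           # keep shuffled precedence
      n_take <- min(length(pos), length(ctl))
      matched_case <- c(matched_case, case_order[pos[seq_len(n_take)]])
      matched_ctrl <- c(matched_ctrl, ctl[sample.int(length(ctl), n_take)])
    }
  } else {
    other <- setdiff(keys, "age")
    key_of <- function(d) do.call(paste, c(d[other], sep = "\r"))
    ck <- key_of(cases); pk <- key_of(pool)
    used <- logical(nrow(pool))
    matched_case <- integer(0); matched_ctrl <- integer(0)
    for (i in case_order) {
      elig <- which(!used & pk == ck[i] &
                      abs(pool$age - cases$age[i]) <= caliper)
      if (length(elig) == 0) next
      j <- elig[sample.int(length(elig), 1)]
      used[j] <- TRUE
      matched_case <- c(matched_case, i)
      matched_ctrl <- c(matched_ctrl, j)
    }
  }
  if (length(matched_case) == 0) stop("no case could be matched")
  dropped <- cases$patient_id[setdiff(seq_len(nrow(cases)), matched_case)]
  structure(list(cases = cases[matched_case, , drop = FALSE],
                 controls = pool[matched_ctrl, , drop = FALSE],
                 dropped = dropped, keys = keys),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat("matched_cohort:", nrow(x$cases), "matched pairs on (",
      paste(x$keys, collapse = ", "), ");", length(x$dropped),
      "cases dropped\n")
  invisible(x)
}

#' Comorbidity ratios of diseases among AD cases versus matched controls
#'
#' For each disease code, counts patients carrying the code (prefix match by
#' default, following the ICD-9-CM hierarchy) among the matched AD cases and
#' among their matched controls, and forms ratioAD = case count / control
#' count. Diseases whose combined count is not strictly greater than
#' `min_patients` are excluded for lack of statistical power, as are
#' diseases with a zero control count (ratio undefined; warned).
#'
#' @param matched A [match_controls()] result.
#' @param disease_codes Character vector of codes to evaluate.
#' @param min_patients Strict lower bound on case + control count.
#' @param prefix Prefix (TRUE) or exact (FALSE) code matching.
#' @return data.frame `disease`, `n_cases`, `n_controls`, `n_total`, `ratio`.
#' @export
comorbidity_ratios <- function(matched, disease_codes, min_patients = 15,
                               prefix = TRUE) {
  stopifnot(inherits(matched, "matched_cohort"))
  rows <- lapply(disease_codes, function(code) {
    cc <- sum(has_code(matched$cases$dx, code, prefix))
    kc <- sum(has_code(matched$controls$dx, code, prefix))
    data.frame(disease = code, n_cases = cc, n_controls = kc,
               n_total = cc + kc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  undef <- out$n_controls == 0 & out$n_cases > 0 &
    out$n_total > min_patients
  if (any(undef))
    warning("ratio undefined (zero control count), excluded: ",
            paste(out$disease[undef], collapse = ", "))
  out <- out[out$n_total > min_patients & out$n_controls > 0, , drop = FALSE]
  out$ratio <- out$n_cases / out$n_controls
  rownames(out) <- NULL
  out
}

#' Correlate pathway load with AD comorbidity ratio across diseases
#'
#' For each pathway, computes Pearson's correlation between the diseases'
#' loads on that pathway and their AD comorbidity ratios, over the diseases
#' present in both tables (optionally restricted to a user-supplied subset,
#' e.g. inflammatory diseases). Diseases missing a load for a pathway
#' contribute load 0. Pathways with a constant load vector are skipped with
#' a warning; p-values are Bonferroni-corrected over the pathways tested.
#'
#' @param loads A [pathway_load()] table.
#' @param ratios A [comorbidity_ratios()] table; `disease` must use the
#'   same identifiers as `loads`.
#' @param subset Optional disease subset to restrict the correlation to.
#' @param pathways Pathways to test (default: all in `loads`).
#' @return data.frame of class `load_ratio_correlation`, ranked by p:
#'   `pathway`, `n`, `r`, `p`, `p_bonferroni`.
#' @export
correlate_load_vs_ratio <- function(loads, ratios, subset = NULL,
                                    pathways = sort(unique(loads$pathway))) {
  diseases <- intersect(unique(loads$disease), ratios$disease)
  if (!is.null(subset)) diseases <- intersect(diseases, subset)
  if (length(diseases) < 3)
    stop("need at least 3 diseases present in both tables")
  W <- load_matrix(loads, pathways)
  missing_d <- setdiff(diseases, rownames(W))
  if (length(missing_d)) {
    W <- rbind(W, matrix(0, length(missing_d), ncol(W),
                         dimnames = list(missing_d, colnames(W))))
  }
  W <- W[diseases, , drop = FALSE]
  rvec <- ratios$ratio[match(diseases, ratios$disease)]

  skipped <- character(0)
  rows <- lapply(pathways, function(p) {
    x <- W[, p]
    if (stats::sd(x) == 0 || stats::sd(rvec) == 0) {
      skipped <<- c(skipped, p)
      return(NULL)
    }
    ct <- stats::cor.test(x, rvec, method = "pearson")
    data.frame(pathway = p, n = length(diseases),
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  if (length(skipped))
    warning("pathways with constant load skipped: ",
            length(skipped), " of ", length(pathways))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no pathway with varying load")
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  class(out) <- c("load_ratio_correlation", "data.frame")
  out
}

#' Plant a comorbidity-driving pathway in the cohort generator
#'
#' Builds the `comorbidity_effects` relative-risk map that makes a chosen
#' pathway drive AD comorbidity: each disease's relative risk among AD
#' cases rises linearly with its load on that pathway, up to `max_rr` for
#' the most loaded disease. Used by the parameter-recovery checks of the
#' load-ratio correlation.
#'
#' @param loads A [pathway_load()] table.
#' @param pathway Pathway id to plant on; default picks the pathway whose
#'   load varies most across diseases (the most identifiable plant).
#' @param max_rr Relative risk of the most loaded disease.
#' @return Named numeric vector of relative risks (one per disease), with
#'   the chosen pathway id attached as attribute `pathway`.
#' @export
plant_comorbidity_effects <- function(loads, pathway = NULL, max_rr = 3) {
  W <- load_matrix(loads)
  if (is.null(pathway))
    pathway <- colnames(W)[which.max(apply(W, 2, stats::sd))]
  x <- W[, pathway]
  if (max(x) == 0) stop("pathway ", pathway, " has zero load everywhere")
  rr <- 1 + (max_rr - 1) * x / max(x)
  attr(rr, "pathway") <- pathway
  rr
}
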