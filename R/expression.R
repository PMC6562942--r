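#' Expression study container
#'
#' A genes x samples matrix of (log-scale, pre-normalised) expression values
#' together with a sample sheet carrying diagnosis and the model covariates.
#'
#' @param expr Numeric matrix, rows genes, columns samples.
#' @param samples data.frame with columns `sample`, `diagnosis`
#'   (one of AD / MCI / control), `age`, `sex`, `centre`, in the order of
#'   `colnames(expr)`.
#' @return Object of class `expression_study`.
#' @export
expression_study <- function(expr, samples) {
  req <- c("sample", "diagnosis", "age", "sex", "centre")
  stopifnot(is.matrix(expr), all(req %in% names(samples)),
            ncol(expr) == nrow(samples))
  if (!identical(colnames(expr), samples$sample))
    stop("expression columns and sample sheet disagree")
  if (anyNA(samples$diagnosis)) stop("missing diagnosis is not allowed")
  bad <- setdiff(unique(samples$diagnosis), c("AD", "MCI", "control"))
  if (length(bad)) stop("unknown diagnosis labels: ", paste(bad, collapse = ", "))
  structure(list(expr = expr, samples = samples), class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$expr), "genes x", ncol(x$expr), "samples (",
      paste(sprintf("%s=%d", names(table(x$samples$diagnosis)),
                    table(x$samples$diagnosis)), collapse = ", "), ")\n")
  invisible(x)
}

#' Per-gene logistic model of diagnosis on expression
#'
#' For every gene, fits a generalised linear model with binomial link that
#' models case status (group 1 of `comparison` versus group 2) as a
#' function of the gene's expression while controlling for age, sex and
#' sampling centre (the centre term is omitted when only one centre is
#' present, likewise sex). Expression is standardised per gene before the
#' fit for numerical stability; the Wald p-value of the expression term is
#' invariant to that affine transform. Samples with missing covariates are
#' dropped globally before fitting, with the count recorded. Genes with
#' zero expression variance, non-converged fits or (quasi-)separated fits
#' are flagged rather than dropped; flagged genes get p = NA.
#'
#' @param study An [expression_study()].
#' @param comparison Length-2 character, e.g. `c("AD", "control")`; the
#'   first element is coded 1.
#' @param genes Genes to fit (default: all rows).
#' @return data.frame of class `gene_glm_results`: `gene`, `estimate`,
#'   `se`, `p`, `flag` ("" when clean), `comparison`; the number of samples
#'   dropped for missing covariates is attached as attribute
#'   `n_dropped_samples`.
#' @export
per_gene_glm <- function(study, comparison = c("AD", "control"),
                         genes = rownames(study$expr)) {
  stopifnot(inherits(study, "expression_study"), length(comparison) == 2)
  s <- study$samples
  keep <- s$diagnosis %in% comparison
  s <- s[keep, , drop = FALSE]
  complete <- stats::complete.cases(s[c("age", "sex", "centre")])
  n_dropped <- sum(!complete)
  s <- s[complete, , drop = FALSE]
  if (length(unique(s$diagnosis)) < 2 || min(table(s$diagnosis)) < 2)
    stop("need at least 2 samples in each comparison group")
  y <- as.integer(s$diagnosis == comparison[1])
  E <- study$expr[genes, s$sample, drop = FALSE]

  covars <- data.frame(age = s$age)
  if (length(unique(s$sex)) > 1) covars$sex <- factor(s$sex)
  if (length(unique(s$centre)) > 1) covars$centre <- factor(s$centre)

  rows <- lapply(genes, function(g) {
    x <- E[g, ]
    if (stats::sd(x) == 0)
      return(data.frame(gene = g, estimate = NA_real_, se = NA_real_,
                        p = NA_real_, flag = "zero_variance",
                        stringsAsFactors = FALSE))
    dat <- cbind(data.frame(y = y, expr = as.vector(scale(x))), covars)
    flag <- ""
    fit <- withCallingHandlers(
      stats::glm(y ~ ., data = dat, family = stats::binomial()),
      warning = function(w) {
        flag <<- "non_converged"
        invokeRestart("muffleWarning")
      })
    if (!fit$converged) flag <- "non_converged"
    co <- summary(fit)$coefficients
    if (!"expr" %in% rownames(co) || flag == "non_converged")
      return(data.frame(gene = g,
                        estimate = if ("expr" %in% rownames(co))
                          co["expr", 1] else NA_real_,
                        se = NA_real_, p = NA_real_,
                        flag = if (flag == "") "dropped_term" else flag,
                        stringsAsFactors = FALSE))
    data.frame(gene = g, estimate = co["expr", 1], se = co["expr", 2],
               p = co["expr", 4], flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$comparison <- paste(comparison, collapse = "-vs-")
  attr(out, "n_dropped_samples") <- n_dropped
  class(out) <- c("gene_glm_results", "data.frame")
  out
}

#' Exact one-sided binomial test for pathway enrichment
#'
#' Upper-tail probability P(X >= k) for X ~ Binomial(n, p0), computed by
#' direct summation of the binomial mass over k..n. Used to ask whether the
#' proportion of significantly dysregulated genes in a pathway (k of n
#' measured genes) is larger than expected by chance at the per-gene level
#' p0 (default 0.05).
#'
#' @param k Number of significant genes (0 <= k <= n).
#' @param n Number of pathway genes measured.
#' @param p0 Null per-gene significance proportion.
#' @return The exact one-sided p-value.
#' @export
pathway_binomial_test <- function(k, n, p0 = 0.05) {
  stopifnot(length(k) == 1, length(n) == 1, k >= 0, n >= k, p0 > 0, p0 < 1)
  if (k == 0) return(1)
  sum(stats::dbinom(seq(k, n), n, p0))
}

#' Select significant genes under a multiplicity rule
#'
#' @param results A [per_gene_glm()] table.
#' @param method `"raw"` (unadjusted p < alpha), `"bonferroni"` (family =
#'   number of genes tested, i.e. non-NA p-values) or `"bh_fdr"`
#'   (Benjamini-Hochberg step-up).
#' @param alpha Significance level.
#' @return List of class `significance_rule`: `genes` (character vector),
#'   `k`, `n` (genes tested), `method`, `alpha`, and `p_adj` (named, NA for
#'   flagged genes).
#' @export
significance_rule <- function(results, method = c("raw", "bonferroni", "bh_fdr"),
                              alpha = 0.05) {
  method <- match.arg(method)
  p <- stats::setNames(results$p, results$gene)
  tested <- !is.na(p)
  p_adj <- rep(NA_real_, length(p))
  names(p_adj) <- names(p)
  p_adj[tested] <- switch(method,
    raw = p[tested],
    bonferroni = pmin(1, p[tested] * sum(tested)),
    bh_fdr = stats::p.adjust(p[tested], "BH"))
  genes <- names(p_adj)[tested & p_adj < alpha]
  structure(list(genes = genes, k = length(genes), n = sum(tested),
                 method = method, alpha = alpha, p_adj = p_adj),
            class = "significance_rule")
}

#' @export
print.significance_rule <- function(x, ...) {
  cat("significance_rule:", x$k, "of", x$n, "genes significant (",
      x$method, ", alpha =", x$alpha, ")\n")
  invisible(x)
}

#' Spearman concordance of per-gene p-values between two studies
#'
#' @param results_a,results_b Two [per_gene_glm()] tables.
#' @param min_shared Minimum number of shared genes with p-values in both.
#' @return List `rho`, `p`, `n` (shared genes used).
#' @export
cross_dataset_concordance <- function(results_a, results_b, min_shared = 5L) {
  shared <- intersect(results_a$gene[!is.na(results_a$p)],
                      results_b$gene[!is.na(results_b$p)])
  if (length(shared) < min_shared)
    stop("fewer than ", min_shared, " shared genes with p-values")
  pa <- results_a$p[match(shared, results_a$gene)]
  pb <- results_b$p[match(shared, results_b$gene)]
  ct <- suppressWarnings(stats::cor.test(pa, pb, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Merge expression studies on their shared genes
#'
#' Concatenates samples over the gene intersection. The centre covariate of
#' the merged study is prefixed with the study of origin, so the downstream
#' model absorbs between-study differences the same way it absorbs
#' between-centre differences; sample ids are prefixed likewise to stay
#' unique.
#'
#' @param studies Named list of [expression_study()] objects.
#' @return A merged `expression_study`.
#' @export
merge_studies <- function(studies) {
  stopifnot(length(studies) >= 2)
  if (is.null(names(studies)) || any(names(studies) == ""))
    names(studies) <- sprintf("study%d", seq_along(studies))
  genes <- Reduce(intersect, lapply(studies, function(s) rownames(s$expr)))
  if (length(genes) == 0) stop("the studies share no genes")
  mats <- list(); sheets <- list()
  for (nm in names(studies)) {
    s <- studies[[nm]]
    sm <- s$samples
    sm$sample <- paste(nm, sm$sample, sep = ".")
    sm$centre <- paste(nm, sm$centre, sep = ".")
    E <- s$expr[genes, , drop = FALSE]
    colnames(E) <- sm$sample
    mats[[nm]] <- E
    sheets[[nm]] <- sm
  }
  expression_study(do.call(cbind, mats), do.call(rbind, sheets))
}

#' Pathway-level dysregulation analysis of an expression study
#'
#' Convenience wrapper running the per-gene model over the measured genes
#' of one pathway, applying a significance rule, and testing whether the
#' significant proportion exceeds the chance level p0 with the exact
#' binomial test.
#'
#' @param study An [expression_study()].
#' @param annotation A [pathway_annotation()].
#' @param pathway Pathway id.
#' @param comparison Passed to [per_gene_glm()].
#' @param method,alpha Passed to [significance_rule()].
#' @param p0 Null proportion for [pathway_binomial_test()].
#' @return List of class `pathway_enrichment`: `pathway`, `n_measured`,
#'   `k`, `rule`, `p0`, `p_binomial`, `glm_results`.
#' @export
pathway_enrichment <- function(study, annotation, pathway,
                               comparison = c("AD", "control"),
                               method = "raw", alpha = 0.05, p0 = 0.05) {
  genes <- intersect(annotation$sets[[pathway]], rownames(study$expr))
  if (length(genes) == 0) stop("no gene of ", pathway, " is measured")
  res <- per_gene_glm(study, comparison, genes = genes)
  rule <- significance_rule(res, method, alpha)
  structure(list(pathway = pathway, n_measured = rule$n, k = rule$k,
                 rule = rule$method, p0 = p0,
                 p_binomial = pathway_binomial_test(rule$k, rule$n, p0),
                 glm_results = res),
            class = "pathway_enrichment")
}

#' @export
print.pathway_enrichment <- function(x, ...) {
  cat(sprintf("pathway_enrichment %s: %d of %d genes significant (%s); exact binomial p = %.3g\n",
              x$pathway, x$k, x$n_measured, x$rule, x$p_binomial))
  invisible(x)
}
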