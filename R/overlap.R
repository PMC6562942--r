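#' Filter a disease-gene catalog to its retained genes
#'
#' Keeps only diseases with at least `min_genes` associated genes and, per
#' disease, the `top_k` most strongly associated genes ranked by ascending
#' p-value. Ties on p-value are broken by original row order, then by gene
#' symbol, so the selection is deterministic.
#'
#' @param catalog data.frame with columns `disease`, `gene`, `p_value`.
#' @param top_k Genes retained per disease.
#' @param min_genes Minimum associated genes for a disease to enter.
#' @return The retained catalog, sorted by p within disease, with attribute
#'   `retained = TRUE`.
#' @export
retain_catalog <- function(catalog, top_k = 25L, min_genes = 25L) {
  stopifnot(all(c("disease", "gene", "p_value") %in% names(catalog)))
  if (nrow(catalog) == 0) stop("empty catalog")
  if (anyDuplicated(catalog[c("disease", "gene")]))
    stop("duplicate gene within a disease")
  catalog$.row <- seq_len(nrow(catalog))
  parts <- split(catalog, catalog$disease)
  parts <- parts[vapply(parts, nrow, 0L) >= min_genes]
  if (length(parts) == 0)
    stop("no disease has at least ", min_genes, " associated genes")
  out <- do.call(rbind, lapply(parts, function(d) {
    d <- d[order(d$p_value, d$.row, d$gene), ]
    utils::head(d, top_k)
  }))
  out$.row <- NULL
  rownames(out) <- NULL
  attr(out, "retained") <- TRUE
  out
}

#' Build the gene-by-gene shared-pathway matrix
#'
#' For every pair of genes in the catalog's retained gene universe, counts
#' the number of pathways the two genes share: n(alpha, beta). The diagonal
#' holds each gene's own pathway-membership count; genes absent from the
#' annotation get an all-zero row (diagonal included).
#'
#' @param catalog A retained catalog (see [retain_catalog()]); if not yet
#'   retained it is filtered with the default thresholds.
#' @param annotation A [pathway_annotation()].
#' @return A symmetric integer matrix with the gene universe as dimnames
#'   and the retained catalog attached as attribute `catalog`.
#' @export
build_shared_matrix <- function(catalog, annotation) {
  if (is.null(attr(catalog, "retained"))) catalog <- retain_catalog(catalog)
  if (nrow(catalog) == 0) stop("empty catalog")
  universe <- unique(catalog$gene)
  path_ids <- names(annotation$sets)
  m <- matrix(0L, length(universe), length(path_ids),
              dimnames = list(universe, path_ids))
  for (p in path_ids) {
    members <- intersect(annotation$sets[[p]], universe)
    m[members, p] <- 1L
  }
  n <- m %*% t(m)
  storage.mode(n) <- "integer"
  stopifnot(isSymmetric(n))
  attr(n, "catalog") <- catalog
  n
}

#' One-tailed rank-sum test that `x` is stochastically greater than `y`
#'
#' Mann-Whitney form with midranks. For small samples (both sizes at most
#' `exact_max`) the p-value is computed by exhaustive enumeration of every
#' assignment of the pooled observations to the two groups, which is exact
#' under ties. Otherwise the normal approximation with tie-corrected
#' variance and a continuity correction is used. If the pooled sample is
#' constant the p-value is 1.
#'
#' @param x,y Numeric samples.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) enumeration; default
#'   `NULL` enumerates when both samples have at most `exact_max` elements.
#' @param exact_max Size cutoff for automatic enumeration.
#' @return List with `statistic` (Mann-Whitney U for `x`), `p.value`, and
#'   `exact` (logical).
#' @export
rank_sum_greater <- function(x, y, exact = NULL, exact_max = 8L) {
  n <- length(x); m <- length(y)
  if (n < 1 || m < 1) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  U <- W - n * (n + 1) / 2
  if (is.null(exact)) exact <- n <= exact_max && m <= exact_max
  if (exact) {
    cmb <- utils::combn(n + m, n)
    Ws <- colSums(matrix(r[cmb], nrow = n))
    p <- mean(Ws >= W - 1e-9)
  } else {
    N <- n + m
    tie <- table(r)
    s2 <- (n * m / 12) * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (s2 <= 0) {
      p <- 1
    } else {
      z <- (U - n * m / 2 - 0.5) / sqrt(s2)
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
  }
  list(statistic = U, p.value = min(1, max(p, 0)), exact = exact)
}

# classify the retained gene universe of the matrix for a disease pair and
# pull the two shared-pathway count samples:
#   S+ : unordered gene pairs with one end in A and the other in B
#   S- : unordered pairs with at least one end in A or B that do not qualify
#        for S+ (exactly-one-membership orientation of the defining rule)
# the diagonal (a gene paired with itself) is excluded from both.
overlap_samples <- function(a_genes, b_genes, matrix) {
  u <- rownames(matrix)
  inA <- u %in% a_genes
  inB <- u %in% b_genes
  iA <- which(inA & !inB)   # A only
  iB <- which(inB & !inA)   # B only
  iC <- which(inA & inB)    # both
  iN <- which(!inA & !inB)  # neither
  ut <- function(M) M[upper.tri(M)]
  splus <- c(as.vector(matrix[iA, iB, drop = FALSE]),
             as.vector(matrix[iA, iC, drop = FALSE]),
             as.vector(matrix[iB, iC, drop = FALSE]),
             ut(matrix[iC, iC, drop = FALSE]))
  sminus <- c(ut(matrix[iA, iA, drop = FALSE]),
              as.vector(matrix[iA, iN, drop = FALSE]),
              ut(matrix[iB, iB, drop = FALSE]),
              as.vector(matrix[iB, iN, drop = FALSE]),
              as.vector(matrix[iC, iN, drop = FALSE]))
  list(splus = splus, sminus = sminus)
}

#' Test a disease pair for overlap in pathway space
#'
#' Collects the shared-pathway counts of gene pairs with one gene in each
#' disease's retained set (sample S+) and of pairs where exactly one gene
#' belongs to the corresponding disease set, the partner ranging over the
#' full retained gene universe (sample S-), and applies a one-tailed
#' Wilcoxon rank-sum test of whether S+ is stochastically greater than S-.
#' Unordered gene pairs enter once; a gene paired with itself is excluded
#' from both samples, so shared susceptibility genes cannot drive the test
#' through their own diagonal counts. If either sample has fewer than
#' `min_sample` elements the pair is flagged and given p = 1.
#'
#' @param a,b Disease ids (must differ and be present in the catalog).
#' @param matrix Shared-pathway matrix from [build_shared_matrix()].
#' @param catalog Retained catalog; defaults to the one attached to `matrix`.
#' @param exact_max Passed to [rank_sum_greater()].
#' @param min_sample Minimum size of each sample.
#' @return List of class `overlap_test` with the pair, sample sizes, U
#'   statistic, one-tailed `p.value` and `low_n` flag.
#' @export
overlap_test <- function(a, b, matrix, catalog = attr(matrix, "catalog"),
                         exact_max = 8L, min_sample = 3L) {
  if (identical(a, b)) stop("the two diseases must differ")
  if (is.null(catalog)) stop("catalog required")
  if (!all(c(a, b) %in% catalog$disease))
    stop("disease not in catalog: ",
         paste(setdiff(c(a, b), catalog$disease), collapse = ", "))
  s <- overlap_samples(catalog$gene[catalog$disease == a],
                       catalog$gene[catalog$disease == b], matrix)
  if (length(s$splus) < min_sample || length(s$sminus) < min_sample) {
    warning("overlap_test(", a, ", ", b, "): sample below ", min_sample,
            " gene pairs; returning p = 1")
    res <- list(statistic = NA_real_, p.value = 1, exact = FALSE)
    low_n <- TRUE
  } else {
    res <- rank_sum_greater(s$splus, s$sminus, exact_max = exact_max)
    low_n <- FALSE
  }
  structure(list(disease_a = a, disease_b = b,
                 n_splus = length(s$splus), n_sminus = length(s$sminus),
                 statistic = res$statistic, p.value = res$p.value,
                 exact = res$exact, low_n = low_n),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("overlap %s ~ %s: |S+|=%d |S-|=%d U=%s p=%.3g%s\n",
              x$disease_a, x$disease_b, x$n_splus, x$n_sminus,
              format(x$statistic), x$p.value,
              if (x$low_n) " [low n]" else ""))
  invisible(x)
}

#' Test all disease pairs and summarise the significance graph
#'
#' Runs [overlap_test()] on every unordered disease pair, corrects the
#' p-values over the family of all tested pairs (Bonferroni by default,
#' Benjamini-Hochberg optionally), and summarises the graph whose edges are
#' the significant pairs: adjacency matrix, connected components and
#' per-disease significant-neighbour counts. No clustering algorithm is
#' imposed; the graph summary supports statements such as "k of the m
#' pairs within this disease subset are significant".
#'
#' @param catalog Retained catalog (see [retain_catalog()]).
#' @param matrix Shared-pathway matrix over the catalog's universe.
#' @param alpha Significance level applied to adjusted p-values.
#' @param correction `"bonferroni"` (default) or `"bh_fdr"`.
#' @param subset Optional character vector of diseases; the returned
#'   summary then counts significant pairs within this subset.
#' @param exact_max,min_sample Passed to [overlap_test()].
#' @return List of class `overlap_scan`: `results` (one row per pair with
#'   `p_adj` and `significant`), `adjacency`, `components` (membership),
#'   `neighbour_counts`, `n_pairs`, and `subset_summary` (or NULL).
#' @export
all_pairs_overlap <- function(catalog, matrix, alpha = 0.05,
                              correction = c("bonferroni", "bh_fdr"),
                              subset = NULL, exact_max = 8L, min_sample = 3L) {
  correction <- match.arg(correction)
  diseases <- unique(catalog$disease)
  if (length(diseases) < 2) stop("need at least two diseases")
  pairs <- utils::combn(diseases, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    r <- overlap_test(pairs[1, i], pairs[2, i], matrix, catalog,
                      exact_max = exact_max, min_sample = min_sample)
    data.frame(disease_a = r$disease_a, disease_b = r$disease_b,
               n_splus = r$n_splus, n_sminus = r$n_sminus,
               statistic = r$statistic, p = r$p.value, low_n = r$low_n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  n_pairs <- nrow(res)
  res$p_adj <- if (correction == "bonferroni")
    pmin(1, res$p * n_pairs) else stats::p.adjust(res$p, "BH")
  res$significant <- res$p_adj < alpha

  adj <- matrix(FALSE, length(diseases), length(diseases),
                dimnames = list(diseases, diseases))
  sig <- res[res$significant, , drop = FALSE]
  if (nrow(sig)) {
    adj[cbind(sig$disease_a, sig$disease_b)] <- TRUE
    adj[cbind(sig$disease_b, sig$disease_a)] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership

  subset_summary <- NULL
  if (!is.null(subset)) {
    subset <- intersect(subset, diseases)
    k <- length(subset)
    n_sig <- sum(sig$disease_a %in% subset & sig$disease_b %in% subset)
    subset_summary <- list(diseases = subset,
                           n_significant = n_sig,
                           n_possible = k * (k - 1) / 2)
  }
  structure(list(results = res[order(res$p), ], adjacency = adj,
                 components = comp,
                 neighbour_counts = rowSums(adj),
                 n_pairs = n_pairs, alpha = alpha, correction = correction,
                 subset_summary = subset_summary),
            class = "overlap_scan")
}

#' @export
print.overlap_scan <- function(x, ...) {
  cat("overlap_scan:", x$n_pairs, "pairs,",
      sum(x$results$significant), "significant at adjusted alpha =",
      x$alpha, paste0("(", x$correction, ")\n"))
  if (!is.null(x$subset_summary))
    cat("  subset:", x$subset_summary$n_significant, "of",
        x$subset_summary$n_possible, "pairs significant\n")
  invisible(x)
}
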