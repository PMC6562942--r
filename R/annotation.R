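#' Pathway annotation (gene sets)
#'
#' A pathway annotation maps pathway ids to gene sets, with a consistent
#' inverse map from gene to the set of pathways it belongs to. This is the
#' container behind the shared-pathway counts n(alpha, beta) and the
#' per-disease pathway loads.
#'
#' @param sets Named list of character vectors (pathway id -> genes).
#' @param descriptions Optional named character vector of pathway
#'   descriptions (defaults to the pathway id).
#' @return An object of class `pathway_annotation` with elements `sets`
#'   (forward map, genes deduplicated) and `inverse` (gene -> pathway ids).
#' @export
pathway_annotation <- function(sets, descriptions = NULL) {
  if (length(sets) == 0) stop("annotation must contain at least one pathway")
  if (is.null(names(sets)) || anyNA(names(sets)) || any(names(sets) == ""))
    stop("all pathways must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate pathway ids: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) stop("empty pathways are not allowed")
  if (is.null(descriptions)) descriptions <- names(sets)
  ids <- names(sets)
  inverse <- split(rep(ids, lengths(sets)), unlist(sets, use.names = FALSE))
  structure(list(sets = sets, inverse = inverse,
                 descriptions = stats::setNames(descriptions, ids)),
            class = "pathway_annotation")
}

#' @export
print.pathway_annotation <- function(x, ...) {
  cat("pathway_annotation:", length(x$sets), "pathways,",
      length(x$inverse), "genes; sizes",
      min(lengths(x$sets)), "-", max(lengths(x$sets)), "\n")
  invisible(x)
}

#' Pathways of a gene
#'
#' @param annotation A [pathway_annotation()].
#' @param gene Gene symbol.
#' @return Character vector of pathway ids (empty if unannotated).
#' @export
gene_pathways <- function(annotation, gene) {
  p <- annotation$inverse[[gene]]
  if (is.null(p)) character(0) else p
}

#' Drop pathways from an annotation
#'
#' @param annotation A [pathway_annotation()].
#' @param drop Pathway ids to remove.
#' @return A new `pathway_annotation`.
#' @export
drop_pathways <- function(annotation, drop) {
  keep <- setdiff(names(annotation$sets), drop)
  if (length(keep) == 0) stop("cannot drop every pathway")
  pathway_annotation(annotation$sets[keep], annotation$descriptions[keep])
}
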