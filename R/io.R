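pkg_version <- function() {
  as.character(utils::packageVersion("pathcomorbid"))
}

# header line written at the top of every output file
output_header <- function(seed = NA, config = NULL) {
  sprintf("# pathcomorbid %s | seed=%s | config=%s", pkg_version(),
          as.character(seed),
          if (is.null(config)) "-" else config_hash(config))
}

write_with_header <- function(df, path, sep, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, config), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_skip_header <- function(path, sep, ...) {
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: one pathway per line, fields pathway id,
#' description, then member genes (at least one). Duplicate genes within a
#' line are deduplicated; duplicate pathway ids across lines and malformed
#' lines are rejected with the offending line number.
#'
#' @param path File path.
#' @return A [pathway_annotation()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop("malformed GMT line ", bad[1], " in ", path,
         ": fewer than 3 tab-separated fields")
  ids <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate pathway id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  pathway_annotation(sets, vapply(fields, `[[`, "", 2))
}

#' Write a pathway annotation as GMT
#'
#' @param annotation A [pathway_annotation()].
#' @param path File path.
#' @export
write_gmt <- function(annotation, path) {
  lines <- vapply(names(annotation$sets), function(id) {
    paste(c(id, annotation$descriptions[[id]], annotation$sets[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a disease-gene catalog TSV
#'
#' Columns `disease`, `gene`, `p_value`; a `#` header records the package
#' version, seed and configuration hash.
#'
#' @param catalog The catalog data.frame.
#' @param path File path.
#' @param seed,config Provenance recorded in the header.
#' @export
write_catalog_tsv <- function(catalog, path, seed = NA, config = NULL) {
  write_with_header(catalog, path, "\t", seed, config)
}

#' @rdname write_catalog_tsv
#' @export
read_catalog_tsv <- function(path) {
  out <- read_skip_header(path, "\t")
  req <- c("disease", "gene", "p_value")
  if (!all(req %in% names(out)))
    stop("catalog TSV must have columns ", paste(req, collapse = ", "))
  out$p_value <- as.numeric(out$p_value)
  if (anyNA(out$p_value)) stop("non-numeric p_value in ", path)
  out
}

#' Write / read a discharge cohort CSV
#'
#' Diagnosis codes are semicolon-joined in the `dx` column; the reader
#' rebuilds the list-column. Records with an empty code list are rejected.
#'
#' @param cohort A `discharge_cohort` data.frame.
#' @param path File path.
#' @param seed,config Provenance recorded in the header.
#' @export
write_cohort_csv <- function(cohort, path, seed = NA, config = NULL) {
  flat <- as.data.frame(cohort[setdiff(names(cohort), "dx")])
  flat$dx <- vapply(cohort$dx, paste, "", collapse = ";")
  write_with_header(flat, path, ",", seed, config)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- read_skip_header(path, ",", colClasses = c(dx = "character"))
  req <- c("patient_id", "age", "sex", "race", "survey_year", "dx")
  if (!all(req %in% names(out)))
    stop("cohort CSV must have columns ", paste(req, collapse = ", "))
  if (any(out$age < 0)) stop("negative age in ", path)
  dx <- strsplit(as.character(out$dx), ";", fixed = TRUE)
  if (any(lengths(dx) == 0) || any(!nzchar(unlist(dx))))
    stop("empty diagnosis code list in ", path)
  out$dx <- dx
  class(out) <- c("discharge_cohort", "data.frame")
  out
}

#' Write / read an expression study (matrix TSV + sample sheet TSV)
#'
#' @param study An [expression_study()].
#' @param matrix_path,samples_path File paths.
#' @param seed,config Provenance recorded in the headers.
#' @export
write_expression_tsv <- function(study, matrix_path, samples_path,
                                 seed = NA, config = NULL) {
  m <- data.frame(gene = rownames(study$expr), study$expr,
                  check.names = FALSE)
  write_with_header(m, matrix_path, "\t", seed, config)
  write_with_header(study$samples, samples_path, "\t", seed, config)
  invisible(c(matrix_path, samples_path))
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(matrix_path, samples_path) {
  m <- read_skip_header(matrix_path, "\t")
  samples <- read_skip_header(samples_path, "\t")
  expr <- as.matrix(m[, -1, drop = FALSE])
  rownames(expr) <- m$gene
  samples$sample <- as.character(samples$sample)
  expression_study(expr, samples)
}

#' Write / read a qPCR plate CSV
#'
#' Columns `sample`, `group`, `gene`, `replicate`, `ct`.
#'
#' @param plate A `qpcr_plate` data.frame.
#' @param path File path.
#' @param seed,config Provenance recorded in the header.
#' @export
write_qpcr_csv <- function(plate, path, seed = NA, config = NULL) {
  write_with_header(as.data.frame(plate), path, ",", seed, config)
}

#' @rdname write_qpcr_csv
#' @export
read_qpcr_csv <- function(path) {
  out <- read_skip_header(path, ",")
  req <- c("sample", "group", "gene", "replicate", "ct")
  if (!all(req %in% names(out)))
    stop("qPCR CSV must have columns ", paste(req, collapse = ", "))
  out$ct <- as.numeric(out$ct)
  if (anyNA(out$ct) || any(out$ct <= 0))
    stop("CT values must be positive numbers in ", path)
  class(out) <- c("qpcr_plate", "data.frame")
  out
}
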