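#' Relative quantification of a qPCR target by the 2^-ddCT method
#'
#' Per sample, technical replicates are averaged to one CT per gene; the
#' normaliser is the arithmetic mean of the housekeeping genes' replicate-
#' mean CTs (equivalent to a geometric mean of the linear quantities);
#' dCT = mean target CT - normaliser CT, ddCT = dCT - mean dCT of the
#' control group (the calibrator), and the fold change is 2^-ddCT. By
#' construction the control group's mean ddCT is 0, so its geometric mean
#' fold is 1. Samples missing any housekeeping measurement are excluded
#' with a warning; an empty control group is an error.
#'
#' @param plate A `qpcr_plate` data.frame (`sample`, `group`, `gene`,
#'   `replicate`, `ct`).
#' @param target Target gene name.
#' @param housekeeping Character vector of housekeeping gene names.
#' @param control_group Group label used as calibrator.
#' @return List of class `fold_change_result`: `gene`, `per_sample`
#'   (data.frame `sample`, `group`, `dct`, `ddct`, `fold`), `control_group`
#'   and per-group `mean_fold` / `sem` (mean and standard error of the
#'   per-sample folds).
#' @export
ddct_fold_changes <- function(plate, target, housekeeping,
                              control_group = "PBS") {
  stopifnot(all(c("sample", "group", "gene", "replicate", "ct") %in%
                  names(plate)))
  if (any(plate$ct <= 0)) stop("CT values must be positive")
  if (!target %in% plate$gene) stop("target gene absent from plate: ", target)
  if (!all(housekeeping %in% plate$gene))
    stop("housekeeping gene absent from plate: ",
         paste(setdiff(housekeeping, plate$gene), collapse = ", "))

  mean_ct <- stats::aggregate(ct ~ sample + group + gene, plate, mean)
  samples <- unique(mean_ct[c("sample", "group")])
  hk <- mean_ct[mean_ct$gene %in% housekeeping, ]
  hk_n <- table(hk$sample)
  ok <- names(hk_n)[hk_n == length(housekeeping)]
  bad <- setdiff(samples$sample, ok)
  tg <- mean_ct[mean_ct$gene == target, ]
  bad <- union(bad, setdiff(samples$sample, tg$sample))
  if (length(bad)) {
    warning("samples missing target or housekeeping measurements excluded: ",
            paste(bad, collapse = ", "))
    samples <- samples[!samples$sample %in% bad, , drop = FALSE]
  }
  if (!any(samples$group == control_group))
    stop("control group '", control_group, "' is empty")

  norm_ct <- tapply(hk$ct[hk$sample %in% samples$sample],
                    hk$sample[hk$sample %in% samples$sample], mean)
  dct <- tg$ct[match(samples$sample, tg$sample)] -
    as.vector(norm_ct[samples$sample])
  calibrator <- mean(dct[samples$group == control_group])
  ddct <- dct - calibrator
  per_sample <- data.frame(sample = samples$sample, group = samples$group,
                           dct = dct, ddct = ddct, fold = 2^(-ddct),
                           stringsAsFactors = FALSE)
  stats_by_group <- lapply(split(per_sample$fold, per_sample$group),
                           function(f) c(mean_fold = mean(f),
                                         sem = stats::sd(f) / sqrt(length(f))))
  structure(list(gene = target, per_sample = per_sample,
                 control_group = control_group,
                 group_stats = do.call(rbind, stats_by_group)),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat("fold_change_result", x$gene, "(calibrator:", x$control_group, ")\n")
  print(round(x$group_stats, 3))
  invisible(x)
}

#' Two-sample Student's t-test between treatment groups
#'
#' Equal-variance two-sample t-test comparing the two groups of a fold-
#' change result. By default the test is performed on the ddCT values,
#' whose Gaussian-noise assumptions match the t-test (folds are
#' log-normal); `on = "fold"` tests the fold scale instead. Identical
#' groups give p = 1.
#'
#' @param result A [ddct_fold_changes()] result.
#' @param on `"ddct"` (default) or `"fold"`.
#' @return List `t`, `p`, `df`, `on`.
#' @export
group_ttest <- function(result, on = c("ddct", "fold")) {
  on <- match.arg(on)
  ps <- result$per_sample
  groups <- unique(ps$group)
  if (length(groups) != 2) stop("need exactly two groups, got ",
                                length(groups))
  if (any(table(ps$group) < 2)) stop("need at least 2 samples per group")
  x <- ps[[on]][ps$group == groups[1]]
  y <- ps[[on]][ps$group == groups[2]]
  df <- length(x) + length(y) - 2
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # both groups constant: no within-group variance for the t denominator
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t = 0, p = 1, df = df, on = on))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0, df = df, on = on))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), on = on)
}

#' Quantify several qPCR targets and test group differences
#'
#' @param plate A `qpcr_plate` data.frame.
#' @param targets Target gene names.
#' @param housekeeping Housekeeping gene names.
#' @param control_group Calibrator group label.
#' @param on Scale of the t-test, see [group_ttest()].
#' @return data.frame `gene`, `mean_fold`, `sem` (treated group), `t`, `p`.
#' @export
qpcr_analysis <- function(plate, targets, housekeeping,
                          control_group = "PBS", on = "ddct") {
  rows <- lapply(targets, function(g) {
    fc <- ddct_fold_changes(plate, g, housekeeping, control_group)
    treated <- setdiff(rownames(fc$group_stats), control_group)
    tt <- group_ttest(fc, on)
    data.frame(gene = g,
               mean_fold = fc$group_stats[treated, "mean_fold"],
               sem = fc$group_stats[treated, "sem"],
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
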