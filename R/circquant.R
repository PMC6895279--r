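# Circular-RNA enrichment from backsplice/linear junction-count tables.

#' Detect circular RNAs from backsplice junction reads
#'
#' A circle is detected in a condition when it has at least `min_reads`
#' backsplice junction reads in at least one library of that condition; the
#' replicate-consistent set additionally requires `min_reads` in every
#' replicate.
#'
#' @param table junction table (see [read_junctions()] for columns).
#' @param min_reads minimum junction reads (default 2).
#' @return data.frame per gene: `detected_control`, `detected_rnaser`,
#'   `consistent_control`, `consistent_rnaser`.
#' @export
detect_circles <- function(table, min_reads = 2L) {
  if (!nrow(table)) stop_param("empty junction table")
  genes <- unique(table$gene_id)
  res <- lapply(c("control", "rnaser"), function(cond) {
    sub <- table[table$condition == cond, , drop = FALSE]
    det <- tapply(sub$backsplice_reads >= min_reads, sub$gene_id, any)
    con <- tapply(sub$backsplice_reads >= min_reads, sub$gene_id, all)
    cbind(det[genes], con[genes])
  })
  out <- data.frame(
    gene_id = genes,
    detected_control = unname(res[[1L]][, 1L]),
    detected_rnaser = unname(res[[2L]][, 1L]),
    consistent_control = unname(res[[1L]][, 2L]),
    consistent_rnaser = unname(res[[2L]][, 2L]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Fold enrichment of backsplice junction reads after RNase R
#'
#' Per gene and replicate, backsplice reads are normalized to reads per
#' million mapped reads (RPM); the fold enrichment is the treated/control RPM
#' ratio averaged over replicates. Genes with zero control RPM in every
#' replicate are undefined (`NA`, with a message). The pooled fold (total
#' treated RPM over total control RPM across all libraries and genes) is
#' attached as attribute `pooled_fold`.
#'
#' @param table junction table.
#' @return data.frame `gene_id`, `fold_enrichment`; attribute `pooled_fold`.
#' @export
fold_enrichment <- function(table) {
  if (!nrow(table)) stop_param("empty junction table")
  rpm <- table$backsplice_reads / table$library_mapped_reads * 1e6
  genes <- unique(table$gene_id)
  reps <- sort(unique(table$replicate))
  fold <- vapply(genes, function(g) {
    fr <- vapply(reps, function(r) {
      ci <- table$gene_id == g & table$condition == "control" & table$replicate == r
      ti <- table$gene_id == g & table$condition == "rnaser" & table$replicate == r
      if (!any(ci) || !any(ti) || sum(rpm[ci]) == 0) return(NA_real_)
      sum(rpm[ti]) / sum(rpm[ci])
    }, numeric(1L))
    if (all(is.na(fr))) NA_real_ else mean(fr, na.rm = TRUE)
  }, numeric(1L))
  if (anyNA(fold)) {
    message(sum(is.na(fold)), " gene(s) excluded from fold enrichment: zero control junction RPM")
  }
  out <- data.frame(gene_id = genes, fold_enrichment = unname(fold),
                    stringsAsFactors = FALSE)
  ctrl <- table$condition == "control"
  pooled_c <- sum(rpm[ctrl]); pooled_t <- sum(rpm[!ctrl])
  attr(out, "pooled_fold") <- if (pooled_c > 0) pooled_t / pooled_c else NA_real_
  out
}

#' Ratio of circRNA junction reads to total spliced reads
#'
#' Per gene, the mean over replicates of
#' `backsplice / (backsplice + linear_spliced)` in the given condition;
#' replicates with no spliced reads at all are undefined and excluded from
#' the mean (`NA` when no replicate is defined).
#'
#' @param table junction table.
#' @param condition `"control"` or `"rnaser"`.
#' @return Named numeric vector of ratios in `[0, 1]`, one per gene.
#' @export
junction_ratio <- function(table, condition) {
  sub <- table[table$condition == condition, , drop = FALSE]
  if (!nrow(sub)) stop_param("no libraries for condition ", condition)
  tot <- sub$backsplice_reads + sub$linear_spliced_reads
  r <- ifelse(tot > 0, sub$backsplice_reads / tot, NA_real_)
  vapply(split(r, sub$gene_id), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1L))
}

#' Compare junction-read ratio distributions between conditions
#'
#' Mann-Whitney U test (delegating to [mwu_test()]) plus empirical CDF
#' tables for plotting.
#'
#' @param ratios_a,ratios_b numeric vectors (NAs dropped).
#' @param alternative passed to [mwu_test()].
#' @return List with `U`, `p_value`, `method`, and `cdf_a` / `cdf_b`
#'   (data.frames of sorted values and cumulative fractions).
#' @export
compare_conditions <- function(ratios_a, ratios_b,
                               alternative = "two.sided") {
  a <- ratios_a[!is.na(ratios_a)]; b <- ratios_b[!is.na(ratios_b)]
  res <- mwu_test(a, b, alternative = alternative)
  ecdf_tab <- function(v) {
    v <- sort(v)
    data.frame(value = v, cdf = seq_along(v) / length(v))
  }
  c(res, list(cdf_a = ecdf_tab(a), cdf_b = ecdf_tab(b)))
}
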