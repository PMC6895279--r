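#' Reads Per Kilobase per Million mapped reads (RPKM)
#'
#' `RPKM = count * 1e9 / (length * mapped)`. Vectorized over all arguments.
#'
#' @param count gene read count (>= 0).
#' @param length_nt exonic gene length in nt (> 0).
#' @param mapped total mapped reads in the library (> 0).
#' @return numeric RPKM.
#' @examples
#' compute_rpkm(500, 2000, 1e7)  # 25
#' @export
compute_rpkm <- function(count, length_nt, mapped) {
  if (any(length_nt <= 0)) stop_param("gene length must be > 0")
  if (any(mapped <= 0)) stop_param("library size must be > 0")
  if (any(count < 0)) stop_param("counts must be >= 0")
  count * 1e9 / (length_nt * mapped)
}

#' Flag highly expressed genes by a control-sample RPKM quantile
#'
#' Per replicate, genes at or above the `quantile` (type-7) quantile of the
#' control-sample RPKM distribution are flagged; a gene is retained when
#' flagged in every replicate (intersection across replicates, matching the
#' replicate-agreement convention used for resistance calls). Ties at the
#' threshold are included.
#'
#' @param rpkm genes x samples RPKM matrix (column names are sample ids).
#' @param samples data.frame with `sample_id`, `condition`
#'   (control/rnaser), `replicate`.
#' @param quantile expression quantile (default 0.75 = top 25%).
#' @return List with `highly_expressed` (logical per gene, all replicates)
#'   and `per_replicate` (logical matrix genes x replicates).
#' @export
expression_filter <- function(rpkm, samples, quantile = 0.75) {
  if (is.null(dim(rpkm)) || nrow(rpkm) < 4L) {
    stop_param("need an RPKM matrix with at least 4 genes")
  }
  if (quantile < 0 || quantile > 1) stop_param("quantile must be in [0,1]")
  ctrl <- samples[samples$condition == "control", , drop = FALSE]
  if (!nrow(ctrl)) stop_param("no control samples")
  per_rep <- vapply(seq_len(nrow(ctrl)), function(i) {
    v <- rpkm[, ctrl$sample_id[i]]
    v >= stats::quantile(v, quantile, type = 7, names = FALSE)
  }, logical(nrow(rpkm)))
  colnames(per_rep) <- ctrl$sample_id
  list(highly_expressed = rowSums(!per_rep) == 0L, per_replicate = per_rep)
}

#' Call RNase R resistance from replicate RPKM ratios
#'
#' A gene is resistant iff it is highly expressed and its RNase R/Control
#' RPKM ratio is at or above `ratio_threshold` in every replicate (the
#' threshold is inclusive). Genes with an undefined ratio in any replicate
#' (control RPKM of zero) are skipped with a warning and called `NA`.
#'
#' @param records data.frame with `gene_id`, `highly_expressed`, and one
#'   `ratio_rep<i>` column per replicate.
#' @param ratio_threshold minimum ratio (default 1.0).
#' @return `records` with a logical `resistant` column added.
#' @export
classify_resistant <- function(records, ratio_threshold = 1.0) {
  ratio_cols <- grep("^ratio_rep", names(records), value = TRUE)
  if (!length(ratio_cols)) stop_param("no ratio_rep<i> columns in records")
  if (is.null(records$highly_expressed)) stop_param("records lacks highly_expressed")
  rmat <- as.matrix(records[, ratio_cols, drop = FALSE])
  incomplete <- rowSums(is.na(rmat)) > 0L
  if (any(incomplete)) {
    warning(sum(incomplete), " gene(s) skipped: undefined ratio in >=1 replicate (",
            paste(utils::head(records$gene_id[incomplete], 5L), collapse = ", "),
            if (sum(incomplete) > 5L) ", ..." else "", ")")
  }
  pass <- rowSums(rmat < ratio_threshold) == 0L
  records$resistant <- ifelse(incomplete, NA, records$highly_expressed & pass)
  records
}

#' Spike-in quality control: pairwise log-RPKM correlation
#'
#' Squared Pearson correlation of `log10(RPKM + eps)` between all sample
#' pairs, computed over the shared spike-in species. Requires at least three
#' species; fewer yields `NULL` with a warning.
#'
#' @param spikein_rpkm species x samples RPKM matrix.
#' @param eps pseudo-RPKM added before the log.
#' @return Symmetric matrix of r-squared values (class `spikein_qc`), unit
#'   diagonal, or `NULL`.
#' @export
spikein_qc <- function(spikein_rpkm, eps = 0.01) {
  if (is.null(dim(spikein_rpkm)) || nrow(spikein_rpkm) < 3L) {
    warning("spike-in QC skipped: fewer than 3 shared species")
    return(NULL)
  }
  lg <- log10(spikein_rpkm + eps)
  r2 <- stats::cor(lg)^2
  structure(r2, class = c("spikein_qc", class(r2)))
}

#' Quantify a library set: RPKM, ratios, expression filter, resistance
#'
#' Computes gene counts as summed per-base coverage over the gene's exon
#' union (all transcripts of the gene, circles included), library sizes as
#' total gene counts plus spike-in counts, RPKM per sample, per-replicate
#' RNase R/Control ratios (replicate i treated over replicate i control),
#' the top-quantile expression filter and the resistance call.
#'
#' @param libs a `sim_libraries` object, or a compatible list with
#'   `coverage`, `samples`, `genes`, `transcripts` and optionally
#'   `spikein_counts`.
#' @param quantile expression quantile (default 0.75).
#' @param ratio_threshold resistance threshold (default 1).
#' @return An `expression_table` data.frame: `gene_id`, `length`,
#'   `rpkm_<sample>` columns, `ratio_rep<i>` columns, `highly_expressed`,
#'   `resistant`.
#' @export
quantify_libraries <- function(libs, quantile = 0.75, ratio_threshold = 1.0) {
  genes <- libs$genes
  samples <- libs$samples
  ngene <- nrow(genes)
  if (!ngene) stop_param("empty gene table")

  union_idx <- vector("list", ngene)
  for (tm in libs$transcripts) {
    g <- match(tm$gene_id, genes$gene_id)
    if (is.na(g)) next
    off <- tx_genomic_positions(tm) - genes$start[g] + 1L
    union_idx[[g]] <- union(union_idx[[g]], off)
  }
  union_len <- vapply(union_idx, length, integer(1L))
  if (any(union_len == 0L)) stop_param("gene(s) without exons in annotation")

  counts <- matrix(0, nrow = ngene, ncol = nrow(samples),
                   dimnames = list(genes$gene_id, samples$sample_id))
  for (g in seq_len(ngene)) {
    counts[g, ] <- colSums(libs$coverage[[genes$gene_id[g]]][union_idx[[g]], , drop = FALSE])
  }
  mapped <- colSums(counts)
  if (!is.null(libs$spikein_counts)) mapped <- mapped + colSums(libs$spikein_counts)
  rpkm <- compute_rpkm(counts, matrix(union_len, ngene, ncol(counts)),
                       matrix(mapped, ngene, ncol(counts), byrow = TRUE))

  ef <- expression_filter(rpkm, samples, quantile = quantile)

  reps <- sort(unique(samples$replicate))
  ratios <- vapply(reps, function(r) {
    cs <- samples$sample_id[samples$condition == "control" & samples$replicate == r]
    ts <- samples$sample_id[samples$condition == "rnaser" & samples$replicate == r]
    if (length(cs) != 1L || length(ts) != 1L) {
      stop_param("need exactly one control and one rnaser sample for replicate ", r)
    }
    ifelse(rpkm[, cs] > 0, rpkm[, ts] / rpkm[, cs], NA_real_)
  }, numeric(ngene))
  colnames(ratios) <- paste0("ratio_rep", reps)

  out <- data.frame(gene_id = genes$gene_id, length = union_len,
                    stringsAsFactors = FALSE)
  rpkm_df <- as.data.frame(rpkm, check.names = FALSE)
  names(rpkm_df) <- paste0("rpkm_", names(rpkm_df))
  out <- cbind(out, rpkm_df, as.data.frame(ratios, check.names = FALSE))
  out$highly_expressed <- ef$highly_expressed
  out <- classify_resistant(out, ratio_threshold = ratio_threshold)
  rownames(out) <- NULL
  class(out) <- c("expression_table", class(out))
  out
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %d genes; %d highly expressed; %d resistant\n",
              nrow(x), sum(x$highly_expressed, na.rm = TRUE),
              sum(x$resistant, na.rm = TRUE)))
  NextMethod()
}
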