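# File-format boundary: bedGraph / GTF / BED / FASTA / TSV readers and
# writers. All internal coordinates are 0-based half-open; GTF is 1-based
# closed and converted exactly here.

#' Write a simulated library set to a run directory
#'
#' Emits one 4-column bedGraph per sample (runs of zero coverage omitted), a
#' GTF annotation (transcript + exon features with `gene_id`,
#' `transcript_id`, `topology`, `end_structure`, `gene_class` attributes), the
#' genome FASTA, a BED6 of planted G4 elements, and TSV tables for junction
#' counts, spike-ins, samples and ground truth. Files round-trip losslessly
#' through [read_coverage()] / [read_annotation()] / [read_fasta()].
#'
#' @param libs a `sim_libraries` object.
#' @param outdir output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_tracks <- function(libs, outdir) {
  stopifnot(inherits(libs, "sim_libraries"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop_param("cannot create output directory: ", outdir)
  paths <- c()
  tsv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }

  # per-sample coverage bedGraph
  for (s in libs$samples$sample_id) {
    grl <- list()
    for (g in seq_len(nrow(libs$genes))) {
      v <- libs$coverage[[g]][, s]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values != 0
      if (!any(keep)) next
      grl[[length(grl) + 1L]] <- GenomicRanges::GRanges(
        seqnames = libs$genes$chrom[g],
        ranges = IRanges::IRanges(start = libs$genes$start[g] + starts[keep] + 1L,
                                  end = libs$genes$start[g] + ends[keep]),
        score = r$values[keep]
      )
    }
    gr <- if (length(grl)) do.call(c, grl) else
      GenomicRanges::GRanges(score = numeric(0))
    p <- file.path(outdir, paste0("coverage_", s, ".bedGraph"))
    rtracklayer::export(gr, p, format = "bedGraph")
    paths[paste0("coverage_", s)] <- p
  }

  # annotation GTF (1-based closed at this boundary)
  feat <- list()
  for (tm in libs$transcripts) {
    cls <- libs$genes$class[match(tm$gene_id, libs$genes$gene_id)]
    n <- nrow(tm$exons)
    feat[[length(feat) + 1L]] <- data.frame(
      chrom = tm$chrom,
      start = c(min(tm$exons[, 1L]), tm$exons[, 1L]) + 1L,
      end = c(max(tm$exons[, 2L]), tm$exons[, 2L]),
      strand = tm$strand,
      type = c("transcript", rep("exon", n)),
      gene_id = tm$gene_id, transcript_id = tm$transcript_id,
      topology = tm$topology, end_structure = tm$end_structure,
      gene_class = if (is.na(cls)) "unknown" else cls,
      stringsAsFactors = FALSE
    )
  }
  feat <- do.call(rbind, feat)
  gr <- GenomicRanges::GRanges(
    seqnames = feat$chrom,
    ranges = IRanges::IRanges(start = feat$start, end = feat$end),
    strand = feat$strand, type = feat$type, gene_id = feat$gene_id,
    transcript_id = feat$transcript_id, topology = feat$topology,
    end_structure = feat$end_structure, gene_class = feat$gene_class
  )
  paths["annotation"] <- file.path(outdir, "annotation.gtf")
  rtracklayer::export(gr, paths["annotation"], format = "gtf")

  # genome FASTA
  paths["genome"] <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(libs$genome, paths["genome"])

  # planted G4 elements as BED6
  g4 <- libs$genes[!is.na(libs$genes$g4_genomic), , drop = FALSE]
  mlen <- nchar(G4_MOTIF)
  g4gr <- GenomicRanges::GRanges(
    seqnames = g4$chrom,
    ranges = IRanges::IRanges(
      start = ifelse(g4$strand == "+", g4$g4_genomic - mlen + 1L, g4$g4_genomic) + 1L,
      width = mlen
    ),
    strand = g4$strand
  )
  names(g4gr) <- if (nrow(g4)) paste0("G4_", g4$gene_id) else character(0)
  paths["g4_annotation"] <- file.path(outdir, "g4_annotation.bed")
  rtracklayer::export(g4gr, paths["g4_annotation"], format = "bed")

  paths["junctions"] <- tsv(libs$junctions, "junctions.tsv")
  paths["truth"] <- tsv(libs$truth, "truth.tsv")
  paths["samples"] <- tsv(libs$samples, "samples.tsv")
  paths["spikeins"] <- tsv(
    cbind(libs$spikeins,
          as.data.frame(libs$spikein_counts, check.names = FALSE)),
    "spikeins.tsv"
  )
  invisible(paths)
}

#' Read a GTF annotation into transcript models
#'
#' Accepts GTF with `transcript` and `exon` features carrying `gene_id` and
#' `transcript_id` attributes; optional `topology`, `end_structure` and
#' `gene_class` attributes (as written by [write_tracks()]) are honoured,
#' defaulting to linear/free/unknown. 1-based closed GTF intervals are
#' converted to the internal 0-based half-open convention.
#'
#' @param path GTF file.
#' @return List with `transcripts` (named list of transcript models) and
#'   `genes` (data.frame with gene span, class, representative linear
#'   transcript and its last exon — for multiple linear isoforms the longest
#'   last exon wins).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop_param("annotation file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$transcript_id) || is.null(md$gene_id)) {
    stop_param("GTF must carry gene_id and transcript_id attributes: ", path)
  }
  ex <- gr[md$type == "exon"]
  if (!length(ex)) stop_param("no exon features in ", path)
  exd <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = S4Vectors::mcols(ex)$gene_id,
    transcript_id = S4Vectors::mcols(ex)$transcript_id,
    topology = S4Vectors::mcols(ex)$topology %||% NA_character_,
    end_structure = S4Vectors::mcols(ex)$end_structure %||% NA_character_,
    gene_class = S4Vectors::mcols(ex)$gene_class %||% NA_character_,
    stringsAsFactors = FALSE
  )
  transcripts <- list()
  for (tid in unique(exd$transcript_id)) {
    rows <- exd[exd$transcript_id == tid, , drop = FALSE]
    if (length(unique(rows$strand)) != 1L || !all(rows$strand %in% c("+", "-"))) {
      stop_param("transcript ", tid, ": inconsistent or missing strand")
    }
    transcripts[[tid]] <- new_transcript_model(
      transcript_id = tid, gene_id = rows$gene_id[1L], chrom = rows$chrom[1L],
      strand = rows$strand[1L],
      exons = as.matrix(rows[order(rows$start), c("start", "end")]),
      topology = if (is.na(rows$topology[1L])) "linear" else rows$topology[1L],
      end_structure = if (is.na(rows$end_structure[1L])) "free" else rows$end_structure[1L]
    )
    attr(transcripts[[tid]], "gene_class") <- rows$gene_class[1L]
  }

  gene_ids <- unique(exd$gene_id)
  gene_rows <- lapply(gene_ids, function(gid) {
    tms <- Filter(function(tm) tm$gene_id == gid, transcripts)
    lin <- Filter(function(tm) tm$topology == "linear", tms)
    circ <- Filter(function(tm) tm$topology != "linear", tms)
    rep_tm <- NULL; le <- c(NA_integer_, NA_integer_)
    if (length(lin)) {
      # representative = linear transcript with the longest last exon
      lens <- vapply(lin, function(tm) {
        i <- if (tm$strand == "+") nrow(tm$exons) else 1L
        tm$exons[i, 2L] - tm$exons[i, 1L]
      }, numeric(1L))
      rep_tm <- lin[[which.max(lens)]]
      i <- if (rep_tm$strand == "+") nrow(rep_tm$exons) else 1L
      le <- rep_tm$exons[i, ]
    }
    all_ex <- do.call(rbind, lapply(tms, function(tm) tm$exons))
    data.frame(
      gene_id = gid,
      class = attr(tms[[1L]], "gene_class") %||% NA_character_,
      chrom = tms[[1L]]$chrom, strand = tms[[1L]]$strand,
      start = min(all_ex[, 1L]), end = max(all_ex[, 2L]),
      last_exon_start = le[1L], last_exon_end = le[2L],
      transcript_id = if (is.null(rep_tm)) NA_character_ else rep_tm$transcript_id,
      circle_id = if (length(circ)) circ[[1L]]$transcript_id else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  genes <- do.call(rbind, gene_rows)
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  list(transcripts = transcripts, genes = genes)
}

#' Read a bedGraph coverage track into per-gene vectors
#'
#' Positions absent from the bedGraph are read as zero coverage.
#'
#' @param path bedGraph file (4 columns, 0-based half-open).
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end` (as from
#'   [read_annotation()]).
#' @return Named list of numeric vectors, one per gene, covering
#'   `[start, end)` of the gene span.
#' @export
read_coverage <- function(path, genes) {
  if (!file.exists(path)) stop_param("coverage file not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  cov <- GenomicRanges::coverage(gr, weight = "score")
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene_id
  for (g in seq_len(nrow(genes))) {
    chrom <- genes$chrom[g]
    span <- genes$end[g] - genes$start[g]
    v <- numeric(span)
    if (chrom %in% names(cov)) {
      r <- cov[[chrom]]
      n_avail <- min(genes$end[g], length(r)) - genes$start[g]
      if (n_avail > 0) {
        v[seq_len(n_avail)] <-
          as.numeric(r[(genes$start[g] + 1L):(genes$start[g] + n_avail)])
      }
    }
    out[[g]] <- v
  }
  out
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return A \code{Biostrings::DNAStringSet}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_param("FASTA file not found: ", path)
  Biostrings::readDNAStringSet(path)
}

#' Read a junction-count table
#'
#' @param path TSV with columns `gene_id`, `sample_id`, `condition`,
#'   `replicate`, `backsplice_reads`, `linear_spliced_reads`,
#'   `library_mapped_reads`.
#' @return data.frame.
#' @export
read_junctions <- function(path) {
  if (!file.exists(path)) stop_param("junction table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "sample_id", "condition", "replicate",
            "backsplice_reads", "linear_spliced_reads", "library_mapped_reads")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_param("junction table lacks columns: ", paste(missing, collapse = ", "))
  }
  df
}

#' Read a BED6 file of G4 (or other) intervals
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `name`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_param("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(names(gr))) names(gr) else
      S4Vectors::mcols(gr)$name %||% NA_character_,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}
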