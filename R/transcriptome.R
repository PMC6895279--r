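#' Transcript classes emulated by the synthetic transcriptome
#'
#' @format Character vector of the five transcript classes:
#' \describe{
#'   \item{plain_mRNA}{polyadenylated mRNA with a free single-stranded 3'
#'     overhang; fully degraded by RNase R.}
#'   \item{g4_mRNA}{polyadenylated mRNA carrying an internal G-quadruplex
#'     element at which RNase R stalls in K+ buffer.}
#'   \item{structured_end}{RNA with a structured 3' terminus and no overhang
#'     (snRNA/histone-mRNA-like); resistant unless A-tailed.}
#'   \item{circRNA_host}{gene producing a linear mRNA plus an exonic circular
#'     RNA from its middle exon.}
#'   \item{ciRNA_host}{gene producing a linear mRNA plus a circular intronic
#'     RNA (stable lariat) from its intron.}
#' }
#' @export
TRANSCRIPT_CLASSES <- c(
  "plain_mRNA", "g4_mRNA", "structured_end", "circRNA_host", "ciRNA_host"
)

# Canonical quadruplex-forming sequence planted into g4_mRNA transcripts
# (telomeric-repeat-like; four G3 runs, loops of 3).
G4_MOTIF <- "GGGTTAGGGTTAGGGTTAGGG"

new_transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                                 topology = "linear", end_structure = "free",
                                 overhang_len = 0L, g4_elements = NULL,
                                 abundance = 1) {
  stopifnot(strand %in% c("+", "-"))
  stopifnot(topology %in% c("linear", "circular_exonic", "circular_intronic"))
  stopifnot(end_structure %in% c("free", "structured"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 2L] <= exons[, 1L])) {
    stop_param("transcript ", transcript_id, ": empty or inverted exon")
  }
  if (nrow(exons) > 1L) {
    o <- order(exons[, 1L])
    exons <- exons[o, , drop = FALSE]
    if (any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
      stop_param("transcript ", transcript_id, ": overlapping exons")
    }
  }
  if (overhang_len < 0L) stop_param("overhang_len must be >= 0")
  if (abundance < 0) stop_param("abundance must be non-negative")
  if (is.null(g4_elements)) {
    g4_elements <- data.frame(
      tx_position = integer(), stall_prob_K = numeric(),
      stall_prob_Na = numeric(), stall_prob_Li = numeric()
    )
  }
  L <- sum(exons[, 2L] - exons[, 1L])
  if (nrow(g4_elements)) {
    with(g4_elements, {
      if (any(tx_position < 0L | tx_position >= L)) {
        stop_param("G4 tx_position outside transcript")
      }
      probs <- c(stall_prob_K, stall_prob_Na, stall_prob_Li)
      if (any(probs < 0 | probs > 1)) stop_param("stall probabilities must be in [0,1]")
      if (any(stall_prob_K < stall_prob_Li)) {
        stop_param("cation asymmetry violated: stall_prob_K < stall_prob_Li")
      }
    })
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons, topology = topology,
         end_structure = end_structure, overhang_len = as.integer(overhang_len),
         g4_elements = g4_elements, abundance = abundance),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s:%s %d exon(s), %d nt, %s/%s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              tx_length(x), x$topology, x$end_structure))
  invisible(x)
}

#' Generate a synthetic transcriptome with known RNase R susceptibility
#'
#' Builds `n_genes` gene models on a single synthetic chromosome, assigns each
#' gene one of the five classes in [TRANSCRIPT_CLASSES] according to
#' `class_mix`, and generates a matching genome sequence. `g4_mRNA` genes carry
#' a planted quadruplex-forming G-rich (QGRS) motif in their last exon, with
#' cation-specific stalling probabilities. `circRNA_host` / `ciRNA_host` genes
#' additionally produce a circular transcript (middle exon or intronic
#' interval) at `circle_fraction` of the host abundance. A set of spike-in
#' species (ERCC-like, not placed on the genome) is included for QC.
#'
#' Gene abundances are log-normal (sdlog 1); genes are separated by
#' intergenic gaps so that windows around 3'-end features never leave the
#' chromosome. All coordinates are 0-based half-open.
#'
#' @param n_genes number of genes (>= 1).
#' @param class_mix named numeric vector of proportions over
#'   [TRANSCRIPT_CLASSES]; must be non-negative and sum to 1.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param n_spikeins number of spike-in species.
#' @param stall_prob cation-specific stalling probabilities for planted G4
#'   elements, named `K`, `Na`, `Li` (K >= Li required).
#' @param circle_fraction circle abundance as a fraction of host abundance.
#' @param gap intergenic gap in nt.
#' @return An object of class `sim_transcriptome`: list with `transcripts`
#'   (named list of transcript models), `genes` (data.frame of gene metadata
#'   incl. class and last-exon coordinates), `genome`
#'   (\code{Biostrings::DNAStringSet}), `spikeins` (data.frame), `seed`.
#' @examples
#' tx <- build_transcriptome(12, seed = 1)
#' tx
#' @export
build_transcriptome <- function(n_genes,
                                class_mix = c(plain_mRNA = 0.40, g4_mRNA = 0.35,
                                              structured_end = 0.10,
                                              circRNA_host = 0.10,
                                              ciRNA_host = 0.05),
                                seed = 1L,
                                n_spikeins = 20L,
                                stall_prob = c(K = 0.9, Na = 0.1, Li = 0.05),
                                circle_fraction = 0.5,
                                gap = 1000L) {
  if (n_genes < 1L) stop_param("n_genes must be >= 1")
  if (is.null(names(class_mix))) names(class_mix) <- TRANSCRIPT_CLASSES[seq_along(class_mix)]
  if (!all(names(class_mix) %in% TRANSCRIPT_CLASSES)) {
    stop_param("unknown class in class_mix: ",
               paste(setdiff(names(class_mix), TRANSCRIPT_CLASSES), collapse = ", "))
  }
  if (any(class_mix < 0)) stop_param("class_mix proportions must be non-negative")
  if (abs(sum(class_mix) - 1) > 1e-9) stop_param("class_mix must sum to 1")
  mix <- stats::setNames(numeric(length(TRANSCRIPT_CLASSES)), TRANSCRIPT_CLASSES)
  mix[names(class_mix)] <- class_mix

  with_seed(seed, {
    cls <- sample(TRANSCRIPT_CLASSES, n_genes, replace = TRUE, prob = mix)
    chrom <- "chrS"
    transcripts <- list()
    gene_rows <- vector("list", n_genes)
    g4_plants <- list()   # genomic planting instructions, applied post hoc
    cursor <- 0L

    for (i in seq_len(n_genes)) {
      gid <- sprintf("G%04d", i)
      strand <- sample(c("+", "-"), 1L)
      abundance <- stats::rlnorm(1L, meanlog = 0, sdlog = 1)
      klass <- cls[i]

      # exon/intron widths in transcript (5'->3') order
      if (klass %in% c("plain_mRNA", "g4_mRNA")) {
        exw <- c(round(runif(1, 200, 400)), round(runif(1, 800, 1200)))
        inw <- round(runif(1, 200, 400))
      } else if (klass == "structured_end") {
        exw <- round(runif(1, 150, 300))
        inw <- integer(0)
      } else if (klass == "circRNA_host") {
        exw <- c(round(runif(1, 200, 400)), round(runif(1, 300, 500)),
                 round(runif(1, 500, 900)))
        inw <- round(runif(2, 200, 400))
      } else { # ciRNA_host
        exw <- c(round(runif(1, 200, 400)), round(runif(1, 800, 1200)))
        inw <- round(runif(1, 600, 1000))
      }
      exw <- as.integer(exw); inw <- as.integer(inw)
      span <- sum(exw) + sum(inw)
      gstart <- cursor + as.integer(gap)
      cursor <- gstart + span

      # genomic exon layout: transcript order for +, reversed for -
      exw_g <- if (strand == "+") exw else rev(exw)
      inw_g <- if (strand == "+") inw else rev(inw)
      starts <- integer(length(exw_g)); ends <- integer(length(exw_g))
      pos <- gstart
      for (j in seq_along(exw_g)) {
        starts[j] <- pos
        ends[j] <- pos + exw_g[j]
        pos <- ends[j] + if (j < length(exw_g)) inw_g[j] else 0L
      }
      exons <- cbind(starts, ends)

      g4 <- NULL
      if (klass == "g4_mRNA") {
        # plant one element in the last exon, away from both edges
        last_w <- exw[length(exw)]
        off <- as.integer(round(runif(1, 0.35, 0.65) * last_w))
        off <- max(150L, min(last_w - 150L, off))
        tx_pos <- sum(exw[-length(exw)]) + off   # 3'-most base, 0-based
        g4 <- data.frame(tx_position = tx_pos,
                         stall_prob_K = unname(stall_prob["K"]),
                         stall_prob_Na = unname(stall_prob["Na"]),
                         stall_prob_Li = unname(stall_prob["Li"]))
      }

      tm <- new_transcript_model(
        transcript_id = paste0(gid, ".t1"), gene_id = gid, chrom = chrom,
        strand = strand, exons = exons, topology = "linear",
        end_structure = if (klass == "structured_end") "structured" else "free",
        overhang_len = if (klass == "structured_end") 0L else 30L,
        g4_elements = g4, abundance = abundance
      )
      transcripts[[tm$transcript_id]] <- tm

      if (klass == "g4_mRNA") {
        gp <- tx_genomic_positions(tm)
        motif_tx <- (g4$tx_position - nchar(G4_MOTIF) + 1L):g4$tx_position
        g4_plants[[length(g4_plants) + 1L]] <- list(
          gene_id = gid, strand = strand,
          gpos = gp[motif_tx + 1L],             # genomic pos of each motif base
          g4_genomic = gp[g4$tx_position + 1L]  # genomic pos of the 3'-most base
        )
      }

      circle_id <- NA_character_
      if (klass == "circRNA_host") {
        mid <- if (strand == "+") 2L else 2L    # middle of 3 either way
        ctm <- new_transcript_model(
          transcript_id = paste0(gid, ".circ"), gene_id = gid, chrom = chrom,
          strand = strand, exons = exons[mid, , drop = FALSE],
          topology = "circular_exonic", abundance = circle_fraction * abundance
        )
        transcripts[[ctm$transcript_id]] <- ctm
        circle_id <- ctm$transcript_id
      } else if (klass == "ciRNA_host") {
        # intronic circle: interval inside the single intron
        intron <- c(exons[1L, 2L], exons[2L, 1L])
        clen <- as.integer(round(runif(1, 300, 500)))
        cstart <- intron[1L] + 100L
        ctm <- new_transcript_model(
          transcript_id = paste0(gid, ".ciRNA"), gene_id = gid, chrom = chrom,
          strand = strand, exons = c(cstart, cstart + clen),
          topology = "circular_intronic", abundance = circle_fraction * abundance
        )
        transcripts[[ctm$transcript_id]] <- ctm
        circle_id <- ctm$transcript_id
      }

      last_ex <- if (strand == "+") nrow(exons) else 1L
      gene_rows[[i]] <- data.frame(
        gene_id = gid, class = klass, chrom = chrom, strand = strand,
        start = gstart, end = gstart + span,
        last_exon_start = exons[last_ex, 1L], last_exon_end = exons[last_ex, 2L],
        transcript_id = tm$transcript_id, circle_id = circle_id,
        abundance = abundance, stringsAsFactors = FALSE
      )
    }

    genes <- do.call(rbind, gene_rows)
    chrom_len <- cursor + as.integer(gap)

    # genome: random background, then plant the G4 motifs (strand-aware)
    chars <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
    motif_chars <- strsplit(G4_MOTIF, "")[[1L]]
    for (pl in g4_plants) {
      put <- if (pl$strand == "+") motif_chars else unname(DNA_COMPLEMENT[motif_chars])
      chars[pl$gpos + 1L] <- put   # gpos runs in transcript order (descending on -)
    }
    genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
    names(genome) <- chrom

    genes$g4_genomic <- NA_integer_
    genes$g4_tx <- NA_integer_
    for (pl in g4_plants) {
      genes$g4_genomic[genes$gene_id == pl$gene_id] <- pl$g4_genomic
    }
    for (tm in transcripts) {
      if (nrow(tm$g4_elements)) {
        genes$g4_tx[genes$gene_id == tm$gene_id] <- tm$g4_elements$tx_position[1L]
      }
    }

    spikeins <- data.frame(
      spikein_id = sprintf("SPIKE%02d", seq_len(n_spikeins)),
      length = as.integer(round(runif(n_spikeins, 250, 2000))),
      abundance = 10^runif(n_spikeins, -1, 1),
      stringsAsFactors = FALSE
    )

    structure(
      list(transcripts = transcripts, genes = genes, genome = genome,
           spikeins = spikeins, seed = seed,
           params = list(class_mix = mix, stall_prob = stall_prob,
                         circle_fraction = circle_fraction, gap = gap)),
      class = "sim_transcriptome"
    )
  })
}

#' @export
print.sim_transcriptome <- function(x, ...) {
  cat(sprintf("<sim_transcriptome> %d genes, %d transcripts on %s (%d nt), %d spike-ins\n",
              nrow(x$genes), length(x$transcripts), names(x$genome)[1L],
              Biostrings::width(x$genome)[1L], nrow(x$spikeins)))
  print(table(x$genes$class))
  invisible(x)
}
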