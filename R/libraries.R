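#' Render paired control/RNase R sequencing libraries from a transcriptome
#'
#' Digests every transcript under the control and treated configurations and
#' renders per-base coverage, splice-junction counts and spike-in counts with
#' Poisson noise, independently per replicate. Coverage is simulated at base
#' resolution directly (expected coverage = `depth` times surviving fragment
#' weight at that base); read placement is intentionally not modelled.
#'
#' The returned object also carries a ground-truth table: each gene's expected
#' RNase R/Control RPKM ratio (computed from the noise-free expected counts
#' with the same exon-union counting and library normalization the analysis
#' uses), the implied resistance label, and the planted/realized G4 stalling
#' coordinates — the reference against which the downstream detectors are
#' validated.
#'
#' @param tx a `sim_transcriptome` from [build_transcriptome()].
#' @param control_cfg digestion config of the mock-treated libraries
#'   (default [control_config()]).
#' @param rnaser_cfg digestion config of the RNase R libraries (default K+
#'   buffer, 90 min).
#' @param depth expected reads (coverage units) per unit abundance per base.
#' @param n_replicates biological replicates per condition (>= 2; the
#'   analysis requires replicate agreement).
#' @param junction_factor expected junction reads per unit fragment weight
#'   relative to `depth`.
#' @param noise `"poisson"` for sampled libraries, `"none"` for noise-free
#'   expected values (diagnostic mode; counts are then rounded expectations
#'   and coverage is real-valued).
#' @param quantile_he expression quantile defining "highly expressed" in the
#'   truth labels (matches the analysis default).
#' @param ratio_threshold resistance ratio threshold in the truth labels.
#' @param seed integer seed.
#' @return A `sim_libraries` object: `samples` (data.frame), `coverage`
#'   (named list of per-gene base-by-sample matrices over the gene span),
#'   `junctions` (long data.frame incl. `library_mapped_reads`),
#'   `spikein_counts` / `spikein_rpkm` (matrices), `truth` (data.frame),
#'   `genes`, `transcripts`, `params`.
#' @export
render_libraries <- function(tx,
                             control_cfg = control_config(),
                             rnaser_cfg = digestion_config(incubation_min = 90),
                             depth = 100, n_replicates = 2L,
                             junction_factor = 0.5,
                             noise = c("poisson", "none"),
                             quantile_he = 0.75, ratio_threshold = 1,
                             seed = 1L) {
  stopifnot(inherits(tx, "sim_transcriptome"))
  noise <- match.arg(noise)
  if (depth <= 0) stop_param("depth must be > 0")
  if (n_replicates < 2L) stop_param("n_replicates must be >= 2 (replicate agreement is required downstream)")

  conditions <- c("control", "rnaser")
  cfgs <- list(control = control_cfg, rnaser = rnaser_cfg)
  samples <- data.frame(
    sample_id = as.vector(t(outer(conditions, seq_len(n_replicates),
                                  function(c, r) paste0(c, "_rep", r)))),
    condition = rep(conditions, each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = 2L),
    stringsAsFactors = FALSE
  )

  genes <- tx$genes
  ngene <- nrow(genes)

  with_seed(seed, {
    # --- digest every transcript once per condition -----------------------
    fps <- list(control = list(), rnaser = list())
    for (cond in conditions) {
      cfg <- cfgs[[cond]]
      cfg$seed <- NULL   # randomness flows from the render seed
      for (tm in tx$transcripts) {
        fps[[cond]][[tm$transcript_id]] <- simulate_digestion(tm, cfg)
      }
    }

    # --- expected per-base coverage over each gene span -------------------
    exp_cov <- vector("list", ngene); names(exp_cov) <- genes$gene_id
    union_idx <- vector("list", ngene); names(union_idx) <- genes$gene_id
    for (g in seq_len(ngene)) {
      span <- genes$end[g] - genes$start[g]
      exp_cov[[g]] <- matrix(0, nrow = span, ncol = 2L,
                             dimnames = list(NULL, conditions))
    }
    lin_w <- matrix(0, nrow = ngene, ncol = 2L, dimnames = list(genes$gene_id, conditions))
    back_w <- matrix(0, nrow = ngene, ncol = 2L, dimnames = list(genes$gene_id, conditions))

    for (tm in tx$transcripts) {
      g <- match(tm$gene_id, genes$gene_id)
      gp <- tx_genomic_positions(tm)
      off <- gp - genes$start[g] + 1L
      union_idx[[g]] <- union(union_idx[[g]], off)
      k <- nrow(tm$exons)
      jx <- if (tm$topology == "linear" && k > 1L) {
        w <- tm$exons[, 2L] - tm$exons[, 1L]
        worder <- if (tm$strand == "+") w else rev(w)
        cumsum(worder)[seq_len(k - 1L)]   # junction tx coordinates
      } else integer(0)
      for (cond in conditions) {
        fr <- fps[[cond]][[tm$transcript_id]]$fragments
        for (i in seq_len(nrow(fr))) {
          idx <- off[(fr$tx_start[i] + 1L):fr$tx_end[i]]
          exp_cov[[g]][idx, cond] <- exp_cov[[g]][idx, cond] + fr$weight[i]
        }
        if (tm$topology != "linear") {
          back_w[g, cond] <- back_w[g, cond] + sum(fr$weight)
        } else if (length(jx)) {
          for (cj in jx) {
            lin_w[g, cond] <- lin_w[g, cond] + sum(fr$weight[fr$tx_end > cj])
          }
        }
      }
    }

    # --- sample per-replicate coverage, junction and spike-in counts ------
    draw <- function(lambda) {
      if (noise == "poisson") stats::rpois(length(lambda), lambda) else lambda
    }
    draw_int <- function(lambda) {
      if (noise == "poisson") stats::rpois(length(lambda), lambda) else round(lambda)
    }

    coverage <- vector("list", ngene); names(coverage) <- genes$gene_id
    for (g in seq_len(ngene)) {
      m <- matrix(0, nrow = nrow(exp_cov[[g]]), ncol = nrow(samples),
                  dimnames = list(NULL, samples$sample_id))
      for (s in seq_len(nrow(samples))) {
        m[, s] <- draw(depth * exp_cov[[g]][, samples$condition[s]])
      }
      coverage[[g]] <- m
    }

    junctions <- do.call(rbind, lapply(seq_len(nrow(samples)), function(s) {
      cond <- samples$condition[s]
      data.frame(
        gene_id = genes$gene_id, sample_id = samples$sample_id[s],
        condition = cond, replicate = samples$replicate[s],
        backsplice_reads = draw_int(depth * junction_factor * back_w[, cond]),
        linear_spliced_reads = draw_int(depth * junction_factor * lin_w[, cond]),
        stringsAsFactors = FALSE
      )
    }))

    spike_lambda <- depth * tx$spikeins$abundance * tx$spikeins$length * 0.01
    spikein_counts <- matrix(0, nrow = nrow(tx$spikeins), ncol = nrow(samples),
                             dimnames = list(tx$spikeins$spikein_id, samples$sample_id))
    for (s in seq_len(nrow(samples))) spikein_counts[, s] <- draw_int(spike_lambda)

    # --- library sizes (gene exon-union counts + spike-ins) ---------------
    gene_counts <- matrix(0, nrow = ngene, ncol = nrow(samples),
                          dimnames = list(genes$gene_id, samples$sample_id))
    for (g in seq_len(ngene)) {
      gene_counts[g, ] <- colSums(coverage[[g]][union_idx[[g]], , drop = FALSE])
    }
    mapped <- colSums(gene_counts) + colSums(spikein_counts)
    junctions$library_mapped_reads <- mapped[junctions$sample_id]

    spikein_rpkm <- sweep(
      spikein_counts * 1e9 / tx$spikeins$length, 2L, mapped, "/"
    )

    # --- ground truth from the noise-free expectations --------------------
    union_len <- vapply(union_idx, length, integer(1L))
    cnt_exp <- matrix(
      vapply(conditions, function(cond) {
        vapply(seq_len(ngene),
               function(g) depth * sum(exp_cov[[g]][union_idx[[g]], cond]),
               numeric(1L))
      }, numeric(ngene)),
      nrow = ngene, dimnames = list(genes$gene_id, conditions)
    )
    mapped_exp <- colSums(cnt_exp) + sum(if (noise == "poisson") spike_lambda else round(spike_lambda))
    rpkm_exp <- t(t(cnt_exp * 1e9 / union_len) / mapped_exp)
    he_thr <- stats::quantile(rpkm_exp[, "control"], quantile_he, type = 7, names = FALSE)
    he_exp <- rpkm_exp[, "control"] >= he_thr
    ratio_exp <- ifelse(rpkm_exp[, "control"] > 0,
                        rpkm_exp[, "rnaser"] / rpkm_exp[, "control"], NA_real_)

    lin_ids <- genes$transcript_id
    survival <- vapply(lin_ids, function(id) fps$rnaser[[id]]$survival, numeric(1L))
    stall_tx <- vapply(seq_len(ngene), function(g) {
      se <- fps$rnaser[[lin_ids[g]]]$stall_ends
      if (length(se) && !all(is.na(se))) se[which(!is.na(se))[1L]] else NA_integer_
    }, integer(1L))
    stall_genomic <- vapply(seq_len(ngene), function(g) {
      if (is.na(stall_tx[g])) return(NA_integer_)
      gp <- tx_genomic_positions(tx$transcripts[[lin_ids[g]]])
      gp[stall_tx[g]]   # genomic position of the last covered base
    }, integer(1L))

    truth <- data.frame(
      gene_id = genes$gene_id, class = genes$class, strand = genes$strand,
      circle = !is.na(genes$circle_id),
      survival = survival,
      expected_ratio = ratio_exp,
      highly_expressed = he_exp,
      resistant = he_exp & !is.na(ratio_exp) & ratio_exp >= ratio_threshold,
      g4_tx = genes$g4_tx, g4_genomic = genes$g4_genomic,
      stall_tx = stall_tx, stall_genomic = stall_genomic,
      stringsAsFactors = FALSE
    )
    rownames(truth) <- NULL

    structure(
      list(samples = samples, coverage = coverage, junctions = junctions,
           spikein_counts = spikein_counts, spikein_rpkm = spikein_rpkm,
           spikeins = tx$spikeins, truth = truth, genes = genes,
           transcripts = tx$transcripts, genome = tx$genome,
           params = list(depth = depth, n_replicates = n_replicates,
                         junction_factor = junction_factor, noise = noise,
                         control_cfg = control_cfg, rnaser_cfg = rnaser_cfg,
                         seed = seed)),
      class = "sim_libraries"
    )
  })
}

#' @export
print.sim_libraries <- function(x, ...) {
  cat(sprintf("<sim_libraries> %d genes x %d samples (%s noise, depth %g)\n",
              length(x$coverage), nrow(x$samples), x$params$noise, x$params$depth))
  cat("  conditions:", paste(unique(x$samples$condition), collapse = ", "),
      sprintf("(%d replicates)\n", x$params$n_replicates))
  cat(sprintf("  truth: %d resistant genes, %d with planted G4\n",
              sum(x$truth$resistant, na.rm = TRUE), sum(!is.na(x$truth$g4_tx))))
  invisible(x)
}
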