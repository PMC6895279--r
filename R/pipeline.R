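# End-to-end orchestration: simulate -> quantify -> stallfind -> g4score ->
# circquant, with plain-text artifacts and a reproducibility manifest.

#' Build a validated pipeline configuration
#'
#' All module parameters are validated up front; unknown keys are rejected
#' (they raise the usual unused-argument error). In `analyze` mode the input
#' paths must point to existing files; `simulate` and `full` generate their
#' own inputs under `outdir/sim`.
#'
#' @param mode `"full"` (simulate then analyze the written files),
#'   `"simulate"` (write synthetic inputs only) or `"analyze"` (consume
#'   user-provided inputs).
#' @param outdir run directory.
#' @param seed root seed; stage seeds are derived from it (build: seed,
#'   render: seed + 1, shuffles: seed + 2).
#' @param n_genes,class_mix,depth,n_replicates simulator settings (see
#'   [build_transcriptome()] and [render_libraries()]).
#' @param cation,atailed,incubation_min digestion conditions of the treated
#'   libraries (see [digestion_config()]).
#' @param annotation,coverage,junctions,fasta,g4_bed,spikeins input paths for
#'   `analyze` mode; `coverage` is a named character vector of bedGraph paths,
#'   names being sample ids of the form `<condition>_rep<i>`.
#' @param quantile,ratio_threshold quantify parameters.
#' @param fdr_threshold,min_segment,pseudocount,theta,inspect_tolerance
#'   stallfind parameters.
#' @param half_width,n_shuffles,qgrs_shuffles,L_max g4score parameters
#'   (`qgrs_shuffles`: how many of the shuffles also get QGRS-scored windows
#'   for the score comparison).
#' @param min_reads circquant detection threshold.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("full", "simulate", "analyze"),
                       outdir = tempfile("rnaserseq_run_"),
                       seed = 1L,
                       n_genes = 1200L, class_mix = NULL,
                       depth = 100, n_replicates = 2L,
                       cation = "K", atailed = FALSE, incubation_min = 90,
                       annotation = NULL, coverage = NULL, junctions = NULL,
                       fasta = NULL, g4_bed = NULL, spikeins = NULL,
                       quantile = 0.75, ratio_threshold = 1,
                       fdr_threshold = 0.05, min_segment = 25L,
                       pseudocount = 1, theta = 0.2, inspect_tolerance = 200L,
                       half_width = 200L, n_shuffles = 100L,
                       qgrs_shuffles = 1L, L_max = 30L, min_reads = 2L) {
  mode <- match.arg(mode)
  stopifnot(seed == round(seed), n_genes >= 1, depth > 0, n_replicates >= 2,
            quantile >= 0, quantile <= 1, fdr_threshold > 0, fdr_threshold <= 1,
            half_width > 0, n_shuffles >= 1, qgrs_shuffles >= 0,
            qgrs_shuffles <= n_shuffles, min_reads >= 1, min_segment >= 2)
  # validates the digestion parameters early
  digestion_config(cation = cation, atailed = atailed,
                   incubation_min = incubation_min)
  cfg <- list(mode = mode, outdir = outdir, seed = as.integer(seed),
              n_genes = as.integer(n_genes), class_mix = class_mix,
              depth = depth, n_replicates = as.integer(n_replicates),
              cation = cation, atailed = atailed,
              incubation_min = incubation_min,
              annotation = annotation, coverage = coverage,
              junctions = junctions, fasta = fasta, g4_bed = g4_bed,
              spikeins = spikeins,
              quantile = quantile, ratio_threshold = ratio_threshold,
              fdr_threshold = fdr_threshold, min_segment = as.integer(min_segment),
              pseudocount = pseudocount, theta = theta,
              inspect_tolerance = as.integer(inspect_tolerance),
              half_width = as.integer(half_width),
              n_shuffles = as.integer(n_shuffles),
              qgrs_shuffles = as.integer(qgrs_shuffles),
              L_max = as.integer(L_max), min_reads = as.integer(min_reads))
  class(cfg) <- "run_config"
  cfg
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

# Pooled, 5'->3' oriented last-exon coverage of one gene.
last_exon_profile <- function(libs, gid) {
  g <- match(gid, libs$genes$gene_id)
  les <- libs$genes$last_exon_start[g]; lee <- libs$genes$last_exon_end[g]
  if (is.na(les) || is.na(lee)) return(NULL)
  idx <- (les - libs$genes$start[g] + 1L):(lee - libs$genes$start[g])
  cov <- libs$coverage[[gid]]
  ctrl <- rowSums(cov[idx, libs$samples$sample_id[libs$samples$condition == "control"],
                      drop = FALSE])
  trt <- rowSums(cov[idx, libs$samples$sample_id[libs$samples$condition == "rnaser"],
                     drop = FALSE])
  if (libs$genes$strand[g] == "-") { ctrl <- rev(ctrl); trt <- rev(trt) }
  list(control = ctrl, treated = trt)
}

#' Run the RNase R resistance pipeline
#'
#' Executes the stages in dependency order (simulate, quantify, stallfind,
#' g4score, circquant), writing each stage's outputs before the next begins,
#' and finishes with a manifest recording parameters, seeds, stage timings
#' and MD5 checksums of every artifact. Reruns with an identical
#' configuration reproduce identical checksums for all deterministic
#' artifacts.
#'
#' @param cfg a [run_config()].
#' @return An `rnaser_run` list: `config`, `expression`, `sites` (all fitted,
#'   with inspection flags), `windows` (inspected sites with sequences),
#'   `qgrs`, `profile`, `g4_stats`, `spikein_qc`, `circ`, `manifest`,
#'   `paths`. In `simulate` mode only the simulation artifacts are produced.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  timings <- c(); paths <- c()
  tic <- function() proc.time()[["elapsed"]]

  # ---- simulate --------------------------------------------------------
  if (cfg$mode %in% c("full", "simulate")) {
    t0 <- tic()
    pipeline_log("simulate", "building transcriptome of ", cfg$n_genes, " genes")
    mix_args <- if (is.null(cfg$class_mix)) list() else list(class_mix = cfg$class_mix)
    tx <- do.call(build_transcriptome,
                  c(list(n_genes = cfg$n_genes, seed = cfg$seed), mix_args))
    libs <- render_libraries(
      tx,
      control_cfg = control_config(cation = cfg$cation,
                                   incubation_min = cfg$incubation_min),
      rnaser_cfg = digestion_config(cation = cfg$cation, atailed = cfg$atailed,
                                    incubation_min = cfg$incubation_min),
      depth = cfg$depth, n_replicates = cfg$n_replicates,
      quantile_he = cfg$quantile, ratio_threshold = cfg$ratio_threshold,
      seed = cfg$seed + 1L
    )
    simdir <- file.path(cfg$outdir, "sim")
    sim_paths <- write_tracks(libs, simdir)
    paths <- c(paths, sim_paths)
    timings["simulate"] <- tic() - t0
    if (cfg$mode == "simulate") {
      manifest <- write_manifest(cfg, timings, paths)
      return(invisible(structure(
        list(config = cfg, libs = libs, manifest = manifest, paths = paths),
        class = "rnaser_run"
      )))
    }
  }

  # ---- load inputs -----------------------------------------------------
  t0 <- tic()
  if (cfg$mode == "full") {
    # full mode analyzes the in-memory simulation; the written artifacts are
    # identical (analyze mode on them reproduces this run, see tests)
    samples <- libs$samples
    dat <- list(coverage = libs$coverage, samples = samples,
                genes = libs$genes, transcripts = libs$transcripts,
                spikein_counts = libs$spikein_counts)
    spikes <- libs$spikein_counts
    spikes_len <- libs$spikeins$length
    ann <- list(genes = libs$genes, transcripts = libs$transcripts)
    genome <- libs$genome
    junc <- libs$junctions
    g4 <- {
      gg <- libs$genes[!is.na(libs$genes$g4_genomic), , drop = FALSE]
      mlen <- nchar(G4_MOTIF)
      data.frame(chrom = gg$chrom,
                 start = ifelse(gg$strand == "+",
                                gg$g4_genomic - mlen + 1L, gg$g4_genomic),
                 end = ifelse(gg$strand == "+",
                              gg$g4_genomic + 1L, gg$g4_genomic + mlen),
                 name = paste0("G4_", gg$gene_id), strand = gg$strand,
                 stringsAsFactors = FALSE)
    }
  } else {
    need <- c("annotation", "coverage", "junctions", "fasta")
    for (key in need) {
      p <- cfg[[key]]
      if (is.null(p)) stop_param("analyze mode requires a '", key, "' path")
      missing <- p[!file.exists(p)]
      if (length(missing)) stop_param("input file not found: ", missing[1L])
    }
    ann <- read_annotation(cfg$annotation)
    sample_ids <- names(cfg$coverage)
    if (is.null(sample_ids) || !all(grepl("^(control|rnaser)_rep[0-9]+$", sample_ids))) {
      stop_param("coverage paths must be named '<condition>_rep<i>' with condition control/rnaser")
    }
    samples <- data.frame(
      sample_id = sample_ids,
      condition = sub("_rep[0-9]+$", "", sample_ids),
      replicate = as.integer(sub("^.*_rep", "", sample_ids)),
      stringsAsFactors = FALSE
    )
    cov_by_sample <- lapply(cfg$coverage, read_coverage, genes = ann$genes)
    coverage <- lapply(seq_len(nrow(ann$genes)), function(g) {
      m <- vapply(sample_ids, function(s) cov_by_sample[[s]][[g]],
                  numeric(ann$genes$end[g] - ann$genes$start[g]))
      colnames(m) <- sample_ids
      m
    })
    names(coverage) <- ann$genes$gene_id
    genome <- read_fasta(cfg$fasta)
    junc <- read_junctions(cfg$junctions)
    g4 <- if (!is.null(cfg$g4_bed)) read_bed(cfg$g4_bed) else NULL
    spikes <- NULL
    if (!is.null(cfg$spikeins) && file.exists(cfg$spikeins)) {
      sp <- utils::read.table(cfg$spikeins, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, check.names = FALSE)
      cols <- intersect(sample_ids, names(sp))
      if (length(cols) >= 2L) {
        spikes <- as.matrix(sp[, cols, drop = FALSE])
        rownames(spikes) <- sp$spikein_id
        spikes_len <- sp$length
      }
    }
    dat <- list(coverage = coverage, samples = samples, genes = ann$genes,
                transcripts = ann$transcripts, spikein_counts = spikes)
  }
  timings["load"] <- tic() - t0

  # ---- quantify --------------------------------------------------------
  t0 <- tic()
  expr <- quantify_libraries(dat, quantile = cfg$quantile,
                             ratio_threshold = cfg$ratio_threshold)
  pipeline_log("quantify", sum(expr$resistant, na.rm = TRUE), " / ", nrow(expr),
               " genes called resistant")
  sp_qc <- NULL
  if (!is.null(spikes)) {
    # library sizes for QC: total gene-span coverage + spike counts (only
    # relative spike levels matter for the correlation)
    gene_counts <- vapply(samples$sample_id, function(s) {
      sum(vapply(seq_along(dat$coverage), function(g) {
        sum(dat$coverage[[g]][, s])
      }, numeric(1L)))
    }, numeric(1L))
    mapped <- gene_counts + colSums(spikes)
    sp_rpkm <- sweep(spikes * 1e9 / spikes_len, 2L, mapped, "/")
    sp_qc <- spikein_qc(sp_rpkm)
  }
  paths["expression"] <- file.path(cfg$outdir, "expression.tsv")
  utils::write.table(expr, paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  timings["quantify"] <- tic() - t0

  # ---- stallfind -------------------------------------------------------
  t0 <- tic()
  resistant <- expr$gene_id[which(expr$resistant)]
  sites <- detect_stalling_sites(dat, resistant,
                                 fdr_threshold = cfg$fdr_threshold,
                                 min_segment = cfg$min_segment,
                                 pseudocount = cfg$pseudocount)
  if (nrow(sites)) {
    sites$inspected <- vapply(seq_len(nrow(sites)), function(i) {
      prof <- last_exon_profile(dat, sites$gene_id[i])
      auto_inspect(sites$exon_offset[i], prof$treated, theta = cfg$theta,
                   tolerance = cfg$inspect_tolerance)
    }, logical(1L))
  } else {
    sites$inspected <- logical(0)
  }
  windows <- extract_window(sites[sites$inspected, , drop = FALSE], genome,
                            half_width = cfg$half_width)
  pipeline_log("stallfind", nrow(sites), " sites at FDR <= ", cfg$fdr_threshold,
               "; ", nrow(windows), " pass inspection")
  paths["sites"] <- file.path(cfg$outdir, "stalling_sites.tsv")
  utils::write.table(sites, paths["sites"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["sites_bed"] <- file.path(cfg$outdir, "stalling_sites.bed")
  write_sites_bed(sites, paths["sites_bed"])
  if (nrow(windows)) {
    paths["windows_fa"] <- file.path(cfg$outdir, "windows.fa")
    ws <- Biostrings::DNAStringSet(windows$window_seq)
    names(ws) <- paste0(windows$gene_id, "_", windows$pos)
    Biostrings::writeXStringSet(ws, paths["windows_fa"])
  }
  timings["stallfind"] <- tic() - t0

  # ---- g4score ---------------------------------------------------------
  t0 <- tic()
  he_genes <- expr$gene_id[expr$highly_expressed]
  elig <- ann$genes[ann$genes$gene_id %in% he_genes &
                      !is.na(ann$genes$last_exon_start), , drop = FALSE]
  elig <- data.frame(chrom = elig$chrom, start = elig$last_exon_start,
                     end = elig$last_exon_end, strand = elig$strand,
                     gene_id = elig$gene_id, stringsAsFactors = FALSE)
  g4_stats <- list(n_sites = nrow(windows))
  qgrs_tab <- NULL; profile <- NULL
  if (nrow(windows)) {
    obs_scores <- vapply(windows$window_seq, function(s) {
      m <- max_qgrs(s, L_max = cfg$L_max)
      if (is.null(m)) NA_real_ else as.numeric(m$score)
    }, numeric(1L), USE.NAMES = FALSE)
    nulls <- shuffle_sites(nrow(windows), elig, n = cfg$n_shuffles,
                           half_width = cfg$half_width, seed = cfg$seed + 2L)
    enr <- g4_enrichment(windows, nulls, g4, window = cfg$half_width)
    dist <- nearest_g4(windows, g4)

    profile <- nucleotide_profile(windows$window_seq)
    gmat <- do.call(rbind, strsplit(windows$window_seq, "")) == "G"
    center <- abs(profile$position) <= 50
    g_center <- rowMeans(gmat[, center, drop = FALSE])
    g_flank <- rowMeans(gmat[, !center, drop = FALSE])
    prof_test <- mwu_test(g_center, g_flank, alternative = "greater")

    null_scores <- numeric(0)
    if (cfg$qgrs_shuffles > 0L) {
      nsites <- nulls$sites[nulls$sites$shuffle <= cfg$qgrs_shuffles, , drop = FALSE]
      nwin <- extract_window(nsites, genome, half_width = cfg$half_width)
      null_scores <- vapply(nwin$window_seq, function(s) {
        m <- max_qgrs(s, L_max = cfg$L_max)
        if (is.null(m)) NA_real_ else as.numeric(m$score)
      }, numeric(1L), USE.NAMES = FALSE)
    }
    qgrs_p <- if (sum(!is.na(obs_scores)) && sum(!is.na(null_scores))) {
      mwu_test(obs_scores[!is.na(obs_scores)],
               null_scores[!is.na(null_scores)],
               alternative = "greater")$p_value
    } else NA_real_

    qgrs_tab <- data.frame(
      gene_id = windows$gene_id, chrom = windows$chrom, pos = windows$pos,
      strand = windows$strand, max_qgrs = obs_scores, nearest_g4 = dist,
      stringsAsFactors = FALSE
    )
    g4_stats <- list(
      n_sites = nrow(windows),
      fisher_table = enr$table, fisher_p = enr$p_value,
      observed_g4_frac = enr$observed_frac, null_g4_frac = enr$null_frac,
      profile_mwu_p = prof_test$p_value, qgrs_mwu_p = qgrs_p,
      median_obs_qgrs = stats::median(obs_scores, na.rm = TRUE),
      median_null_qgrs = if (length(null_scores))
        stats::median(null_scores, na.rm = TRUE) else NA_real_
    )
    paths["qgrs"] <- file.path(cfg$outdir, "qgrs.tsv")
    utils::write.table(qgrs_tab, paths["qgrs"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["profile"] <- file.path(cfg$outdir, "nt_profile.tsv")
    utils::write.table(profile, paths["profile"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  paths["g4_stats"] <- file.path(cfg$outdir, "g4_stats.json")
  jsonlite::write_json(manifest_safe(g4_stats), paths["g4_stats"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log("g4score", "Fisher p = ", format(g4_stats$fisher_p %||% NA))
  timings["g4score"] <- tic() - t0

  # ---- circquant -------------------------------------------------------
  t0 <- tic()
  det <- detect_circles(junc, min_reads = cfg$min_reads)
  circle_genes <- det$gene_id[det$detected_control | det$detected_rnaser]
  sub <- junc[junc$gene_id %in% circle_genes, , drop = FALSE]
  circ_stats <- list(n_circle_genes = length(circle_genes))
  circ_tab <- det
  if (length(circle_genes)) {
    fe <- fold_enrichment(sub)
    r_ctrl <- junction_ratio(sub, "control")
    r_trt <- junction_ratio(sub, "rnaser")
    cmp <- compare_conditions(r_trt[circle_genes], r_ctrl[circle_genes],
                              alternative = "greater")
    circ_tab <- merge(det, fe, by = "gene_id", all.x = TRUE)
    circ_tab$junction_ratio_control <- r_ctrl[circ_tab$gene_id]
    circ_tab$junction_ratio_rnaser <- r_trt[circ_tab$gene_id]
    circ_stats <- list(
      n_circle_genes = length(circle_genes),
      median_fold_enrichment = stats::median(fe$fold_enrichment, na.rm = TRUE),
      pooled_fold_enrichment = attr(fe, "pooled_fold"),
      junction_ratio_mwu_p = cmp$p_value,
      median_ratio_control = stats::median(r_ctrl[circle_genes], na.rm = TRUE),
      median_ratio_rnaser = stats::median(r_trt[circle_genes], na.rm = TRUE)
    )
  }
  paths["circ"] <- file.path(cfg$outdir, "circ_enrichment.tsv")
  utils::write.table(circ_tab, paths["circ"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["circ_stats"] <- file.path(cfg$outdir, "circ_stats.json")
  jsonlite::write_json(manifest_safe(circ_stats), paths["circ_stats"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log("circquant", length(circle_genes), " circle genes; median fold ",
               format(circ_stats$median_fold_enrichment %||% NA))
  timings["circquant"] <- tic() - t0

  manifest <- write_manifest(cfg, timings, paths)
  invisible(structure(
    list(config = cfg, genes = ann$genes, expression = expr, sites = sites,
         windows = windows, qgrs = qgrs_tab, profile = profile,
         g4_stats = g4_stats, spikein_qc = sp_qc, circ = circ_tab,
         circ_stats = circ_stats, manifest = manifest, paths = paths),
    class = "rnaser_run"
  ))
}

#' @export
print.rnaser_run <- function(x, ...) {
  cat(sprintf("<rnaser_run> mode=%s seed=%d outdir=%s\n",
              x$config$mode, x$config$seed, x$config$outdir))
  if (!is.null(x$expression)) {
    cat(sprintf("  resistant genes: %d; stalling sites: %d (%d inspected)\n",
                sum(x$expression$resistant, na.rm = TRUE),
                NROW(x$sites), NROW(x$windows)))
  }
  invisible(x)
}

write_sites_bed <- function(sites, path) {
  # BED6, score = -log10 FDR (capped at 300)
  bed <- data.frame(
    chrom = sites$chrom, start = sites$pos, end = sites$pos + 1L,
    name = sites$gene_id,
    score = round(pmin(300, -log10(pmax(sites$fdr, 1e-300))), 3L),
    strand = sites$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# Drop non-serializable entries and convert matrices for JSON output.
manifest_safe <- function(x) {
  lapply(x, function(v) {
    if (is.matrix(v)) as.data.frame(v) else v
  })
}

write_manifest <- function(cfg, timings, paths) {
  manifest <- list(
    package = "rnaserseq",
    version = as.character(utils::packageVersion("rnaserseq")),
    mode = cfg$mode, seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("outdir", "annotation", "coverage",
                                           "junctions", "fasta", "g4_bed",
                                           "spikeins"))],
    stage_seconds = as.list(round(timings, 3)),
    checksums = as.list(tools::md5sum(unname(paths[file.exists(paths)])))
  )
  p <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  manifest$path <- p
  manifest
}
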