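test_that("degenerate class mix yields plain free-end mRNAs only", {
  tx <- build_transcriptome(4, class_mix = c(plain_mRNA = 1), seed = 1)
  expect_equal(nrow(tx$genes), 4L)
  expect_true(all(tx$genes$class == "plain_mRNA"))
  expect_length(tx$transcripts, 4L)
  for (tm in tx$transcripts) {
    expect_equal(tm$topology, "linear")
    expect_equal(tm$end_structure, "free")
    expect_equal(nrow(tm$g4_elements), 0L)
  }
  # sequences match the genome at the exon positions
  tm <- tx$transcripts[[1L]]
  expect_equal(nchar(rnaserseq:::tx_sequence(tm, tx$genome)),
               sum(tm$exons[, 2] - tm$exons[, 1]))
})

test_that("invalid class mixes are rejected", {
  expect_error(build_transcriptome(4, class_mix = c(plain_mRNA = -0.5, g4_mRNA = 1.5)),
               "non-negative")
  expect_error(build_transcriptome(4, class_mix = c(plain_mRNA = 0.7)), "sum to 1")
})

test_that("the same seed reproduces the transcriptome and libraries exactly", {
  tx1 <- build_transcriptome(25, seed = 42)
  tx2 <- build_transcriptome(25, seed = 42)
  expect_identical(tx1$genes, tx2$genes)
  expect_identical(as.character(tx1$genome), as.character(tx2$genome))
  libs1 <- render_libraries(tx1, seed = 9)
  libs2 <- render_libraries(tx2, seed = 9)
  expect_identical(libs1$coverage, libs2$coverage)
  expect_identical(libs1$junctions, libs2$junctions)
  expect_identical(libs1$truth, libs2$truth)
})

test_that("class counts follow the requested multinomial mix", {
  tx <- build_transcriptome(100, class_mix = stats::setNames(rep(0.2, 5), TRANSCRIPT_CLASSES),
                            seed = 7)
  counts <- table(factor(tx$genes$class, levels = TRANSCRIPT_CLASSES))
  gof <- suppressWarnings(stats::chisq.test(counts, p = rep(0.2, 5)))
  expect_gt(gof$p.value, 0.001)
})

test_that("planted G4 elements carry a QGRS motif in the transcript sequence", {
  tx <- build_transcriptome(10, class_mix = c(g4_mRNA = 1), seed = 3)
  for (tm in tx$transcripts) {
    seq <- rnaserseq:::tx_sequence(tm, tx$genome)
    pos <- tm$g4_elements$tx_position[1]
    motif <- substr(seq, pos - nchar(rnaserseq:::G4_MOTIF) + 2L, pos + 1L)
    expect_equal(motif, rnaserseq:::G4_MOTIF)
    expect_gt(nrow(find_qgrs(motif)), 0L)
  }
})

test_that("digestion limit cases obey the overhang, circularity and cation rules", {
  inf_cfg <- function(...) digestion_config(incubation_min = 1e6, jitter_sd = 0, ...)

  circ <- make_tm(topology = "circular_exonic", abundance = 2)
  fp <- simulate_digestion(circ, inf_cfg(seed = 1))
  expect_equal(fp$fragments, data.frame(tx_start = 0L, tx_end = 1000L, weight = 2))

  protected <- make_tm(end_structure = "structured", overhang_len = 0L)
  fp <- simulate_digestion(protected, inf_cfg(seed = 1))
  expect_equal(fp$survival, 1)
  expect_equal(fp$fragments$tx_end, 1000L)

  # A-tailing creates the overhang the enzyme needs
  fp <- simulate_digestion(protected, inf_cfg(atailed = TRUE, tail_mean = 200, seed = 4))
  expect_equal(fp$survival, 0)

  g4 <- make_tm(g4_at = 600L, stall = c(K = 1, Na = 0, Li = 0))
  fp <- simulate_digestion(g4, inf_cfg(seed = 1))
  expect_equal(nrow(fp$fragments), 1L)
  expect_equal(fp$fragments$tx_end, 605L)  # element 3' edge + 5 nt footprint
  expect_equal(fp$fragments$weight, 1)

  fp <- simulate_digestion(g4, inf_cfg(cation = "Li", seed = 1))
  expect_equal(nrow(fp$fragments), 0L)
  expect_equal(fp$survival, 0)
})

test_that("surviving weight is conserved and monotone in time and cation", {
  tx <- build_transcriptome(40, class_mix = stats::setNames(rep(0.2, 5), TRANSCRIPT_CLASSES),
                            seed = 5)
  for (tm in tx$transcripts) {
    surv <- sapply(c(`15` = 15, `90` = 90), function(t) {
      sapply(c("K", "Li"), function(cat) {
        simulate_digestion(tm, digestion_config(cation = cat, incubation_min = t,
                                                seed = 99))$survival
      })
    })
    expect_true(all(surv <= 1 + 1e-12))
    expect_true(all(surv[, "90"] <= surv[, "15"] + 1e-12))   # monotone in time
    if (tm$topology != "linear") expect_true(all(surv == 1))
    if (tm$end_structure == "structured") expect_true(all(surv == 1))
    if (nrow(tm$g4_elements)) {
      expect_true(all(surv["K", ] >= surv["Li", ] - 1e-12)) # K+ stabilizes G4s
    }
    if (tm$topology == "linear" && tm$end_structure == "free" &&
        !nrow(tm$g4_elements)) {
      expect_true(all(surv["K", ] <= surv["Li", ] + 1e-12)) # rate K >= rate Li
    }
  }
})

test_that("rendered coverage reflects the digestion weights", {
  # plain mRNA at long incubation: treated coverage ~ 0
  tx <- build_transcriptome(5, class_mix = c(plain_mRNA = 1), seed = 8)
  libs <- render_libraries(tx, depth = 100, seed = 2)
  trt <- libs$samples$sample_id[libs$samples$condition == "rnaser"]
  for (g in tx$genes$gene_id) {
    expect_lt(max(libs$coverage[[g]][, trt]), 3)
  }

  # G4 mRNA: treated/control coverage ratio 5' of the stall ~ stall_prob
  tx <- build_transcriptome(12, class_mix = c(g4_mRNA = 1), seed = 9)
  libs <- render_libraries(tx, depth = 100, seed = 3)
  ctl <- libs$samples$sample_id[libs$samples$condition == "control"]
  for (g in seq_len(nrow(tx$genes))) {
    gid <- tx$genes$gene_id[g]
    tm <- tx$transcripts[[tx$genes$transcript_id[g]]]
    gp <- rnaserseq:::tx_genomic_positions(tm)
    stall_end <- libs$truth$stall_tx[libs$truth$gene_id == gid]
    up_idx <- gp[1:(stall_end - 30L)] - tx$genes$start[g] + 1L
    mu_t <- mean(libs$coverage[[gid]][up_idx, trt])
    mu_c <- mean(libs$coverage[[gid]][up_idx, ctl])
    # expected ratio: stalled (0.9) plus the undigested remnant (~0)
    se <- sqrt(mu_t / (length(up_idx) * 2)) / mu_c
    expect_lt(abs(mu_t / mu_c - 0.9), 4 * se + 0.02)
  }

  # circRNA host: treated coverage over the circularized exon equals the
  # circle weight; control adds the linear transcript on top
  tx <- build_transcriptome(10, class_mix = c(circRNA_host = 1), seed = 10)
  libs <- render_libraries(tx, depth = 100, seed = 4)
  for (g in seq_len(nrow(tx$genes))) {
    gid <- tx$genes$gene_id[g]
    circ <- tx$transcripts[[tx$genes$circle_id[g]]]
    idx <- (circ$exons[1, 1]:(circ$exons[1, 2] - 1L)) - tx$genes$start[g] + 1L
    mu_t <- mean(libs$coverage[[gid]][idx, trt])
    expected <- 100 * circ$abundance
    expect_lt(abs(mu_t - expected), 4 * sqrt(expected / (2 * length(idx))) + 0.05)
  }
})

test_that("truth table covers every planted G4 and realized stall", {
  tx <- build_transcriptome(60, seed = 11)
  libs <- render_libraries(tx, seed = 12)
  g4_rows <- libs$truth[libs$truth$class == "g4_mRNA", ]
  expect_true(all(!is.na(g4_rows$g4_tx)))
  expect_true(all(!is.na(g4_rows$g4_genomic)))
  # with stall probability 0.9 nearly all G4 genes stall; realized ends sit
  # near the element (footprint 5, jitter sd 10)
  stalled <- g4_rows[!is.na(g4_rows$stall_tx), ]
  expect_gt(nrow(stalled), 0.6 * nrow(g4_rows))
  expect_true(all(abs(stalled$stall_tx - (stalled$g4_tx + 5)) <= 60))
  expect_true(all(libs$truth$gene_id == tx$genes$gene_id))
  # replicate requirement
  expect_error(render_libraries(tx, n_replicates = 1), "n_replicates")
})
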