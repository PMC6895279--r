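# Coverage pairs engineered so the log2 ratio y is exact: with pseudocount 1,
# control 1 and treated 3 give y = 1; treated 1 gives y = 0.
step_pair <- function(n_up, n_down) {
  list(control = rep(1, n_up + n_down),
       treated = c(rep(3, n_up), rep(1, n_down)))
}

test_that("a noiseless step is recovered exactly", {
  cv <- step_pair(10, 10)
  fit <- fit_changepoint(cv$control, cv$treated, min_segment = 5)
  expect_equal(fit$breakpoint, 10L)
  expect_equal(fit$a, 1)
  expect_equal(fit$b, 0)
  expect_equal(fit$sse_two, 0)
  expect_equal(fit$p_value, 0)
  expect_gt(fit$drop, 0)
})

test_that("a constant ratio yields no significant split", {
  fit <- fit_changepoint(rep(5, 100), rep(5, 100))
  expect_equal(fit$f_stat, 0)
  expect_equal(fit$p_value, 1)
  # all-zero input is a no-signal result, not an error
  fit0 <- fit_changepoint(rep(0, 100), rep(0, 100))
  expect_true(is.na(fit0$breakpoint))
  expect_equal(fit0$p_value, 1)
  expect_error(fit_changepoint(1:10, 1:9), "equal length")
  expect_error(fit_changepoint(rep(1, 10), rep(1, 10), min_segment = 25), "too short")
})

test_that("the breakpoint is equivariant under y-shift and reversal", {
  set.seed(31)
  for (i in 1:20) {
    y <- c(rep(1.5, 60), rep(0.2, 40)) + stats::rnorm(100, 0, 0.3)
    y <- pmax(y, 0)
    ctrl <- rep(0, 100)
    f1 <- fit_changepoint(ctrl, 2^y - 1, min_segment = 10)
    # shift: y + 1 corresponds to doubling (treated + 1)
    f2 <- fit_changepoint(ctrl, 2^(y + 1) - 1, min_segment = 10)
    expect_equal(f2$breakpoint, f1$breakpoint)
    expect_equal(f2$a - f1$a, 1, tolerance = 1e-9)
    # reversal: breakpoint maps to L - p
    f3 <- fit_changepoint(rev(ctrl), rev(2^y - 1), min_segment = 10)
    expect_equal(f3$breakpoint, 100L - f1$breakpoint)
    expect_true(f1$sse_two <= f1$sse_one + 1e-12)
  }
})

test_that("a noisy step of height 1 is localized within +/-20 nt", {
  set.seed(32)
  hits <- 0L
  for (i in 1:200) {
    y <- c(rep(1, 200), rep(0, 200)) + stats::rnorm(400, 0, 0.25)
    fit <- fit_changepoint(rep(0, 400), 2^y - 1)
    hits <- hits + (abs(fit$breakpoint - 200L) <= 20L)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("stalling sites are recovered near the planted G4 elements", {
  tx <- build_transcriptome(40, class_mix = c(g4_mRNA = 1), seed = 33)
  libs <- render_libraries(tx, depth = 100, seed = 34)
  sites <- detect_stalling_sites(libs, tx$genes$gene_id)
  err <- abs(sites$pos - libs$truth$g4_genomic[match(sites$gene_id, libs$truth$gene_id)])
  expect_gte(nrow(sites), 0.8 * 40)
  # footprint 5 + jitter sd 10: median error within footprint + 2 sd
  expect_lte(median(err), 25)
  expect_true(all(sites$drop > 0))
  expect_true(all(sites$fdr <= 0.05))
  # empty resistant set
  expect_equal(nrow(detect_stalling_sites(libs, character(0))), 0L)
})

test_that("genes with uniform treated/control ratio rarely yield sites", {
  tx <- build_transcriptome(60, class_mix = c(circRNA_host = 1), seed = 35)
  libs <- render_libraries(tx, depth = 100, seed = 36)
  sites <- detect_stalling_sites(libs, tx$genes$gene_id)
  expect_lte(nrow(sites) / 60, 0.1)
})

test_that("automated inspection accepts drops at the breakpoint and rejects distant ones", {
  trt <- c(rep(100, 400), rep(0, 400))
  expect_true(auto_inspect(400L, trt))
  expect_false(auto_inspect(100L, trt))        # 300 nt 5' of the only drop
  expect_true(auto_inspect(350L, trt))         # within the 200 nt tolerance
  expect_false(auto_inspect(400L, rep(100, 800)))  # no drop at all
  expect_warning(expect_false(auto_inspect(2L, c(1, 2, 3))), "too short")
})

test_that("window extraction is strand-aware and refuses uncenterable sites", {
  set.seed(37)
  chrseq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(chrseq); names(genome) <- "chrT"
  sites <- data.frame(gene_id = c("g1", "g2"), chrom = "chrT",
                      pos = c(1000L, 1000L), strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  win <- extract_window(sites, genome)
  expect_equal(win$window_start, c(800L, 800L))
  expect_equal(win$window_end, c(1200L, 1200L))
  fwd <- substr(chrseq, 801, 1200)
  expect_equal(win$window_seq[1], fwd)
  expect_equal(win$window_seq[2],
               as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd))))
  near_edge <- data.frame(gene_id = "g3", chrom = "chrT", pos = 100L, strand = "+",
                          stringsAsFactors = FALSE)
  expect_warning(win2 <- extract_window(near_edge, genome), "dropped")
  expect_equal(nrow(win2), 0L)
})
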