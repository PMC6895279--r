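test_that("QGRS enumeration matches the worked examples", {
  m <- find_qgrs("GGGTGGGTGGGTGGG")
  top <- max_qgrs("GGGTGGGTGGGTGGG")
  expect_equal(top$x, 3L)
  expect_equal(c(top$y1, top$y2, top$y3), c(1L, 1L, 1L))
  expect_equal(top$length, 15L)
  expect_equal(top$score, 35L)
  expect_true(nrow(m) > 1L)   # overlapping x = 2 motifs are enumerated too

  top <- max_qgrs(strrep("G", 12))   # no room for 4 runs of 3
  expect_equal(top$x, 2L)
  expect_equal(top$length, 11L)
  expect_equal(top$score, 19L)

  expect_equal(nrow(find_qgrs("ACACACACACAC")), 0L)
  expect_null(max_qgrs("ACACACACACAC"))
  expect_error(find_qgrs("ACGU"), "A/C/G/T/N")
})

test_that("QGRS enumeration agrees exactly with the brute-force oracle", {
  set.seed(41)
  canon <- function(df) {
    df <- df[order(df$start, df$x, df$y1, df$y2, df$y3), , drop = FALSE]
    rownames(df) <- NULL
    as.data.frame(lapply(df, as.integer))
  }
  for (i in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    expect_equal(canon(find_qgrs(s)), canon(brute_qgrs(s)))
  }
  # and on a pathological G-rich sequence
  s <- paste0("GG", strrep("GGA", 15))
  expect_equal(canon(find_qgrs(s)), canon(brute_qgrs(s)))
})

test_that("the QGRS score rewards tetrads and short, even loops", {
  for (x in 2:6) {
    for (y1 in 1:5) for (y2 in 1:5) for (y3 in 1:5) {
      len <- 4 * x + y1 + y2 + y3
      if (len > 30) next
      s <- qgrs_score(x, y1, y2, y3)
      if (4 * (x + 1) + y1 + y2 + y3 <= 30) {
        expect_gt(qgrs_score(x + 1, y1, y2, y3), s)   # more tetrads
      }
      if (len + 3 <= 30) {
        expect_lt(qgrs_score(x, y1 + 1, y2 + 1, y3 + 1), s)  # longer loops
      }
    }
  }
  # equal loops maximize the score at fixed x and total length
  for (tot in 3:12) {
    parts <- expand.grid(y1 = 1:tot, y2 = 1:tot, y3 = 1:tot)
    parts <- parts[rowSums(parts) == tot, ]
    sc <- qgrs_score(3, parts$y1, parts$y2, parts$y3)
    best <- parts[which.max(sc), ]
    expect_lte(max(best) - min(best), 1)
  }
})

test_that("nucleotide profiles are per-position frequencies over non-N bases", {
  prof <- nucleotide_profile(c(strrep("G", 8), strrep("G", 8)))
  expect_true(all(prof$G == 1))
  expect_equal(prof$position, -4:3)

  prof <- nucleotide_profile(strrep("ACGT", 2))
  expect_equal(prof$A, c(1, 0, 0, 0, 1, 0, 0, 0))
  expect_equal(prof$T, c(0, 0, 0, 1, 0, 0, 0, 1))
  expect_true(all(abs(rowSums(prof[, c("A", "C", "G", "T")]) - 1) < 1e-9))

  # N bases are excluded from the denominator
  prof <- nucleotide_profile(c("ANGT", "ACGT"))
  expect_equal(prof$C[2], 1)

  expect_error(nucleotide_profile(c("ACG", "ACGT")), "mixed lengths")
})

test_that("shuffled sites are uniform, reproducible and boundary-respecting", {
  reg <- data.frame(chrom = "chrT", start = 0L, end = 1000L, strand = "+")
  null <- shuffle_sites(1, reg, n = 10000, half_width = 0, seed = 5)
  h <- table(cut(null$sites$pos, breaks = seq(0, 1000, by = 50)))
  expect_gt(suppressWarnings(stats::chisq.test(h)$p.value), 0.01)

  null2 <- shuffle_sites(1, reg, n = 10000, half_width = 0, seed = 5)
  expect_identical(null$sites, null2$sites)

  regs <- data.frame(chrom = "chrT", start = c(0L, 5000L), end = c(2000L, 6600L),
                     strand = c("+", "-"), gene_id = c("a", "b"))
  null3 <- shuffle_sites(7, regs, n = 100, half_width = 200, seed = 6)
  expect_true(all(table(null3$sites$shuffle) == 7))
  lo <- regs$start[match(null3$sites$gene_id, regs$gene_id)]
  hi <- regs$end[match(null3$sites$gene_id, regs$gene_id)]
  expect_true(all(null3$sites$pos - 200 >= lo & null3$sites$pos + 200 <= hi))

  expect_error(shuffle_sites(100, reg, half_width = 200), "insufficient eligible space")
})

test_that("nearest-G4 distances are signed in transcript orientation", {
  g4 <- data.frame(chrom = "chrT", start = 1050L, end = 1080L, strand = "+",
                   name = "q1")
  site <- data.frame(chrom = "chrT", pos = 1000L, strand = "+")
  expect_equal(nearest_g4(site, g4), 50)
  site$strand <- "-"
  g4$strand <- "-"
  expect_equal(nearest_g4(site, g4), -50)
  # inside the interval
  expect_equal(nearest_g4(data.frame(chrom = "chrT", pos = 1060L, strand = "-"), g4), 0)
  # upstream on + strand is negative
  g4$strand <- "+"
  expect_equal(nearest_g4(data.frame(chrom = "chrT", pos = 1100L, strand = "+"), g4), -21)
  expect_true(is.na(nearest_g4(site, g4[0, ])))
  # strand mismatch yields no eligible annotation
  expect_true(is.na(nearest_g4(data.frame(chrom = "chrT", pos = 1, strand = "-"), g4)))
})

test_that("the Fisher test matches enumeration, the closed form and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  set.seed(42)
  for (i in 1:100) {
    m <- matrix(sample(0:12, 4, replace = TRUE), 2)
    expect_equal(fisher_exact_2x2(m), fisher_oracle(m), tolerance = 1e-12)
    if (sum(m) > 0) {
      expect_equal(fisher_exact_2x2(m), stats::fisher.test(m)$p.value,
                   tolerance = 1e-9)
    }
  }
})

test_that("Mann-Whitney p-values match the rank-assignment enumeration oracle", {
  res <- mwu_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, mwu_oracle(c(1, 2, 3), c(4, 5, 6)))

  expect_equal(mwu_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  set.seed(43)
  for (i in 1:20) {
    a <- stats::rnorm(sample(3:6, 1)); b <- stats::rnorm(sample(3:6, 1))
    expect_equal(mwu_test(a, b)$p_value, mwu_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("G4 proximity enrichment is detected against the shuffled null", {
  # sites planted on top of G4s; nulls scattered over a mostly G4-free space
  g4 <- data.frame(chrom = "chrT", start = seq(10000L, 19000L, by = 1000L),
                   strand = "+")
  g4$end <- g4$start + 30L
  g4$name <- paste0("q", seq_len(nrow(g4)))
  sites <- data.frame(chrom = "chrT", pos = g4$start[1:10] + 40L, strand = "+")
  reg <- data.frame(chrom = "chrT", start = 0L, end = 200000L, strand = "+")
  null <- shuffle_sites(10, reg, n = 100, half_width = 200, seed = 7)
  enr <- g4_enrichment(sites, null, g4)
  expect_equal(enr$table["observed", "g4_near"], 10)
  expect_lt(enr$p_value, 1e-6)
  expect_warning(out <- g4_enrichment(sites[0, ], null, g4), "undefined")
  expect_true(is.na(out$p_value))
})
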