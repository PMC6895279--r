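make_junc <- function(back_c, back_r, lin_c = NULL, lin_r = NULL,
                      mapped_c = 1e6, mapped_r = 1e6, gene = "g1") {
  nreps <- length(back_c)
  if (is.null(lin_c)) lin_c <- rep(0L, nreps)
  if (is.null(lin_r)) lin_r <- rep(0L, nreps)
  mapped_c <- rep_len(mapped_c, nreps); mapped_r <- rep_len(mapped_r, nreps)
  data.frame(
    gene_id = gene,
    sample_id = c(paste0("control_rep", 1:nreps), paste0("rnaser_rep", 1:nreps)),
    condition = rep(c("control", "rnaser"), each = nreps),
    replicate = rep(1:nreps, 2),
    backsplice_reads = c(back_c, back_r),
    linear_spliced_reads = c(lin_c, lin_r),
    library_mapped_reads = c(mapped_c, mapped_r),
    stringsAsFactors = FALSE
  )
}

test_that("circle detection applies the 2-read rule per library", {
  det <- detect_circles(make_junc(back_c = c(1L, 1L), back_r = c(0L, 0L)))
  expect_false(det$detected_control)     # (1,1): no single library reaches 2
  det <- detect_circles(make_junc(back_c = c(2L, 0L), back_r = c(0L, 0L)))
  expect_true(det$detected_control)      # (2,0): one library suffices
  expect_false(det$consistent_control)
  det <- detect_circles(make_junc(back_c = c(0L, 0L), back_r = c(5L, 3L)))
  expect_false(det$detected_control)
  expect_true(det$detected_rnaser)
  expect_true(det$consistent_rnaser)
})

test_that("detection is monotone in read counts", {
  set.seed(51)
  for (i in 1:20) {
    bc <- sample(0:4, 2, replace = TRUE); br <- sample(0:4, 2, replace = TRUE)
    d1 <- detect_circles(make_junc(bc, br))
    d2 <- detect_circles(make_junc(bc + sample(0:2, 2, TRUE), br + sample(0:2, 2, TRUE)))
    expect_true(!d1$detected_control || d2$detected_control)
    expect_true(!d1$detected_rnaser || d2$detected_rnaser)
  }
})

test_that("fold enrichment is the replicate-averaged RPM ratio", {
  tab <- make_junc(back_c = 10L, back_r = 30L, mapped_c = 2e6, mapped_r = 1e6)
  fe <- fold_enrichment(tab)
  expect_equal(fe$fold_enrichment, 6)    # (30/1) / (10/2)
  expect_equal(attr(fe, "pooled_fold"), 6)

  tab <- make_junc(back_c = c(10L, 20L), back_r = c(10L, 20L))
  expect_equal(fold_enrichment(tab)$fold_enrichment, 1)

  # zero control RPM in all replicates: undefined, excluded with a message
  tab <- make_junc(back_c = c(0L, 0L), back_r = c(5L, 5L))
  expect_message(fe <- fold_enrichment(tab), "excluded")
  expect_true(is.na(fe$fold_enrichment))
})

test_that("junction ratios are backsplice over total spliced reads", {
  tab <- make_junc(back_c = 5L, back_r = 10L, lin_c = 95L, lin_r = 0L)
  expect_equal(unname(junction_ratio(tab, "control")), 0.05)
  expect_equal(unname(junction_ratio(tab, "rnaser")), 1)
  tab0 <- make_junc(back_c = 0L, back_r = 0L)
  expect_true(is.na(junction_ratio(tab0, "control")))
})

test_that("condition comparison delegates to the exact MWU and emits valid CDFs", {
  same <- c(0.1, 0.2, 0.3)
  res <- compare_conditions(same, same)
  expect_equal(res$p_value, 1)
  res <- compare_conditions(c(0.01, 0.02, 0.03), c(0.5, 0.6, 0.7))
  expect_equal(res$p_value, 0.1)         # disjoint supports, n = 3 each
  expect_true(all(diff(res$cdf_a$cdf) >= 0))
  expect_equal(res$cdf_a$cdf[nrow(res$cdf_a)], 1)
})

test_that("simulated circles are detected and enriched after treatment", {
  tx <- build_transcriptome(60, class_mix = c(plain_mRNA = 0.5, circRNA_host = 0.5),
                            seed = 52)
  libs <- render_libraries(tx, depth = 50, seed = 53)
  hosts <- libs$truth$gene_id[libs$truth$circle]
  det <- detect_circles(libs$junctions)
  det <- det[match(hosts, det$gene_id), ]
  # every circle with appreciable expected junction coverage is recovered
  expect_gte(mean(det$detected_rnaser), 0.95)

  sub <- libs$junctions[libs$junctions$gene_id %in% hosts, ]
  r_c <- junction_ratio(sub, "control")
  r_r <- junction_ratio(sub, "rnaser")
  cmp <- compare_conditions(r_r, r_c, alternative = "greater")
  expect_lt(cmp$p_value, 0.01)

  fe <- fold_enrichment(sub)
  expect_gt(median(fe$fold_enrichment, na.rm = TRUE), 1)
})
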