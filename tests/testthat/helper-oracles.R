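# Independent test oracles. These deliberately use naive, direct algorithms
# so they share no code path with the package implementations they check.

# Brute-force QGRS enumeration: test every (i1, x, y1, y2, y3) tuple by
# checking the four G runs directly.
brute_qgrs <- function(seq, L_max = 30L, x_min = 2L) {
  ch <- strsplit(toupper(seq), "")[[1L]]
  n <- length(ch)
  is_run <- function(i, x) i >= 1L && i + x - 1L <= n && all(ch[i:(i + x - 1L)] == "G")
  rows <- list()
  for (i1 in seq_len(n)) {
    for (x in x_min:((L_max - 3L) %/% 4L)) {
      if (!is_run(i1, x)) next
      for (y1 in 1L:(L_max - 4L * x - 2L)) {
        i2 <- i1 + x + y1
        if (!is_run(i2, x)) next
        for (y2 in 1L:(L_max - 4L * x - y1 - 1L)) {
          i3 <- i2 + x + y2
          if (!is_run(i3, x)) next
          for (y3 in 1L:(L_max - 4L * x - y1 - y2)) {
            i4 <- i3 + x + y3
            if (!is_run(i4, x)) next
            len <- 4L * x + y1 + y2 + y3
            rows[[length(rows) + 1L]] <- c(
              start = i1 - 1L, x = x, y1 = y1, y2 = y2, y3 = y3, length = len,
              score = 20L * (x - 2L) + (L_max - len) -
                (abs(y1 - y2) + abs(y1 - y3) + abs(y2 - y3))
            )
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), x = integer(), y1 = integer(),
                      y2 = integer(), y3 = integer(), length = integer(),
                      score = integer()))
  }
  df <- as.data.frame(do.call(rbind, rows))
  df[order(df$start, df$x, df$y1, df$y2, df$y3), , drop = FALSE]
}

# Two-sided Fisher p as an explicit closed-form hypergeometric sum using
# choose(), not dhyper().
fisher_oracle <- function(m) {
  N <- sum(m); m1 <- sum(m[, 1]); n1 <- sum(m[1, ])
  kk <- max(0, n1 - (N - m1)):min(n1, m1)
  pr <- choose(m1, kk) * choose(N - m1, n1 - kk) / choose(N, n1)
  pobs <- choose(m1, m[1, 1]) * choose(N - m1, n1 - m[1, 1]) / choose(N, n1)
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled observations to the two groups (untied data only).
mwu_oracle <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    aa <- pool[idx]; bb <- pool[-idx]
    sum(outer(aa, bb, ">"))
  }
  u_obs <- sum(outer(a, b, ">"))
  us <- combn(length(pool), na, u_of)
  m <- na * length(b)
  lo <- min(u_obs, m - u_obs); hi <- max(u_obs, m - u_obs)
  min(1, mean(us <= lo) + mean(us >= hi))
}

# Small helpers to build transcript fixtures directly.
make_tm <- function(topology = "linear", end_structure = "free",
                    overhang_len = 30L, length = 1000L, g4_at = NULL,
                    stall = c(K = 0.9, Na = 0.1, Li = 0.05),
                    abundance = 1, strand = "+") {
  g4 <- if (!is.null(g4_at)) {
    data.frame(tx_position = g4_at, stall_prob_K = stall[["K"]],
               stall_prob_Na = stall[["Na"]], stall_prob_Li = stall[["Li"]])
  } else NULL
  rnaserseq:::new_transcript_model(
    transcript_id = "T1", gene_id = "G1", chrom = "chrT", strand = strand,
    exons = c(0L, length), topology = topology, end_structure = end_structure,
    overhang_len = overhang_len, g4_elements = g4, abundance = abundance
  )
}
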