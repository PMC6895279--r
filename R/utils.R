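# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so seeded helpers do not perturb outer
# simulations. A NULL seed draws from the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Random DNA of length n as a single character string.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Genomic position (0-based) of every transcript base, in 5'->3' transcript
# order. Exons are stored in ascending genomic order; minus-strand transcripts
# traverse them right to left.
tx_genomic_positions <- function(tm) {
  ex <- tm$exons
  if (tm$strand == "+") {
    unlist(lapply(seq_len(nrow(ex)), function(i) seq.int(ex[i, 1L], ex[i, 2L] - 1L)))
  } else {
    unlist(lapply(rev(seq_len(nrow(ex))), function(i) seq.int(ex[i, 2L] - 1L, ex[i, 1L])))
  }
}

tx_length <- function(tm) sum(tm$exons[, 2L] - tm$exons[, 1L])

# Exonic sequence of a transcript, 5'->3', from a genome given as a
# Biostrings::DNAStringSet with one entry per chromosome.
tx_sequence <- function(tm, genome) {
  chrseq <- genome[[tm$chrom]]
  parts <- lapply(seq_len(nrow(tm$exons)), function(i) {
    Biostrings::subseq(chrseq, start = tm$exons[i, 1L] + 1L, end = tm$exons[i, 2L])
  })
  s <- do.call(Biostrings::xscat, parts)
  if (tm$strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_param <- function(...) stop(..., call. = FALSE)
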