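#' Fit a single change point to a treated/control coverage log-ratio
#'
#' Models the per-base log2 ratio `y(i) = log2((treated(i)+psi)/(control(i)+psi))`
#' (oriented 5'->3') as piecewise-constant with one breakpoint: mean `a` on
#' `i <= p`, mean `b` on `i > p`. The breakpoint is found by exhaustive search
#' over `p` in `[min_segment, L - min_segment]` minimizing the residual sum of
#' squares. Significance of the drop is assessed with the F statistic
#' `F = (sse_one - sse_two) / (sse_two / (L - 2))` against `F(1, L-2)`;
#' because the breakpoint is chosen as the best of all candidate splits, the
#' reported `p_value` is Bonferroni-adjusted over the number of candidates
#' (the unadjusted tail probability is returned as `p_raw`). An RNase R
#' stalling site appears as `a > b` (signal retained 5' of the stall, lost
#' 3' of it).
#'
#' @param control_cov,treated_cov equal-length non-negative coverage vectors,
#'   oriented 5'->3' in transcript direction.
#' @param min_segment minimum segment length in nt (default 25).
#' @param pseudocount pseudocount psi for the log-ratio (default 1).
#' @return A `changepoint_fit`: `breakpoint` (1-based index of the last
#'   upstream base; `NA` for a no-signal input), `a`, `b`, `drop = a - b`,
#'   `sse_one`, `sse_two`, `f_stat`, `p_raw`, `p_value`, `n_candidates`, `L`.
#' @examples
#' y <- c(rep(8, 50), rep(1, 50))
#' fit_changepoint(rep(10, 100), y, min_segment = 10)
#' @export
fit_changepoint <- function(control_cov, treated_cov, min_segment = 25L,
                            pseudocount = 1) {
  if (length(control_cov) != length(treated_cov)) {
    stop_param("control and treated coverage must have equal length")
  }
  L <- length(control_cov)
  if (L < 2L * min_segment) {
    stop_param("coverage too short: need length >= 2 * min_segment = ", 2L * min_segment)
  }
  y <- log2((treated_cov + pseudocount) / (control_cov + pseudocount))

  s <- cumsum(y); q <- cumsum(y^2)
  tot_s <- s[L]; tot_q <- q[L]
  sse_one <- tot_q - tot_s^2 / L

  p_grid <- seq.int(min_segment, L - min_segment)
  sse_left <- q[p_grid] - s[p_grid]^2 / p_grid
  sse_right <- (tot_q - q[p_grid]) - (tot_s - s[p_grid])^2 / (L - p_grid)
  sse_split <- sse_left + sse_right

  best <- which.min(sse_split)
  p <- p_grid[best]
  sse_two <- max(0, sse_split[best])
  a <- s[p] / p
  b <- (tot_s - s[p]) / (L - p)

  no_signal <- all(control_cov == 0) && all(treated_cov == 0)
  if (no_signal || sse_one < .Machine$double.eps) {
    f_stat <- 0; p_raw <- 1; p_adj <- 1
    if (no_signal) p <- NA_integer_
  } else if (sse_two < .Machine$double.eps * sse_one) {
    f_stat <- Inf; p_raw <- 0; p_adj <- 0
  } else {
    f_stat <- (sse_one - sse_two) / (sse_two / (L - 2))
    p_raw <- stats::pf(f_stat, 1, L - 2, lower.tail = FALSE)
    p_adj <- min(1, length(p_grid) * p_raw)
  }

  structure(
    list(breakpoint = p, a = a, b = b, drop = a - b,
         sse_one = sse_one, sse_two = sse_two, f_stat = f_stat,
         p_raw = p_raw, p_value = p_adj,
         n_candidates = length(p_grid), L = L,
         min_segment = as.integer(min_segment), pseudocount = pseudocount),
    class = "changepoint_fit"
  )
}

#' @export
print.changepoint_fit <- function(x, ...) {
  cat(sprintf(
    "<changepoint_fit> L=%d, breakpoint=%s, a=%.3f, b=%.3f (drop %.3f), F=%.2f, p=%.3g\n",
    x$L, ifelse(is.na(x$breakpoint), "NA", x$breakpoint), x$a, x$b, x$drop,
    x$f_stat, x$p_value))
  invisible(x)
}

#' Detect RNase R stalling sites in resistant genes
#'
#' For each resistant gene, pools replicate coverage (summing within
#' condition) over the gene's annotated last exon, orients it 5'->3', fits a
#' single change point with [fit_changepoint()], applies Benjamini-Hochberg
#' FDR control across all tested genes, and retains sites with
#' `fdr <= fdr_threshold` and a positive drop (signal lost 3' of the site).
#'
#' @param libs a `sim_libraries` object or compatible list (`coverage`,
#'   `samples`, `genes` with last-exon columns).
#' @param resistant_genes character vector of gene ids to test.
#' @param fdr_threshold BH FDR cutoff (default 0.05).
#' @param min_segment,pseudocount passed to [fit_changepoint()].
#' @return data.frame of stalling sites: `gene_id`, `chrom`, `pos` (genomic,
#'   0-based: first base 3' of the fitted breakpoint), `strand`,
#'   `exon_offset` (breakpoint index within the oriented last exon), `drop`,
#'   `p_value`, `fdr`. Genes lacking last-exon annotation are skipped with a
#'   warning; an empty input yields an empty frame.
#' @export
detect_stalling_sites <- function(libs, resistant_genes, fdr_threshold = 0.05,
                                  min_segment = 25L, pseudocount = 1) {
  genes <- libs$genes
  samples <- libs$samples
  empty <- data.frame(gene_id = character(), chrom = character(),
                      pos = integer(), strand = character(),
                      exon_offset = integer(), drop = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE)
  resistant_genes <- intersect(resistant_genes, genes$gene_id)
  if (!length(resistant_genes)) return(empty)

  ctrl_ids <- samples$sample_id[samples$condition == "control"]
  trt_ids <- samples$sample_id[samples$condition == "rnaser"]
  rows <- list()
  for (gid in resistant_genes) {
    g <- match(gid, genes$gene_id)
    les <- genes$last_exon_start[g]; lee <- genes$last_exon_end[g]
    if (is.na(les) || is.na(lee)) {
      warning("gene ", gid, " skipped: no last-exon annotation")
      next
    }
    if (lee - les < 2L * min_segment) {
      warning("gene ", gid, " skipped: last exon shorter than 2*min_segment")
      next
    }
    idx <- (les - genes$start[g] + 1L):(lee - genes$start[g])
    cov <- libs$coverage[[gid]]
    ctrl <- rowSums(cov[idx, ctrl_ids, drop = FALSE])
    trt <- rowSums(cov[idx, trt_ids, drop = FALSE])
    if (genes$strand[g] == "-") { ctrl <- rev(ctrl); trt <- rev(trt) }
    fit <- fit_changepoint(ctrl, trt, min_segment = min_segment,
                           pseudocount = pseudocount)
    if (is.na(fit$breakpoint)) next
    pos <- if (genes$strand[g] == "+") les + fit$breakpoint else lee - 1L - fit$breakpoint
    rows[[gid]] <- data.frame(
      gene_id = gid, chrom = genes$chrom[g], pos = pos,
      strand = genes$strand[g], exon_offset = fit$breakpoint,
      drop = fit$drop, p_value = fit$p_value, stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[out$fdr <= fdr_threshold & out$drop > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Automated inspection of a stalling site against the coverage drop-off
#'
#' Operationalizes the "within ~200 nt of where the signal clearly dropped
#' off" rule: the drop-off position is the 5'-most index at which the 21-nt
#' median-smoothed treated coverage falls below `theta` times the median
#' treated coverage 5' of the fitted breakpoint and stays below it for at
#' least `persist` nt (or through the end of the region). The site passes
#' inspection when `|breakpoint - dropoff| <= tolerance`.
#'
#' @param breakpoint fitted breakpoint (1-based index in the oriented
#'   region).
#' @param treated_cov treated coverage over the region, oriented 5'->3'.
#' @param theta drop fraction relative to the upstream median (default 0.2).
#' @param tolerance maximum allowed distance in nt (default 200).
#' @param smooth_k running-median window (odd, default 21).
#' @param persist minimum run length below threshold (default 50).
#' @return Logical scalar; `FALSE` with a warning if the region is too short
#'   to smooth.
#' @export
auto_inspect <- function(breakpoint, treated_cov, theta = 0.2,
                         tolerance = 200L, smooth_k = 21L, persist = 50L) {
  L <- length(treated_cov)
  if (L < smooth_k) {
    warning("coverage too short to smooth; inspection failed")
    return(FALSE)
  }
  if (is.na(breakpoint) || breakpoint < 1L || breakpoint > L) return(FALSE)
  sm <- stats::runmed(treated_cov, smooth_k)
  baseline <- stats::median(treated_cov[seq_len(breakpoint)])
  below <- sm < theta * baseline
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & (r$lengths >= persist | ends == L)
  if (!any(ok)) return(FALSE)
  dropoff <- starts[which(ok)[1L]]
  abs(breakpoint - dropoff) <= tolerance
}

#' Extract the genomic window centered on a stalling site
#'
#' Returns the `2 * half_width` nt window around the site together with its
#' sequence, 5'->3' in transcript orientation (reverse-complemented for minus
#' strand sites). Sites whose window would extend past either chromosome end
#' are dropped with a warning (they cannot be centered).
#'
#' @param sites data.frame with `chrom`, `pos`, `strand` (and any other
#'   columns, preserved).
#' @param genome \code{Biostrings::DNAStringSet}.
#' @param half_width half window width in nt (default 200).
#' @return `sites` restricted to extractable rows, with `window_start`,
#'   `window_end` (0-based half-open) and `window_seq` columns added.
#' @export
extract_window <- function(sites, genome, half_width = 200L) {
  if (!nrow(sites)) {
    sites$window_start <- integer(0); sites$window_end <- integer(0)
    sites$window_seq <- character(0)
    return(sites)
  }
  chrlen <- stats::setNames(Biostrings::width(genome), names(genome))
  ws <- sites$pos - half_width
  we <- sites$pos + half_width
  ok <- ws >= 0L & we <= chrlen[sites$chrom] & sites$chrom %in% names(genome)
  if (any(!ok)) {
    warning(sum(!ok), " site(s) dropped: window extends past a chromosome end")
  }
  out <- sites[ok, , drop = FALSE]
  out$window_start <- ws[ok]
  out$window_end <- we[ok]
  out$window_seq <- vapply(seq_len(nrow(out)), function(i) {
    s <- Biostrings::subseq(genome[[out$chrom[i]]],
                            start = out$window_start[i] + 1L,
                            end = out$window_end[i])
    if (out$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1L))
  rownames(out) <- NULL
  out
}
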