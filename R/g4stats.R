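# Nucleotide profiles, shuffle nulls over last exons, distances to annotated
# G-quadruplexes, and the enrichment statistics.

#' Per-position nucleotide frequencies across windows
#'
#' @param windows character vector of equal-length sequences, all oriented
#'   5'->3'.
#' @return data.frame with `position` (centered: -W/2 .. W/2 - 1) and
#'   frequency columns `A`, `C`, `G`, `T`; frequencies at each position sum
#'   to 1 over contributing (non-N) bases.
#' @export
nucleotide_profile <- function(windows) {
  if (!length(windows)) stop_param("no windows")
  W <- unique(nchar(windows))
  if (length(W) != 1L) stop_param("windows have mixed lengths")
  mat <- do.call(rbind, strsplit(toupper(windows), ""))
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) colSums(mat == b), numeric(W))
  denom <- rowSums(counts)
  denom[denom == 0] <- NA_real_
  freq <- counts / denom
  data.frame(position = seq_len(W) - 1L - W %/% 2L, freq, check.names = FALSE)
}

#' Shuffle stalling sites uniformly over eligible last exons
#'
#' Places `n_sites` sites per shuffle, per-base uniformly over the
#' concatenation of all eligible positions — the positions at which the full
#' `2 * half_width` window fits inside a single eligible region (windows
#' never cross region boundaries). Shuffles are independent and the whole
#' draw is seed-reproducible.
#'
#' @param n_sites number of sites per shuffle (or a data.frame of observed
#'   sites, whose row count is used).
#' @param eligible_regions data.frame with `chrom`, `start`, `end` and
#'   optionally `strand` and `gene_id` (typically last exons of highly
#'   expressed genes).
#' @param n number of shuffles (default 100).
#' @param half_width half window width (default 200); eligible positions
#'   keep `[pos - half_width, pos + half_width)` inside the region. Use 0 to
#'   shuffle bare positions.
#' @param seed integer seed.
#' @return A `shuffle_null` object: data.frame `sites` with `shuffle`,
#'   `chrom`, `pos`, `strand`, plus `n_shuffles`, `n_sites`, `half_width`,
#'   `seed`.
#' @export
shuffle_sites <- function(n_sites, eligible_regions, n = 100L,
                          half_width = 200L, seed = 1L) {
  if (is.data.frame(n_sites)) n_sites <- nrow(n_sites)
  if (n_sites < 1L) stop_param("need at least one site")
  reg <- eligible_regions
  if (!nrow(reg)) stop_param("no eligible regions")
  if (is.null(reg$strand)) reg$strand <- "+"
  if (sum(reg$end - reg$start) < n_sites * 2L * half_width) {
    stop_param("insufficient eligible space: total region length < site count * window length")
  }
  lo <- reg$start + half_width
  hi <- reg$end - half_width          # pos in [lo, hi)
  nelig <- pmax(0L, hi - lo)
  total <- sum(nelig)
  if (total < 1L) stop_param("no eligible positions: all regions shorter than the window")
  cum <- cumsum(nelig)
  with_seed(seed, {
    u <- sample.int(total, n_sites * n, replace = TRUE)
    ridx <- findInterval(u - 1L, cum) + 1L     # region of each draw
    offset <- u - c(0L, cum)[ridx] - 1L
    sites <- data.frame(
      shuffle = rep(seq_len(n), each = n_sites),
      chrom = reg$chrom[ridx],
      pos = lo[ridx] + offset,
      strand = reg$strand[ridx],
      stringsAsFactors = FALSE
    )
    if (!is.null(reg$gene_id)) sites$gene_id <- reg$gene_id[ridx]
    structure(
      list(sites = sites, n_shuffles = as.integer(n),
           n_sites = as.integer(n_sites), half_width = as.integer(half_width),
           seed = seed),
      class = "shuffle_null"
    )
  })
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat(sprintf("<shuffle_null> %d sites x %d shuffles (half-width %d, seed %s)\n",
              x$n_sites, x$n_shuffles, x$half_width, format(x$seed)))
  invisible(x)
}

#' Signed distance from each site to its nearest G-quadruplex
#'
#' Distances are edge-to-site in transcript orientation: positive when the
#' nearest G4 lies 3' (downstream) of the site, negative when 5', and zero
#' when the site falls inside a G4 interval. With `stranded = TRUE` only
#' same-strand annotations are considered.
#'
#' @param sites data.frame with `chrom`, `pos`, `strand`.
#' @param g4 data.frame of G4 intervals with `chrom`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @param stranded match strands (default TRUE)?
#' @return Numeric vector of signed distances, `NA` where no eligible G4
#'   exists.
#' @export
nearest_g4 <- function(sites, g4, stranded = TRUE) {
  n <- nrow(sites)
  out <- rep(NA_real_, n)
  if (!n || is.null(g4) || !nrow(g4)) return(out)
  for (i in seq_len(n)) {
    sel <- g4$chrom == sites$chrom[i]
    if (stranded) sel <- sel & g4$strand == sites$strand[i]
    if (!any(sel)) next
    st <- g4$start[sel]; en <- g4$end[sel]
    pos <- sites$pos[i]
    d <- ifelse(pos >= st & pos < en, 0,
                ifelse(st > pos, st - pos, -(pos - (en - 1L))))
    d_best <- d[which.min(abs(d))]
    out[i] <- if (sites$strand[i] == "-") -d_best else d_best
  }
  out
}

#' Two-sided Fisher exact test for a 2x2 table by hypergeometric enumeration
#'
#' Enumerates the full hypergeometric support at fixed margins and sums the
#' probabilities of all tables at most as probable as the observed one (with
#' the conventional 1e-7 relative tolerance on "as probable").
#'
#' @param m 2x2 matrix of non-negative counts.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))  # 2 / choose(20, 10)
#' @export
fisher_exact_2x2 <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == 2L) || any(m < 0) || any(m != round(m))) {
    stop_param("need a 2x2 matrix of non-negative integer counts")
  }
  N <- sum(m)
  if (N == 0L) return(1)
  m1 <- sum(m[, 1L]); n1 <- sum(m[1L, ])
  kk <- max(0L, n1 - (N - m1)):min(n1, m1)
  d <- stats::dhyper(kk, m1, N - m1, n1)
  dobs <- stats::dhyper(m[1L, 1L], m1, N - m1, n1)
  min(1, sum(d[d <= dobs * (1 + 1e-7)]))
}

#' G4 proximity enrichment of stalling sites vs a shuffled null
#'
#' Builds the 2x2 table \{observed, pooled-shuffled\} x \{G4 within the
#' window, none\} — pooling all shuffles into one null row — and computes the
#' two-sided Fisher exact p-value by hypergeometric enumeration.
#'
#' @param sites observed sites (data.frame with `chrom`, `pos`, `strand`).
#' @param null a `shuffle_null` from [shuffle_sites()].
#' @param g4 G4 annotation (see [nearest_g4()]).
#' @param window proximity window in nt (default 200; a site counts as "near
#'   a G4" when `|signed distance| <= window`).
#' @param stranded passed to [nearest_g4()].
#' @return List with `table` (2x2 matrix), `p_value`, `observed_frac`,
#'   `null_frac`. An empty site set is undefined: returns `NA` entries with
#'   a warning.
#' @export
g4_enrichment <- function(sites, null, g4, window = 200L, stranded = TRUE) {
  if (!nrow(sites)) {
    warning("empty site set: enrichment undefined")
    return(list(table = NULL, p_value = NA_real_,
                observed_frac = NA_real_, null_frac = NA_real_))
  }
  stopifnot(inherits(null, "shuffle_null"))
  obs_d <- nearest_g4(sites, g4, stranded = stranded)
  null_d <- nearest_g4(null$sites, g4, stranded = stranded)
  obs_hit <- !is.na(obs_d) & abs(obs_d) <= window
  null_hit <- !is.na(null_d) & abs(null_d) <= window
  tab <- matrix(
    c(sum(obs_hit), sum(!obs_hit), sum(null_hit), sum(!null_hit)),
    nrow = 2L, byrow = TRUE,
    dimnames = list(c("observed", "shuffled"), c("g4_near", "no_g4"))
  )
  list(table = tab, p_value = fisher_exact_2x2(tab),
       observed_frac = mean(obs_hit), null_frac = mean(null_hit))
}

#' Mann-Whitney U test
#'
#' Exact p-value for small untied samples (`n_a + n_b <= 12`), normal
#' approximation with tie correction (and continuity correction) otherwise.
#'
#' @param values_a,values_b non-empty numeric vectors.
#' @param alternative `"two.sided"`, `"greater"` (a tends larger) or
#'   `"less"`.
#' @return List with `U` (number of (a, b) pairs with a > b, ties counted
#'   1/2), `p_value`, `method`.
#' @examples
#' mwu_test(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
mwu_test <- function(values_a, values_b,
                     alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(values_a) || !length(values_b)) stop_param("both samples must be non-empty")
  small <- length(values_a) + length(values_b) <= 12L
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  wt <- stats::wilcox.test(values_a, values_b, alternative = alternative,
                           exact = small && !ties, correct = TRUE)
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = if (small && !ties) "exact" else "normal approximation with tie correction")
}
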