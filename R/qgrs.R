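# Quadruplex-forming G-rich sequence (QGRS) enumeration and scoring.
# A motif is G_x N_y1 G_x N_y2 G_x N_y3 G_x: four equal-length runs of >= 2
# guanines separated by loops of >= 1 base (loops may themselves contain G),
# with total length 4x + y1 + y2 + y3 <= L_max.

#' Score a QGRS motif
#'
#' `S = 20 * (x - 2) + (L_max - len) - (|y1-y2| + |y1-y3| + |y2-y3|)`:
#' more stacked tetrads score higher, shorter motifs score higher, and even
#' loop lengths score higher than skewed ones.
#'
#' @param x G-run length (>= 2).
#' @param y1,y2,y3 loop lengths (>= 1).
#' @param L_max maximum motif length (default 30).
#' @return Integer score (can be negative for very skewed loops).
#' @examples
#' qgrs_score(3, 1, 1, 1)  # 35
#' @export
qgrs_score <- function(x, y1, y2, y3, L_max = 30L) {
  len <- 4L * x + y1 + y2 + y3
  20L * (x - 2L) + (L_max - len) -
    (abs(y1 - y2) + abs(y1 - y3) + abs(y2 - y3))
}

#' Enumerate all QGRS motifs in a sequence
#'
#' Exhaustive enumeration of every (start, x, y1, y2, y3) satisfying the
#' QGRS pattern with loops >= 1 and total length <= `L_max`; overlapping
#' motifs are all reported. G runs of length x may themselves sit inside
#' longer G tracts, and loops may contain G.
#'
#' @param seq character scalar over A/C/G/T/N.
#' @param L_max maximum motif length (default 30).
#' @param x_min minimum G-run length (default 2).
#' @return data.frame with `start` (0-based offset), `x`, `y1`, `y2`, `y3`,
#'   `length`, `score`, ordered by start then length. Empty for sequences
#'   without a motif (including sequences shorter than `4 * x_min + 3`).
#' @examples
#' find_qgrs("GGGTGGGTGGGTGGG")
#' @export
find_qgrs <- function(seq, L_max = 30L, x_min = 2L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop_param("sequence contains characters outside A/C/G/T/N")
  n <- nchar(seq)
  out <- list()
  if (n >= 4L * x_min + 3L) {
    isg <- strsplit(seq, "")[[1L]] == "G"
    gcum <- c(0L, cumsum(isg))
    x_max <- (L_max - 3L) %/% 4L
    for (x in x_min:x_max) {
      if (4L * x + 3L > n) break
      starts <- which(gcum[(1L + x):(n + 1L)] - gcum[1L:(n + 1L - x)] == x)
      if (length(starts) < 4L) next
      for (a1 in seq_along(starts)) {
        i1 <- starts[a1]
        hi4 <- i1 + L_max - x          # max allowed i4
        c2 <- starts[starts >= i1 + x + 1L & starts <= hi4 - 2L * (x + 1L)]
        for (i2 in c2) {
          c3 <- starts[starts >= i2 + x + 1L & starts <= hi4 - (x + 1L)]
          for (i3 in c3) {
            i4 <- starts[starts >= i3 + x + 1L & starts <= hi4]
            if (!length(i4)) next
            y1 <- i2 - i1 - x; y2 <- i3 - i2 - x; y3 <- i4 - i3 - x
            out[[length(out) + 1L]] <- data.frame(
              start = i1 - 1L, x = x, y1 = y1, y2 = y2, y3 = y3,
              length = 4L * x + y1 + y2 + y3,
              score = qgrs_score(x, y1, y2, y3, L_max = L_max)
            )
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), x = integer(), y1 = integer(),
                      y2 = integer(), y3 = integer(), length = integer(),
                      score = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$length, -res$score), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Highest QGRS score in a window
#'
#' When a window contains multiple motifs only the highest-scoring one is
#' retained; ties are broken by leftmost start, then smallest total length.
#'
#' @param window_seq character scalar (typically a 400 nt stalling-site
#'   window).
#' @param L_max,x_min passed to [find_qgrs()].
#' @return One-row data.frame describing the retained motif, or `NULL` when
#'   the window contains no motif.
#' @export
max_qgrs <- function(window_seq, L_max = 30L, x_min = 2L) {
  m <- find_qgrs(window_seq, L_max = L_max, x_min = x_min)
  if (!nrow(m)) return(NULL)
  m <- m[order(-m$score, m$start, m$length), , drop = FALSE]
  m[1L, , drop = FALSE]
}
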