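#' Configure an in vitro RNase R digestion
#'
#' Captures the reaction conditions of a single digestion: the monovalent
#' cation in the buffer (K+ stabilizes G-quadruplexes; Na+/Li+ do not), an
#' optional prior A-tailing step (E-PAP), the incubation time, and the kinetic
#' and geometric parameters of the digestion model.
#'
#' Digestion initiation follows a single-exponential model: the fraction of
#' molecules engaged after `incubation_min` minutes is
#' `1 - exp(-rate_k[cation] * incubation_min * r)`, where `r = 1` when the
#' effective 3' overhang is at least `overhang_opt` nt (optimal binding),
#' `r = 0.5` for sub-optimal overhangs between `overhang_min` and
#' `overhang_opt`, and molecules with shorter overhangs are not engaged at
#' all. A-tailing adds a geometric tail of mean `tail_mean` nt to the
#' overhang.
#'
#' @param cation one of `"K"`, `"Na"`, `"Li"`.
#' @param atailed was the RNA A-tailed (E-PAP) before digestion?
#' @param incubation_min incubation time in minutes (> 0; 15 and 90 are the
#'   typical short/long reactions).
#' @param rate_k per-minute digestion initiation rate for each cation; the
#'   default keeps `rate_k["K"] >= rate_k["Na"] >= rate_k["Li"]` (digestion is
#'   less efficient in NaCl/LiCl buffer).
#' @param overhang_min minimum single-stranded 3' overhang (nt) RNase R needs
#'   to engage a substrate (default 7).
#' @param overhang_opt overhang length (nt) for optimal binding and activity
#'   (default 10).
#' @param tail_mean mean A-tail length (nt) added when `atailed`.
#' @param footprint nt left 3' of a stalled position (enzyme footprint).
#' @param jitter_sd sd (nt) of Gaussian noise on stalled fragment 3' ends.
#' @param seed optional seed for the stochastic parts (tail length, jitter);
#'   `NULL` draws from the surrounding RNG stream.
#' @return A `digestion_config` list.
#' @examples
#' digestion_config(cation = "Li", incubation_min = 90)
#' @export
digestion_config <- function(cation = c("K", "Na", "Li"), atailed = FALSE,
                             incubation_min = 15,
                             rate_k = c(K = 0.2, Na = 0.05, Li = 0.05),
                             overhang_min = 7L, overhang_opt = 10L,
                             tail_mean = 50, footprint = 5L, jitter_sd = 10,
                             seed = NULL) {
  cation <- match.arg(cation)
  if (incubation_min < 0) stop_param("incubation_min must be >= 0")
  if (!all(c("K", "Na", "Li") %in% names(rate_k))) {
    stop_param("rate_k must be named with K, Na, Li")
  }
  if (any(rate_k < 0)) stop_param("rate_k must be non-negative")
  if (!(rate_k["K"] >= rate_k["Na"] && rate_k["Na"] >= rate_k["Li"])) {
    warning("rate_k does not satisfy K >= Na >= Li; proceeding as given")
  }
  if (overhang_min >= overhang_opt) stop_param("overhang_min must be < overhang_opt")
  if (tail_mean <= 0) stop_param("tail_mean must be > 0")
  if (footprint < 0) stop_param("footprint must be >= 0")
  if (jitter_sd < 0) stop_param("jitter_sd must be >= 0")
  structure(
    list(cation = cation, atailed = isTRUE(atailed),
         incubation_min = incubation_min, rate_k = rate_k,
         overhang_min = as.integer(overhang_min),
         overhang_opt = as.integer(overhang_opt), tail_mean = tail_mean,
         footprint = as.integer(footprint), jitter_sd = jitter_sd,
         seed = seed),
    class = "digestion_config"
  )
}

#' Mock-digestion (control) configuration
#'
#' The "- RNase R" control: the same buffer incubation with the enzyme
#' omitted, modelled as zero initiation rate.
#'
#' @param ... passed on to [digestion_config()].
#' @export
control_config <- function(...) {
  digestion_config(rate_k = c(K = 0, Na = 0, Li = 0), ...)
}

#' Simulate RNase R digestion of one transcript
#'
#' Applies the 3'->5' exonucleolytic digestion model to a transcript and
#' returns the population of surviving (fully or partially digested)
#' molecules as weighted fragments in transcript coordinates.
#'
#' Rules, in order:
#' \itemize{
#'   \item Circular transcripts (exonic circRNA, intronic ciRNA) have no 3'
#'     end and are returned intact at full weight.
#'   \item Linear transcripts whose effective overhang (annotated overhang
#'     plus sampled A-tail when `cfg$atailed`) is below `cfg$overhang_min`
#'     are returned intact — this is what protects snRNA/histone-like
#'     structured 3' ends absent tailing.
#'   \item Otherwise a fraction `1 - exp(-k * t * r)` of molecules is engaged.
#'     Engaged molecules meet G4 elements 3'->5'; each stalls with the
#'     element's cation-specific probability, leaving a fragment that ends
#'     `footprint` nt past the element (plus Gaussian jitter, clipped to the
#'     transcript). Molecules passing every element are degraded completely
#'     and removed (library size selection discards the limit products).
#' }
#'
#' @param tm a `transcript_model`.
#' @param cfg a [digestion_config()].
#' @return A `fragment_population`: list with `transcript_id`, `fragments`
#'   (data.frame `tx_start`, `tx_end`, `weight`), `survival` (surviving
#'   weight / abundance), and `stall_ends` (realized 3' ends per G4 element,
#'   NA where no stall occurred).
#' @examples
#' tm <- build_transcriptome(4, class_mix = c(g4_mRNA = 1), seed = 2)$transcripts[[1]]
#' simulate_digestion(tm, digestion_config(incubation_min = 90, seed = 1))
#' @export
simulate_digestion <- function(tm, cfg = digestion_config()) {
  stopifnot(inherits(tm, "transcript_model"), inherits(cfg, "digestion_config"))
  with_seed(cfg$seed, {
    L <- tx_length(tm)
    a <- tm$abundance
    full <- data.frame(tx_start = 0L, tx_end = L, weight = a)
    stall_ends <- rep(NA_integer_, nrow(tm$g4_elements))

    if (tm$topology != "linear") {
      return(new_fragment_population(tm$transcript_id, full, a, stall_ends))
    }

    eff_overhang <- tm$overhang_len
    if (cfg$atailed) {
      eff_overhang <- eff_overhang + stats::rgeom(1L, 1 / (cfg$tail_mean + 1))
    }
    if (eff_overhang < cfg$overhang_min) {
      return(new_fragment_population(tm$transcript_id, full, a, stall_ends))
    }
    r <- if (eff_overhang >= cfg$overhang_opt) 1 else 0.5
    f <- 1 - exp(-unname(cfg$rate_k[cfg$cation]) * cfg$incubation_min * r)

    frags <- list()
    if (f < 1) {
      frags[[1L]] <- data.frame(tx_start = 0L, tx_end = L, weight = (1 - f) * a)
    }
    if (f > 0 && nrow(tm$g4_elements)) {
      ord <- order(tm$g4_elements$tx_position, decreasing = TRUE)
      pcol <- paste0("stall_prob_", cfg$cation)
      remaining <- f * a
      for (j in ord) {
        p <- tm$g4_elements[[pcol]][j]
        w <- remaining * p
        if (w > 0) {
          end <- tm$g4_elements$tx_position[j] + cfg$footprint +
            as.integer(round(stats::rnorm(1L, 0, cfg$jitter_sd)))
          end <- max(1L, min(L, as.integer(end)))
          frags[[length(frags) + 1L]] <-
            data.frame(tx_start = 0L, tx_end = end, weight = w)
          stall_ends[j] <- end
        }
        remaining <- remaining * (1 - p)
      }
      # `remaining` passed every element and is degraded completely
    }
    fragments <- if (length(frags)) do.call(rbind, frags) else
      data.frame(tx_start = integer(), tx_end = integer(), weight = numeric())
    new_fragment_population(tm$transcript_id, fragments, a, stall_ends)
  })
}

new_fragment_population <- function(transcript_id, fragments, abundance, stall_ends) {
  survival <- if (abundance > 0) sum(fragments$weight) / abundance else 0
  structure(
    list(transcript_id = transcript_id, fragments = fragments,
         survival = survival, stall_ends = stall_ends),
    class = "fragment_population"
  )
}

#' @export
print.fragment_population <- function(x, ...) {
  cat(sprintf("<fragment_population> %s: %d fragment(s), survival %.3f\n",
              x$transcript_id, nrow(x$fragments), x$survival))
  if (nrow(x$fragments)) print(x$fragments)
  invisible(x)
}
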