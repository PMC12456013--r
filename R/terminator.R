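#' Intrinsic-terminator features at transcript 3' ends
#'
#' For every TEP computes the hallmarks of factor-independent terminators:
#' `u_fraction`, the U (T on the coding strand) fraction of the 8 nt ending
#' at the TEP; and the best stem-loop in the `search_len` nt upstream of the
#' TEP, found by exhaustive enumeration of loop placements with outward
#' stem extension. Paired bases score GC = 3, AU = 2, GU = 1; a stem shorter
#' than `stem_min` does not count (score 0). Windows truncated at the genome
#' start are flagged and processed as-is.
#'
#' @param tep_sites Tibble with `site_id`, `position`, `strand`.
#' @param genome A `txa_genome`.
#' @param stem_min Minimum stem length (bp) for a hairpin call.
#' @param loop_range Allowed loop lengths `c(min, max)` (nt).
#' @param search_len Window (nt) upstream of the TEP searched for the stem.
#' @return Tibble: `site_id`, `u_fraction`, `stem_len`, `loop_len`,
#'   `hairpin_score`, `truncated`.
#' @export
terminator_features <- function(tep_sites, genome, stem_min = 5L,
                                loop_range = c(3L, 10L), search_len = 60L) {
  rows <- lapply(seq_len(nrow(tep_sites)), function(i) {
    pos <- tep_sites$position[i]
    strand <- tep_sites$strand[i]
    if (strand == "+") {
      u_seq <- genome_window(genome, pos - 7L, pos, "+")
      win <- genome_window(genome, pos - search_len + 1L, pos, "+")
    } else {
      u_seq <- genome_window(genome, pos, pos + 7L, "-")
      win <- genome_window(genome, pos, pos + search_len - 1L, "-")
    }
    hp <- best_hairpin(win, stem_min, loop_range)
    tibble(site_id = tep_sites$site_id[i],
           u_fraction = if (nchar(u_seq)) {
             mean(strsplit(u_seq, "")[[1]] == "T")
           } else NA_real_,
           stem_len = hp$stem_len, loop_len = hp$loop_len,
           hairpin_score = hp$score,
           truncated = nchar(win) < search_len | nchar(u_seq) < 8L)
  })
  dplyr::bind_rows(rows)
}

pair_score_tab <- local({
  tab <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  tab["G", "C"] <- tab["C", "G"] <- 3
  tab["A", "T"] <- tab["T", "A"] <- 2
  tab["G", "T"] <- tab["T", "G"] <- 1
  tab
})

# Best-scoring contiguous stem-loop in a window: enumerate every loop
# placement and length, extend the stem outwards while bases pair, keep the
# max. Equivalent to brute force over all contiguous fully paired stems.
best_hairpin <- function(window, stem_min, loop_range) {
  code <- match(strsplit(window, "")[[1]], BASES)
  n <- length(code)
  best <- list(score = 0, stem_len = 0L, loop_len = 0L)
  if (n < 2L * stem_min + loop_range[1]) return(best)
  for (l in seq(loop_range[1], loop_range[2])) {
    for (i in seq_len(max(0L, n - l - 1L))) {
      # innermost pair: positions i and i + l + 1
      left <- i
      right <- i + l + 1L
      score <- 0
      stem <- 0L
      while (left >= 1L && right <= n &&
             !is.na(code[left]) && !is.na(code[right])) {
        s <- pair_score_tab[code[left], code[right]]
        if (s == 0) break
        score <- score + s
        stem <- stem + 1L
        left <- left - 1L
        right <- right + 1L
      }
      if (stem >= stem_min && score > best$score) {
        best <- list(score = score, stem_len = stem, loop_len = l)
      }
    }
  }
  best
}
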