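#' Classify merged TSSs relative to annotated genes
#'
#' Each gene collects same-strand TSSs from `tss_upstream_nt` upstream to
#' `tss_downstream_nt` downstream of its 5' end (strand-aware); a TSS falling
#' in the window of several genes is assigned to the gene with the nearest
#' 5' end (ties to the lower start coordinate). Within a gene the
#' highest site is the primary (P) TSS and the rest are secondary (S); ties
#' go to the site closest to the gene 5' end, then the 5'-most. Sites
#' assigned to no gene are internal (I) when inside a sense-strand gene
#' body, antisense (A) when within a gene body or its
#' `antisense_flank_nt` flank on the opposite strand, else intergenic (N).
#' Precedence is P/S > I > A > N; every site receives exactly one category.
#'
#' @param sites Merged TSS tibble from [merge_sites()].
#' @param annotation A `txa_annotation`.
#' @param params A [classification_params()] object.
#' @return The input tibble with `category`, `gene` and `utr_len` columns
#'   (`utr_len` is the 5'-UTR length, defined for P/S sites).
#' @export
classify_tss <- function(sites, annotation, params = classification_params()) {
  classify_sites(sites, annotation, params, site_class = "TSS",
                 tss_annotated = NULL)
}

#' Classify merged TEPs relative to annotated genes
#'
#' Mirrors [classify_tss()] on the 3' side: each gene collects same-strand
#' TEPs within `tep_downstream_nt` downstream of its 3' end; the highest is
#' primary, the rest secondary. Remaining TEPs lying on a gene's sense
#' strand strictly between that gene's primary TSS and its 5' end (i.e.
#' inside the 5'-UTR) are cis-regulatory (C) — the signature of
#' riboswitch-style premature termination. The rest are I/A/N as for TSSs,
#' with precedence P/S > C > I > A > N.
#'
#' @param sites Merged TEP tibble.
#' @param annotation A `txa_annotation`.
#' @param tss_annotated Output of [classify_tss()]; supplies the primary
#'   TSSs that anchor C calls. Genes without a primary TSS cannot yield C
#'   sites.
#' @param params A [classification_params()] object.
#' @return The input tibble with `category`, `gene` and `utr_len` (3'-UTR
#'   length for P/S sites) columns.
#' @export
classify_tep <- function(sites, annotation, tss_annotated = NULL,
                         params = classification_params()) {
  classify_sites(sites, annotation, params, site_class = "TEP",
                 tss_annotated = tss_annotated)
}

classify_sites <- function(sites, annotation, params, site_class,
                           tss_annotated) {
  sites <- as_tibble(sites)
  n <- nrow(sites)
  category <- rep(NA_character_, n)
  gene <- rep(NA_character_, n)
  utr_len <- rep(NA_integer_, n)
  if (n == 0L) {
    return(dplyr::mutate(sites, category = character(0),
                         gene = character(0), utr_len = integer(0)))
  }
  sgn_gene <- strand_sign(annotation$strand)
  anchor <- if (site_class == "TSS") annotation$five_prime else
    annotation$three_prime
  win_lo <- if (site_class == "TSS") -params$tss_downstream_nt else 0L
  win_hi <- if (site_class == "TSS") params$tss_upstream_nt else
    params$tep_downstream_nt
  # distance convention: for TSS, dist = how far upstream of the gene 5' end
  # the site lies; for TEP, dist = how far downstream of the gene 3' end.
  assigned_gene <- integer(n)   # row index into annotation, 0 = none
  assigned_dist <- numeric(n)
  for (i in seq_len(n)) {
    pos <- sites$position[i]
    same <- annotation$strand == sites$strand[i]
    d <- (anchor - pos) * sgn_gene
    if (site_class == "TEP") d <- -d
    cand <- which(same & d >= win_lo & d <= win_hi)
    if (length(cand)) {
      dd <- abs(anchor[cand] - pos)
      best <- cand[order(dd, annotation$start[cand])][1]
      assigned_gene[i] <- best
      assigned_dist[i] <- d[match(best, seq_len(nrow(annotation)))]
    }
  }
  # primary/secondary per gene
  for (g in unique(assigned_gene[assigned_gene > 0])) {
    idx <- which(assigned_gene == g)
    five_most <- sites$position[idx] *
      strand_sign(annotation$strand[g]) *
      if (site_class == "TSS") 1 else -1
    ord <- order(-sites$height_rpm[idx],
                 abs(anchor[g] - sites$position[idx]),
                 five_most)
    idx <- idx[ord]
    category[idx[1]] <- "P"
    if (length(idx) > 1L) category[idx[-1]] <- "S"
    gene[idx] <- annotation$locus_tag[g]
    utr_len[idx] <- pmax(0L, as.integer(round(assigned_dist[idx])))
  }
  rest <- which(is.na(category))
  # cis-regulatory TEPs inside 5'-UTRs delimited by primary TSSs
  if (site_class == "TEP" && !is.null(tss_annotated) && length(rest)) {
    prim <- tss_annotated[tss_annotated$category %in% "P", , drop = FALSE]
    for (i in rest) {
      pos <- sites$position[i]
      for (j in seq_len(nrow(prim))) {
        g <- match(prim$gene[j], annotation$locus_tag)
        if (is.na(g) || annotation$strand[g] != sites$strand[i]) next
        tss_pos <- prim$position[j]
        fp <- annotation$five_prime[g]
        inside <- if (annotation$strand[g] == "+") {
          pos > tss_pos && pos < fp
        } else {
          pos < tss_pos && pos > fp
        }
        if (inside) {
          category[i] <- "C"
          gene[i] <- annotation$locus_tag[g]
          break
        }
      }
    }
    rest <- which(is.na(category))
  }
  for (i in rest) {
    pos <- sites$position[i]
    same <- annotation$strand == sites$strand[i]
    in_body <- annotation$start <= pos & pos <= annotation$end
    if (any(same & in_body)) {
      category[i] <- "I"
      gene[i] <- annotation$locus_tag[which(same & in_body)[1]]
    } else {
      fl <- params$antisense_flank_nt
      in_flank <- (annotation$start - fl) <= pos & pos <= (annotation$end + fl)
      if (any(!same & in_flank)) {
        category[i] <- "A"
        gene[i] <- annotation$locus_tag[which(!same & in_flank)[1]]
      } else {
        category[i] <- "N"
      }
    }
  }
  dplyr::mutate(sites, category = category, gene = gene, utr_len = utr_len)
}

#' UTR length summaries and leaderless counts
#'
#' 5'-UTR lengths are taken from primary TSSs and 3'-UTR lengths from
#' primary TEPs. Transcripts with a 5'-UTR of at most
#' `leaderless_max_utr_nt` (default 10 nt) are leaderless. Histograms use
#' 10-nt bins `[0-9], [10-19], ...`.
#'
#' @param tss_annotated Output of [classify_tss()] (or `NULL`).
#' @param tep_annotated Output of [classify_tep()] (or `NULL`).
#' @param params A [classification_params()] object.
#' @return A `txa_utr_summary` list with elements `five` and `three`, each
#'   holding `n`, `median`, `histogram` (tibble `bin_start`, `bin_end`,
#'   `count`) and, for `five`, `leaderless_count`/`leadered_count`.
#' @export
utr_stats <- function(tss_annotated = NULL, tep_annotated = NULL,
                      params = classification_params()) {
  one <- function(ann, leaderless_cut = NULL) {
    if (is.null(ann)) return(NULL)
    lens <- ann$utr_len[ann$category %in% "P" & !is.na(ann$utr_len)]
    if (length(lens) == 0L) {
      return(list(n = 0L, median = NA_real_,
                  histogram = tibble(bin_start = integer(),
                                     bin_end = integer(), count = integer())))
    }
    bins <- seq(0L, max(lens) - max(lens) %% 10L, by = 10L)
    hist <- tibble(
      bin_start = bins, bin_end = bins + 9L,
      count = vapply(bins, function(b) sum(lens >= b & lens <= b + 9L),
                     integer(1))
    )
    res <- list(n = length(lens), median = median(lens), histogram = hist)
    if (!is.null(leaderless_cut)) {
      res$leaderless_count <- sum(lens <= leaderless_cut)
      res$leadered_count <- sum(lens > leaderless_cut)
    }
    res
  }
  structure(list(
    five = one(tss_annotated, params$leaderless_max_utr_nt),
    three = one(tep_annotated)
  ), class = "txa_utr_summary")
}

#' Nucleotide composition around site positions
#'
#' Strand-aware base frequencies at offsets -2..+2 around each site (+1 is
#' the site position itself; minus-strand sites read the reverse
#' complement). Sites too close to a genome end for the full window are
#' skipped and counted in the `n_skipped` attribute.
#'
#' @param sites Tibble with `position` and `strand`.
#' @param genome A `txa_genome`.
#' @param offsets Integer offsets relative to the site (+1); 0 is not a
#'   position in this convention and is not allowed.
#' @return Tibble `offset`, `A`, `C`, `G`, `T` (rows sum to 1), with
#'   attributes `n_sites` and `n_skipped`.
#' @export
composition <- function(sites, genome, offsets = c(-2L, -1L, 1L, 2L)) {
  if (nrow(sites) == 0L) abort("no sites supplied")
  if (any(offsets == 0L)) abort("offset 0 is not defined; +1 is the site")
  offsets <- sort(unique(c(offsets, 1L)))
  sgn <- strand_sign(sites$strand)
  # offset k (k>0 downstream of +1): genomic shift (k - 1) positions, since
  # +1 is the site itself and there is no offset 0
  shift <- function(k) ifelse(k > 0, k - 1L, k)
  # restrict to sites with the full window available
  full_ok <- rep(TRUE, nrow(sites))
  for (k in offsets) {
    at <- sites$position + shift(k) * sgn
    full_ok <- full_ok & at >= 1L & at <= genome$length
  }
  rows <- lapply(offsets, function(k) {
    at <- sites$position[full_ok] + shift(k) * sgn[full_ok]
    bases <- substring(genome$seq, at, at)
    bases <- ifelse(sites$strand[full_ok] == "-",
                    chartr("ACGT", "TGCA", bases), bases)
    counts <- table(factor(bases, levels = c("A", "C", "G", "T")))
    tibble(offset = k,
           A = counts[["A"]] / sum(counts), C = counts[["C"]] / sum(counts),
           G = counts[["G"]] / sum(counts), T = counts[["T"]] / sum(counts))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_sites") <- sum(full_ok)
  attr(out, "n_skipped") <- sum(!full_ok)
  class(out) <- c("txa_composition", class(out))
  out
}

#' Ribosome-binding-site scan of leadered 5'-UTRs
#'
#' For every leadered primary/secondary transcript (5'-UTR >=
#' `leaderless_max_utr_nt`), scans the `rbs_search_nt` nt immediately
#' upstream of the start codon with an AG-rich RBS PWM and reports the best
#' placement; a UTR is a hit when the best score's exact p-value is at or
#' below `pvalue_threshold`.
#'
#' @param tss_annotated Output of [classify_tss()].
#' @param annotation A `txa_annotation`.
#' @param genome A `txa_genome`.
#' @param rbs_pwm A [pwm()] (default: Shine-Dalgarno-like AGGAGG consensus).
#' @param params A [classification_params()] object.
#' @param pvalue_threshold Hit cutoff on the exact PWM p-value.
#' @return A list: `fraction` of scanned UTRs with a hit, and `per_utr`
#'   tibble (`site_id`, `gene`, `best_score`, `pvalue`, `hit`).
#' @export
rbs_scan <- function(tss_annotated, annotation, genome,
                     rbs_pwm = consensus_pwm("AGGAGG"),
                     params = classification_params(),
                     pvalue_threshold = 1e-3) {
  keep <- tss_annotated$category %in% c("P", "S") &
    !is.na(tss_annotated$utr_len) &
    tss_annotated$utr_len >= params$leaderless_max_utr_nt
  cand <- tss_annotated[keep, , drop = FALSE]
  dist <- score_distribution(rbs_pwm)
  rows <- purrr::pmap(list(cand$site_id, cand$gene), function(sid, g) {
    gi <- match(g, annotation$locus_tag)
    fp <- annotation$five_prime[gi]
    win <- if (annotation$strand[gi] == "+") {
      genome_window(genome, fp - params$rbs_search_nt, fp - 1L, "+")
    } else {
      genome_window(genome, fp + 1L, fp + params$rbs_search_nt, "-")
    }
    if (nchar(win) < rbs_pwm$width) return(NULL)
    sc <- score_positions(win, rbs_pwm)
    best <- max(sc)
    pv <- pvalue_from_distribution(dist, best)
    tibble(site_id = sid, gene = g, best_score = best, pvalue = pv,
           hit = pv <= pvalue_threshold)
  })
  per_utr <- dplyr::bind_rows(rows)
  list(fraction = if (nrow(per_utr)) mean(per_utr$hit) else NA_real_,
       per_utr = per_utr)
}
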