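#' Peak-calling parameters
#'
#' Thresholds for calling single-nucleotide 5'-end (TSS) and 3'-end (TEP)
#' peaks. The TEX+/TEX- enrichment test applies to TSS calling only. The
#' coverage-support filter is an automated surrogate for manual curation of
#' candidate peaks against RNA-seq profiles: a TSS must show at least
#' `downstream_support_min_cov` RPM mean RNA-seq coverage over the
#' `downstream_support_len` nt downstream (upstream for a TEP).
#'
#' @param min_height_rpm Minimum normalized 5'/3'-end height (RPM).
#' @param enrichment_min Minimum TEX+/TEX- ratio at a TSS.
#' @param pseudocount Read count added to both ratio terms before
#'   normalization.
#' @param local_max_window Radius (nt) of the strict local-maximum test.
#' @param replicate_min_fraction Fraction of replicate (pairs) that must pass
#'   all tests at a position.
#' @param downstream_support_len Length (nt) of the coverage-support window;
#'   set `downstream_support_min_cov = 0` to disable the filter.
#' @param downstream_support_min_cov Minimum mean RNA-seq coverage (RPM) in
#'   the support window.
#' @return A `txa_peak_params` list.
#' @export
peak_call_params <- function(min_height_rpm = 1.5,
                             enrichment_min = 2.0,
                             pseudocount = 1,
                             local_max_window = 2L,
                             replicate_min_fraction = 0.5,
                             downstream_support_len = 50L,
                             downstream_support_min_cov = 1.0) {
  stopifnot(min_height_rpm > 0, enrichment_min > 0, pseudocount > 0,
            local_max_window >= 0,
            replicate_min_fraction > 0, replicate_min_fraction <= 1,
            downstream_support_len > 0, downstream_support_min_cov >= 0)
  structure(list(
    min_height_rpm = min_height_rpm,
    enrichment_min = enrichment_min,
    pseudocount = pseudocount,
    local_max_window = as.integer(local_max_window),
    replicate_min_fraction = replicate_min_fraction,
    downstream_support_len = as.integer(downstream_support_len),
    downstream_support_min_cov = downstream_support_min_cov
  ), class = "txa_peak_params")
}

#' Site-merging parameters
#'
#' @param tolerance_nt Merge radius in nt; peaks whose positions differ by at
#'   most this (transitively, single linkage) collapse to one site.
#' @return A `txa_merge_params` list.
#' @export
merge_params <- function(tolerance_nt = 5L) {
  stopifnot(tolerance_nt >= 0)
  structure(list(tolerance_nt = as.integer(tolerance_nt)),
            class = "txa_merge_params")
}

#' Site-classification parameters
#'
#' Windows (nt) used to place merged sites relative to annotated genes, the
#' leaderless 5'-UTR cutoff, and the RBS search length upstream of start
#' codons.
#'
#' @param tss_upstream_nt,tss_downstream_nt Primary/secondary TSS window
#'   around gene 5' ends.
#' @param tep_downstream_nt Primary/secondary TEP window downstream of gene
#'   3' ends.
#' @param antisense_flank_nt Flank added to gene bodies for antisense calls.
#' @param leaderless_max_utr_nt Maximum 5'-UTR of a leaderless mRNA.
#' @param rbs_search_nt Window upstream of the start codon scanned for an RBS.
#' @return A `txa_class_params` list.
#' @export
classification_params <- function(tss_upstream_nt = 300L,
                                  tss_downstream_nt = 100L,
                                  tep_downstream_nt = 300L,
                                  antisense_flank_nt = 100L,
                                  leaderless_max_utr_nt = 10L,
                                  rbs_search_nt = 20L) {
  p <- list(tss_upstream_nt = tss_upstream_nt,
            tss_downstream_nt = tss_downstream_nt,
            tep_downstream_nt = tep_downstream_nt,
            antisense_flank_nt = antisense_flank_nt,
            leaderless_max_utr_nt = leaderless_max_utr_nt,
            rbs_search_nt = rbs_search_nt)
  stopifnot(all(unlist(p) >= 0))
  structure(lapply(p, as.integer), class = "txa_class_params")
}

#' Transcription-unit assembly parameters
#'
#' @param min_cov_rpm Coverage (RPM) a position needs to count as supported.
#' @param min_support_fraction Minimum fraction of supported positions across
#'   the TSS-TEP span.
#' @param max_gap_nt Longest tolerated run of sub-threshold coverage.
#' @param max_len_nt Cap on the TSS-TEP distance.
#' @param pairing `"nearest"` pairs each TSS with its nearest downstream TEP;
#'   `"all"` considers every downstream TEP within `max_len_nt`.
#' @param stranded_clusters Whether TU clustering requires same-strand
#'   overlap.
#' @return A `txa_tu_params` list.
#' @export
tu_params <- function(min_cov_rpm = 1.0,
                      min_support_fraction = 0.8,
                      max_gap_nt = 50L,
                      max_len_nt = 15000L,
                      pairing = c("nearest", "all"),
                      stranded_clusters = TRUE) {
  pairing <- match.arg(pairing)
  stopifnot(min_cov_rpm > 0, min_support_fraction > 0,
            min_support_fraction <= 1, max_gap_nt >= 0, max_len_nt > 0)
  structure(list(
    min_cov_rpm = min_cov_rpm,
    min_support_fraction = min_support_fraction,
    max_gap_nt = as.integer(max_gap_nt),
    max_len_nt = as.integer(max_len_nt),
    pairing = pairing,
    stranded_clusters = isTRUE(stranded_clusters)
  ), class = "txa_tu_params")
}

#' Gibbs motif-discovery parameters
#'
#' @param width Motif width (nt).
#' @param iterations Sampling sweeps per restart.
#' @param restarts Independent restarts; the best-scoring state wins.
#' @param seed Integer seed; the sampler is bit-reproducible given it.
#' @param zoops_prior Prior probability that a sequence carries one site
#'   (zero-or-one-occurrence-per-sequence model).
#' @param pwm_pseudocount Pseudocount per base in PWM re-estimation.
#' @return A `txa_gibbs_params` list.
#' @export
gibbs_params <- function(width = 6L, iterations = 200L, restarts = 5L,
                         seed = 1L, zoops_prior = 0.9,
                         pwm_pseudocount = 0.5) {
  stopifnot(width >= 3, iterations >= 1, restarts >= 1,
            zoops_prior > 0, zoops_prior <= 1, pwm_pseudocount > 0)
  structure(list(width = as.integer(width),
                 iterations = as.integer(iterations),
                 restarts = as.integer(restarts),
                 seed = as.integer(seed),
                 zoops_prior = zoops_prior,
                 pwm_pseudocount = pwm_pseudocount),
            class = "txa_gibbs_params")
}
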