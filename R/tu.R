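#' Assemble transcription units from classified TSSs and TEPs
#'
#' Every classified TSS seeds at most one transcription unit: the nearest
#' same-strand TEP downstream within `max_len_nt` is taken (with
#' `pairing = "all"`, every such TEP is tried in downstream order and each
#' supported pair is kept). A TSS-TEP pair becomes a
#' TU when the RNA-seq profile supports the span: at least
#' `min_support_fraction` of span positions carry >= `min_cov_rpm` coverage
#' and no sub-threshold run exceeds `max_gap_nt`. Gene content lists the
#' sense-strand genes fully contained in the span; antisense/intergenic TUs
#' simply carry empty gene lists.
#'
#' @param tss_annotated Output of [classify_tss()].
#' @param tep_annotated Output of [classify_tep()].
#' @param coverage RNA-seq `txa_signal` from the matching condition.
#' @param annotation A `txa_annotation`.
#' @param params A [tu_params()] object.
#' @return Tibble of TUs: `tu_id`, `tss_ref`, `tep_ref`, `strand`, `start`,
#'   `end`, `length`, `support_fraction`, `genes` (list column), sorted by
#'   span start.
#' @export
assemble_tus <- function(tss_annotated, tep_annotated, coverage, annotation,
                         params = tu_params()) {
  rows <- list()
  cov_rpm <- list("+" = coverage$plus * rpm_factor(coverage),
                  "-" = coverage$minus * rpm_factor(coverage))
  len <- length(coverage$plus)
  if (any(annotation$end > len)) {
    abort("coverage vector shorter than annotation extent")
  }
  for (i in seq_len(nrow(tss_annotated))) {
    tss <- tss_annotated[i, ]
    sgn <- strand_sign(tss$strand)
    cand <- tep_annotated[tep_annotated$strand == tss$strand, , drop = FALSE]
    d <- (cand$position - tss$position) * sgn
    cand <- cand[d > 0 & d <= params$max_len_nt, , drop = FALSE]
    if (nrow(cand) == 0L) next
    cand <- cand[order((cand$position - tss$position) * sgn), , drop = FALSE]
    n_take <- if (params$pairing == "nearest") 1L else nrow(cand)
    for (j in seq_len(n_take)) {
      tep <- cand[j, ]
      span <- sort(c(tss$position, tep$position))
      v <- cov_rpm[[tss$strand]][span[1]:span[2]]
      supported <- v >= params$min_cov_rpm
      frac <- mean(supported)
      max_gap <- longest_run(!supported)
      if (frac >= params$min_support_fraction &&
          max_gap <= params$max_gap_nt) {
        contained <- annotation$strand == tss$strand &
          annotation$start >= span[1] & annotation$end <= span[2]
        genes <- annotation$locus_tag[contained]
        if (tss$strand == "-") genes <- rev(genes)
        rows[[length(rows) + 1L]] <- tibble(
          tss_ref = tss$site_id, tep_ref = tep$site_id,
          strand = tss$strand, start = span[1], end = span[2],
          length = span[2] - span[1] + 1L,
          support_fraction = frac, genes = list(genes)
        )
        if (params$pairing == "nearest") break
      }
    }
  }
  tus <- dplyr::bind_rows(rows)
  if (nrow(tus) == 0L) {
    return(tibble(tu_id = character(), tss_ref = character(),
                  tep_ref = character(), strand = character(),
                  start = integer(), end = integer(), length = integer(),
                  support_fraction = numeric(), genes = list()))
  }
  tus <- dplyr::arrange(tus, .data$start, .data$end, .data$strand)
  tus$tu_id <- sprintf("TU_%04d", seq_len(nrow(tus)))
  dplyr::relocate(tus, "tu_id")
}

longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Group transcription units into clusters
#'
#' Single-linkage clustering of TUs that share at least 1 nt of their spans;
#' with `stranded_clusters` (the default) only same-strand overlap connects
#' two TUs. Cluster ids are ordered by leftmost span.
#'
#' @param tus Output of [assemble_tus()].
#' @param params A [tu_params()] object (only `stranded_clusters` is used).
#' @return Tibble of clusters: `cluster_id`, `strand` (or `"*"` for
#'   strandless clustering), `start`, `end`, `n_members`, `members` (list
#'   column of TU ids).
#' @export
cluster_tus <- function(tus, params = tu_params()) {
  if (nrow(tus) == 0L) {
    return(tibble(cluster_id = character(), strand = character(),
                  start = integer(), end = integer(), n_members = integer(),
                  members = list()))
  }
  groups <- if (params$stranded_clusters) split(seq_len(nrow(tus)), tus$strand)
    else list(`*` = seq_len(nrow(tus)))
  rows <- list()
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    sub <- tus[idx, , drop = FALSE]
    ord <- order(sub$start, sub$end)
    sub <- sub[ord, , drop = FALSE]
    # 1-D single linkage: sweep sorted spans, extending the open cluster
    cl <- integer(nrow(sub))
    cur <- 0L; reach <- -Inf
    for (k in seq_len(nrow(sub))) {
      if (sub$start[k] > reach) { cur <- cur + 1L; reach <- sub$end[k] }
      else reach <- max(reach, sub$end[k])
      cl[k] <- cur
    }
    for (c0 in unique(cl)) {
      m <- sub[cl == c0, , drop = FALSE]
      rows[[length(rows) + 1L]] <- tibble(
        strand = gname, start = min(m$start), end = max(m$end),
        n_members = nrow(m), members = list(m$tu_id)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$start, .data$end, .data$strand)
  out$cluster_id <- sprintf("TUC_%03d", seq_len(nrow(out)))
  dplyr::relocate(out, "cluster_id")
}
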