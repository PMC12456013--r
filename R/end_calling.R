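#' Call TSS peaks from TEX+/TEX- 5'-end tracks
#'
#' A position is a TSS peak when, in at least `replicate_min_fraction` of
#' TEX+/TEX- replicate pairs (paired by replicate index), all of the
#' following hold on its strand:
#' * normalized TEX+ 5'-end height >= `min_height_rpm`;
#' * TEX+/TEX- enrichment `(c+ + pseudocount)/(c- + pseudocount)` (counts
#'   pseudocounted before normalization) >= `enrichment_min`;
#' * the TEX+ height is the strict maximum within `local_max_window` nt
#'   (ties broken to the 5'-most position);
#' * mean RNA-seq coverage over the `downstream_support_len` nt downstream
#'   >= `downstream_support_min_cov` RPM (the automated stand-in for manual
#'   curation against coverage profiles; disabled when `coverage` is `NULL`
#'   or the threshold is zero).
#'
#' Heights and enrichments are averaged over the passing replicate pairs.
#'
#' @param tex_plus,tex_minus Lists of `txa_signal` 5'-end tracks from the
#'   same condition (TEX-treated and untreated).
#' @param coverage An RNA-seq `txa_signal`, or `NULL` to skip the support
#'   filter.
#' @param params A [peak_call_params()] object.
#' @return Tibble of peaks: `position`, `strand`, `height_rpm`,
#'   `enrichment`, `n_replicates_passing`, `condition`, `site_class`,
#'   sorted by strand then position.
#' @export
call_tss_peaks <- function(tex_plus, tex_minus, coverage = NULL,
                           params = peak_call_params()) {
  pairs <- pair_replicates(tex_plus, tex_minus)
  if (length(pairs) == 0L) abort("no TEX+/TEX- replicate pairs found")
  call_end_peaks(pairs, coverage, params, site_class = "TSS")
}

#' Call TEP peaks from Term-seq 3'-end tracks
#'
#' Same rule as [call_tss_peaks()] but with no TEX enrichment test
#' (enrichment is recorded as `NA`), local-maximum ties broken to the
#' 3'-most position, and the coverage-support window taken upstream of the
#' 3' end.
#'
#' @param termseq List of `txa_signal` 3'-end tracks (replicates of one
#'   condition).
#' @param coverage An RNA-seq `txa_signal`, or `NULL`.
#' @param params A [peak_call_params()] object.
#' @return Tibble of peaks as in [call_tss_peaks()], `site_class = "TEP"`.
#' @export
call_tep_peaks <- function(termseq, coverage = NULL,
                           params = peak_call_params()) {
  if (length(termseq) == 0L) abort("no Term-seq libraries supplied")
  pairs <- lapply(termseq, function(s) list(main = s, ref = NULL))
  call_end_peaks(pairs, coverage, params, site_class = "TEP")
}

pair_replicates <- function(tex_plus, tex_minus) {
  reps_p <- vapply(tex_plus, function(s) s$meta$replicate, integer(1))
  reps_m <- vapply(tex_minus, function(s) s$meta$replicate, integer(1))
  common <- intersect(reps_p, reps_m)
  lapply(common, function(r) {
    list(main = tex_plus[[match(r, reps_p)]],
         ref = tex_minus[[match(r, reps_m)]])
  })
}

call_end_peaks <- function(pairs, coverage, params, site_class) {
  len <- length(pairs[[1]]$main$plus)
  for (p in pairs) {
    n <- c(length(p$main$plus), if (!is.null(p$ref)) length(p$ref$plus))
    if (any(n != len)) abort("signal vector lengths differ between libraries")
  }
  if (!is.null(coverage) && length(coverage$plus) != len) {
    abort("coverage vector length differs from end tracks")
  }
  condition <- pairs[[1]]$main$meta$condition
  out <- list()
  for (strand in c("+", "-")) {
    supp_ok <- support_pass(coverage, strand, len, params, site_class)
    pass <- matrix(FALSE, nrow = len, ncol = length(pairs))
    heights <- matrix(0, nrow = len, ncol = length(pairs))
    enr <- matrix(NA_real_, nrow = len, ncol = length(pairs))
    for (k in seq_along(pairs)) {
      main <- pairs[[k]]$main
      raw <- strand_vec(main, strand)
      rpm <- raw * rpm_factor(main)
      ok <- rpm >= params$min_height_rpm
      if (!is.null(pairs[[k]]$ref)) {
        ref <- pairs[[k]]$ref
        e <- ((raw + params$pseudocount) * rpm_factor(main)) /
          ((strand_vec(ref, strand) + params$pseudocount) * rpm_factor(ref))
        ok <- ok & e >= params$enrichment_min
        enr[, k] <- e
      }
      ok <- ok & local_max(rpm, params$local_max_window, strand, site_class)
      pass[, k] <- ok & supp_ok
      heights[, k] <- rpm
    }
    frac <- rowMeans(pass)
    hit <- which(frac >= params$replicate_min_fraction & frac > 0)
    if (length(hit) == 0L) next
    h <- vapply(hit, function(i) mean(heights[i, pass[i, ]]), numeric(1))
    e_mean <- vapply(hit, function(i) {
      v <- enr[i, pass[i, ]]
      if (all(is.na(v))) NA_real_ else mean(v)
    }, numeric(1))
    out[[strand]] <- tibble(
      position = as.integer(hit),
      strand = strand,
      height_rpm = h,
      enrichment = e_mean,
      n_replicates_passing = as.integer(rowSums(pass)[hit]),
      condition = condition,
      site_class = site_class
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(position = integer(), strand = character(),
                  height_rpm = numeric(), enrichment = numeric(),
                  n_replicates_passing = integer(), condition = character(),
                  site_class = character())
  }
  dplyr::arrange(res, .data$strand, .data$position)
}

# Strict local maximum within +-w; ties resolved to the 5'-most (TSS) or
# 3'-most (TEP) of the tied run, strand-aware.
local_max <- function(rpm, w, strand, site_class) {
  if (w == 0L) return(rpm > 0)
  n <- length(rpm)
  # prefer_low: tied runs resolve to the lower coordinate
  prefer_low <- (site_class == "TSS") == (strand == "+")
  ok <- rpm > 0
  for (d in seq_len(w)) {
    lower <- c(rep(-Inf, d), rpm[seq_len(n - d)])   # value at p - d
    upper <- c(rpm[(d + 1):n], rep(-Inf, d))        # value at p + d
    if (prefer_low) {
      ok <- ok & (rpm > lower) & (rpm >= upper)
    } else {
      ok <- ok & (rpm >= lower) & (rpm > upper)
    }
  }
  ok
}

# Mean-coverage support over a window downstream of a TSS (transcript side)
# or upstream of a TEP, truncated at genome ends.
support_pass <- function(coverage, strand, len, params, site_class) {
  if (is.null(coverage) || params$downstream_support_min_cov <= 0) {
    return(rep(TRUE, len))
  }
  rpm <- strand_vec(coverage, strand) * rpm_factor(coverage)
  w <- params$downstream_support_len
  # window extends downstream for TSS, upstream for TEP -- both are the
  # transcript-body side of the end position
  towards_higher <- (site_class == "TSS") == (strand == "+")
  cs <- c(0, cumsum(rpm))
  pos <- seq_len(len)
  if (towards_higher) {
    lo <- pos
    hi <- pmin(len, pos + w - 1L)
  } else {
    lo <- pmax(1L, pos - w + 1L)
    hi <- pos
  }
  means <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  means >= params$downstream_support_min_cov
}

#' Replicate reproducibility of called end heights
#'
#' Pearson correlation of normalized heights at the called site positions,
#' for every pair of replicate libraries; pairs with zero variance are
#' excluded with a warning.
#'
#' @param replicate_signals List of >= 2 `txa_signal` replicates.
#' @param sites Peak tibble (from [call_tss_peaks()]/[call_tep_peaks()])
#'   with >= 2 rows.
#' @return A `txa_reproducibility` list: `pairs` tibble
#'   (`library_a`, `library_b`, `r`) and `median_r`.
#' @export
reproducibility <- function(replicate_signals, sites) {
  if (length(replicate_signals) < 2L) abort("need >= 2 replicate signals")
  if (nrow(sites) < 2L) abort("need >= 2 called sites")
  heights <- vapply(replicate_signals, function(s) {
    v <- numeric(nrow(sites))
    for (str in c("+", "-")) {
      idx <- sites$strand == str
      v[idx] <- strand_vec(s, str)[sites$position[idx]] * rpm_factor(s)
    }
    v
  }, numeric(nrow(sites)))
  ids <- vapply(replicate_signals, function(s) s$meta$library_id,
                character(1))
  combos <- utils::combn(seq_along(replicate_signals), 2)
  rows <- list()
  for (j in seq_len(ncol(combos))) {
    a <- combos[1, j]; b <- combos[2, j]
    if (stats::sd(heights[, a]) == 0 || stats::sd(heights[, b]) == 0) {
      warn(sprintf("zero-variance heights for pair %s/%s; excluded",
                   ids[a], ids[b]))
      next
    }
    rows[[j]] <- tibble(library_a = ids[a], library_b = ids[b],
                        r = stats::cor(heights[, a], heights[, b]))
  }
  pairs <- dplyr::bind_rows(rows)
  structure(list(pairs = pairs,
                 median_r = if (nrow(pairs)) median(pairs$r) else NA_real_),
            class = "txa_reproducibility")
}

#' @export
print.txa_reproducibility <- function(x, ...) {
  cat(sprintf("<txa_reproducibility> %d pairs, median Pearson r = %.3f\n",
              nrow(x$pairs), x$median_r))
  invisible(x)
}

#' Merge per-condition end peaks into a unified site list
#'
#' Peaks of one site class on the same strand whose positions differ by at
#' most `tolerance_nt` are merged transitively (single linkage), so a chain
#' 100-104-108 collapses even though its extremes are 8 nt apart. The
#' representative position is the member with the greatest height. A merged
#' site observed in two or more conditions is labelled constitutive,
#' otherwise condition-specific. The result is deterministic and independent
#' of input row order.
#'
#' @param peaks A peak tibble carrying a `condition` column (bind several
#'   conditions' calls together), or a named list of per-condition peak
#'   tibbles, or a previous [merge_sites()] output (the operation is
#'   idempotent).
#' @param params A [merge_params()] object.
#' @return Tibble of merged sites: `site_id`, `position`, `strand`,
#'   `site_class`, `height_rpm`, `n_conditions`, `conditions` (list column),
#'   `condition_label`, `per_condition_height` (list column).
#' @export
merge_sites <- function(peaks, params = merge_params()) {
  peaks <- flatten_peaks(peaks)
  if (length(unique(peaks$site_class)) > 1L) {
    abort("cannot merge mixed site classes (TSS and TEP)")
  }
  if (nrow(peaks) == 0L) return(empty_merged())
  peaks <- dplyr::arrange(peaks, .data$strand, .data$position,
                          .data$condition)
  out <- peaks |>
    dplyr::group_by(.data$strand) |>
    dplyr::group_modify(function(df, key) {
      gap <- c(0L, diff(df$position))
      cluster <- cumsum(gap > params$tolerance_nt)
      df$cluster <- cluster
      df |>
        dplyr::group_by(.data$cluster) |>
        dplyr::group_modify(function(m, k) merge_one_cluster(m)) |>
        dplyr::ungroup() |>
        dplyr::select(-"cluster")
    }) |>
    dplyr::ungroup()
  out <- dplyr::arrange(out, .data$strand, .data$position)
  out$site_id <- sprintf("%s_%s_%07d", out$site_class,
                         ifelse(out$strand == "+", "p", "m"), out$position)
  dplyr::relocate(out, "site_id")
}

merge_one_cluster <- function(m) {
  best <- which(m$height_rpm == max(m$height_rpm))
  best <- best[which.min(m$position[best])]
  conds <- sort(unique(m$condition))
  pch <- vapply(conds, function(cc) max(m$height_rpm[m$condition == cc]),
                numeric(1))
  tibble(
    position = m$position[best],
    site_class = m$site_class[1],
    height_rpm = m$height_rpm[best],
    n_conditions = length(conds),
    conditions = list(conds),
    condition_label = if (length(conds) >= 2L) "constitutive" else
      paste0("condition-specific:", conds),
    per_condition_height = list(pch)
  )
}

flatten_peaks <- function(peaks) {
  if (is.data.frame(peaks) && "conditions" %in% names(peaks)) {
    # re-merging merged output: explode back to per-condition rows
    rows <- purrr::pmap(
      list(peaks$position, peaks$strand, peaks$site_class,
           peaks$per_condition_height),
      function(pos, str, cls, pch) {
        tibble(position = pos, strand = str, site_class = cls,
               condition = names(pch), height_rpm = unname(pch))
      })
    return(dplyr::bind_rows(rows))
  }
  if (is.data.frame(peaks)) return(as_tibble(peaks))
  dplyr::bind_rows(purrr::imap(peaks, function(df, nm) {
    if (!"condition" %in% names(df)) df$condition <- nm
    df
  }))
}

empty_merged <- function() {
  tibble(site_id = character(), position = integer(), site_class = character(),
         height_rpm = numeric(), n_conditions = integer(),
         conditions = list(), condition_label = character(),
         per_condition_height = list(), strand = character())
}
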