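#' Run the full calling pipeline on a simulation
#'
#' Convenience wrapper chaining the per-condition peak callers, cross-
#' condition merge, classification, TU assembly and clustering on the
#' tracks of a [simulate_architecture()] result (or equivalently structured
#' inputs).
#'
#' @param sim A `txa_simulation`.
#' @param peak_params A [peak_call_params()].
#' @param merge_p A [merge_params()].
#' @param class_params A [classification_params()].
#' @param tu_p A [tu_params()].
#' @return A list: `tss` / `tep` (classified merged site tibbles), `tus`,
#'   `clusters`, `tss_raw` / `tep_raw` (per-condition peak tibbles).
#' @export
run_pipeline <- function(sim,
                         peak_params = peak_call_params(),
                         merge_p = merge_params(),
                         class_params = classification_params(),
                         tu_p = tu_params()) {
  libs <- sim$libraries
  get_sig <- function(ids) sim$signals[ids]
  tss_raw <- list(); tep_raw <- list()
  for (cond in unique(libs$condition)) {
    texp <- libs$library_id[libs$condition == cond &
                              libs$role == "five_prime" &
                              libs$tex_status == "plus"]
    texm <- libs$library_id[libs$condition == cond &
                              libs$role == "five_prime" &
                              libs$tex_status == "minus"]
    term <- libs$library_id[libs$condition == cond &
                              libs$role == "three_prime"]
    cov_id <- libs$library_id[libs$condition == cond &
                                libs$role == "coverage"][1]
    coverage <- sim$signals[[cov_id]]
    tss_raw[[cond]] <- call_tss_peaks(get_sig(texp), get_sig(texm),
                                      coverage, peak_params)
    tep_raw[[cond]] <- call_tep_peaks(get_sig(term), coverage, peak_params)
  }
  tss_merged <- merge_sites(dplyr::bind_rows(tss_raw), merge_p)
  tep_merged <- merge_sites(dplyr::bind_rows(tep_raw), merge_p)
  tss_ann <- classify_tss(tss_merged, sim$annotation, class_params)
  tep_ann <- classify_tep(tep_merged, sim$annotation, tss_ann, class_params)
  # pool RNA-seq across conditions/replicates so TUs active in any
  # condition are coverage-supported
  cov_ids <- libs$library_id[libs$role == "coverage"]
  pooled <- pool_signals(sim$signals[cov_ids])
  tus <- assemble_tus(tss_ann, tep_ann, pooled, sim$annotation, tu_p)
  clusters <- cluster_tus(tus, tu_p)
  list(tss = tss_ann, tep = tep_ann, tus = tus, clusters = clusters,
       tss_raw = tss_raw, tep_raw = tep_raw)
}

#' Pool several stranded signals into one track
#'
#' Counts are summed per position and library sizes added, so RPM values
#' remain consistent. Useful for condition-pooled RNA-seq support.
#'
#' @param signals List of `txa_signal` objects of equal length.
#' @return A `txa_signal` with a synthetic pooled metadata row.
#' @export
pool_signals <- function(signals) {
  if (length(signals) == 0L) abort("no signals to pool")
  plus <- Reduce(`+`, lapply(signals, `[[`, "plus"))
  minus <- Reduce(`+`, lapply(signals, `[[`, "minus"))
  m1 <- signals[[1]]$meta
  meta <- library_meta(
    paste0("pooled_", m1$role), "pooled", m1$role,
    tex_status = if (m1$role == "five_prime") m1$tex_status else "na",
    replicate = 1L,
    total_mapped_reads = sum(vapply(signals, function(s)
      s$meta$total_mapped_reads, numeric(1))))
  stranded_signal(meta, plus, minus)
}

#' Score recovery of a planted architecture
#'
#' Greedy one-to-one matching (nearest first) of called sites to planted
#' sites within `tolerance_nt` on the same strand, per site class. Reports
#' recall and precision, agreement of constitutive/condition-specific
#' labels on matched sites, a category confusion table when the calls are
#' classified, and the fraction of planted TUs recovered with exactly
#' matching TSS/TEP identity.
#'
#' @param truth The `truth` element of a `txa_simulation`.
#' @param called A [run_pipeline()] result (or a list with `tss`, `tep`,
#'   `tus` tibbles).
#' @param tolerance_nt Matching tolerance (nt).
#' @return A `txa_recovery` list with elements `tss`, `tep` (each
#'   `recall`, `precision`, `n_truth`, `n_called`, `label_agreement`,
#'   `matches` tibble), `confusion` tibble, `tu_exact_fraction`.
#' @export
score_recovery <- function(truth, called, tolerance_nt = 1L) {
  m_tss <- match_sites(truth$tss, called$tss, tolerance_nt)
  m_tep <- match_sites(truth$tep, called$tep, tolerance_nt)
  confusion <- NULL
  if ("category" %in% names(called$tss) && nrow(m_tss$matches)) {
    confusion <- m_tss$matches |>
      dplyr::count(.data$truth_category, .data$called_category)
  }
  tu_frac <- tu_recovery(truth, called, m_tss$matches, m_tep$matches)
  structure(list(tss = m_tss, tep = m_tep, confusion = confusion,
                 tu_exact_fraction = tu_frac,
                 tolerance_nt = tolerance_nt),
            class = "txa_recovery")
}

match_sites <- function(truth_sites, called_sites, tol) {
  n_truth <- nrow(truth_sites)
  n_called <- nrow(called_sites)
  if (n_called == 0L) {
    return(list(recall = 0, precision = 1.0, zero_calls = TRUE,
                n_truth = n_truth, n_called = 0L,
                label_agreement = NA_real_,
                matches = tibble()))
  }
  cand <- list()
  for (i in seq_len(n_truth)) {
    d <- abs(called_sites$position - truth_sites$position[i])
    ok <- which(called_sites$strand == truth_sites$strand[i] & d <= tol)
    if (length(ok)) {
      cand[[length(cand) + 1L]] <- tibble(truth_i = i, called_i = ok,
                                          dist = d[ok])
    }
  }
  cand <- dplyr::bind_rows(cand)
  used_t <- logical(n_truth); used_c <- logical(n_called)
  rows <- list()
  if (nrow(cand)) {
    cand <- dplyr::arrange(cand, .data$dist, .data$truth_i, .data$called_i)
    for (k in seq_len(nrow(cand))) {
      ti <- cand$truth_i[k]; ci <- cand$called_i[k]
      if (used_t[ti] || used_c[ci]) next
      used_t[ti] <- TRUE; used_c[ci] <- TRUE
      rows[[length(rows) + 1L]] <- tibble(
        truth_i = ti, called_i = ci, dist = cand$dist[k],
        truth_position = truth_sites$position[ti],
        called_position = called_sites$position[ci],
        truth_label = truth_sites$condition_label[ti],
        called_label = called_sites$condition_label[ci],
        truth_category = truth_sites$category[ti],
        called_category = if ("category" %in% names(called_sites))
          called_sites$category[ci] else NA_character_)
    }
  }
  matches <- dplyr::bind_rows(rows)
  agree <- if (nrow(matches)) {
    mean((matches$truth_label == "constitutive") ==
           (matches$called_label == "constitutive"))
  } else NA_real_
  list(recall = sum(used_t) / max(1L, n_truth),
       precision = sum(used_c) / n_called,
       zero_calls = FALSE,
       n_truth = n_truth, n_called = n_called,
       label_agreement = agree, matches = matches)
}

tu_recovery <- function(truth, called, m_tss, m_tep) {
  if (is.null(called$tus) || nrow(truth$tus) == 0L) return(NA_real_)
  if (nrow(m_tss) == 0L || nrow(m_tep) == 0L || nrow(called$tus) == 0L) {
    return(0)
  }
  # map called site ids to matched truth positions
  tss_map <- setNames(m_tss$truth_position,
                      called$tss$site_id[m_tss$called_i])
  tep_map <- setNames(m_tep$truth_position,
                      called$tep$site_id[m_tep$called_i])
  hit <- logical(nrow(truth$tus))
  for (k in seq_len(nrow(called$tus))) {
    t5 <- tss_map[called$tus$tss_ref[k]]
    t3 <- tep_map[called$tus$tep_ref[k]]
    if (is.na(t5) || is.na(t3)) next
    j <- which(truth$tus$tss_position == t5 &
                 truth$tus$tep_position == t3 &
                 truth$tus$strand == called$tus$strand[k])
    if (length(j)) hit[j[1]] <- TRUE
  }
  mean(hit)
}

#' @export
print.txa_recovery <- function(x, ...) {
  cat(sprintf(
    "<txa_recovery> (+-%d nt)\n  TSS recall %.3f precision %.3f (labels %.3f)\n  TEP recall %.3f precision %.3f\n  TU exact recovery %.3f\n",
    x$tolerance_nt, x$tss$recall, x$tss$precision, x$tss$label_agreement,
    x$tep$recall, x$tep$precision, x$tu_exact_fraction))
  invisible(x)
}

#' @export
glance.txa_recovery <- function(x, ...) {
  tibble(tss_recall = x$tss$recall, tss_precision = x$tss$precision,
         tep_recall = x$tep$recall, tep_precision = x$tep$precision,
         tu_exact_fraction = x$tu_exact_fraction,
         label_agreement = x$tss$label_agreement,
         tolerance_nt = x$tolerance_nt)
}
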