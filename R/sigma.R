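#' Construct a bipartite sigma-factor promoter model
#'
#' A sigma-factor binding motif is modelled as two PWM blocks (the -35-side
#' and -10-side elements) separated by a spacer whose length is drawn from a
#' small set with prior weights. A placement's score is the sum of both
#' block log-odds scores plus `log2` of the spacer prior; its p-value is the
#' probability that a background-random word pair attains at least the
#' summed block score (the spacer prior enters the score, not the null).
#'
#' @param sigma_name Model label, e.g. `"SigA"`.
#' @param pwm_up Upstream (-35-side) block `txa_pwm`.
#' @param pwm_down Downstream (-10-side) block `txa_pwm`.
#' @param spacer_lengths Allowed spacer lengths (nt between the blocks).
#' @param spacer_weights Prior weights over `spacer_lengths` (normalized to
#'   sum to 1; default uniform).
#' @param score_threshold Minimum total score (bits) for a hit.
#' @param pvalue_threshold Maximum p-value for a hit.
#' @param tg_bonus If `TRUE`, an extended -10 "TG" dinucleotide immediately
#'   upstream of the downstream block adds 1 bit to the score (the SigA
#'   extended -10 element).
#' @return A `txa_sigma_model` object.
#' @export
sigma_model <- function(sigma_name, pwm_up, pwm_down, spacer_lengths,
                        spacer_weights = NULL, score_threshold = 0,
                        pvalue_threshold = 1e-4, tg_bonus = FALSE) {
  spacer_lengths <- as.integer(spacer_lengths)
  if (is.null(spacer_weights)) {
    spacer_weights <- rep(1, length(spacer_lengths))
  }
  if (length(spacer_weights) != length(spacer_lengths)) {
    abort("spacer_weights must match spacer_lengths")
  }
  spacer_weights <- spacer_weights / sum(spacer_weights)
  structure(list(
    sigma_name = sigma_name, pwm_up = pwm_up, pwm_down = pwm_down,
    spacer_lengths = spacer_lengths,
    spacer_prior = setNames(spacer_weights, spacer_lengths),
    score_threshold = score_threshold,
    pvalue_threshold = pvalue_threshold,
    tg_bonus = isTRUE(tg_bonus)
  ), class = "txa_sigma_model")
}

#' @export
print.txa_sigma_model <- function(x, ...) {
  cat(sprintf("<txa_sigma_model> %s: %s -[%s nt]- %s (p <= %g)\n",
              x$sigma_name, pwm_consensus(x$pwm_up),
              paste(x$spacer_lengths, collapse = ","),
              pwm_consensus(x$pwm_down), x$pvalue_threshold))
  invisible(x)
}

#' Default sigma-factor promoter models
#'
#' Six bipartite models covering the housekeeping sigma factor and the
#' alternative factors of endospore-forming Firmicutes:
#' * SigA: TTGHHW / TATAAT, 17-nt spacer, extended -10 TG bonus;
#' * SigH: AGGA / GAAT, 17-18 nt spacers;
#' * SigF, SigE, SigK: B. subtilis-like block approximations, 14-15 nt
#'   spacers (these three are figure-level approximations and fully
#'   configurable);
#' * SigL (sigma-54 family): TGGCA / TTGC with a fixed 6-nt spacer
#'   (-24/-12 elements).
#'
#' @param background Null base distribution shared by all blocks.
#' @return Named list of `txa_sigma_model` objects.
#' @export
sigma_models <- function(background = c(A = .25, C = .25, G = .25, T = .25)) {
  cp <- function(s) consensus_pwm(s, background = background)
  list(
    SigA = sigma_model("SigA", cp("TTGHHW"), cp("TATAAT"), 17L,
                       tg_bonus = TRUE),
    SigH = sigma_model("SigH", cp("AGGA"), cp("GAAT"), c(17L, 18L)),
    SigF = sigma_model("SigF", cp("GCATA"), cp("GGNRA"), c(14L, 15L)),
    SigE = sigma_model("SigE", cp("ATATT"), cp("CATACA"), c(14L, 15L)),
    SigK = sigma_model("SigK", cp("ACACC"), cp("CATAAT"), c(14L, 15L)),
    SigL = sigma_model("SigL", cp("TGGCA"), cp("TTGC"), 6L)
  )
}

# Null distribution of the summed two-block score, cached on the model.
model_null <- function(model, resolution = 1e4) {
  score_distribution(list(model$pwm_up, model$pwm_down), resolution)
}

#' Scan a promoter window with a bipartite sigma model
#'
#' Exhaustively evaluates every placement (upstream-block start x allowed
#' spacer) in the window and returns the best-scoring hit passing both the
#' score and the p-value thresholds, or no rows. Equal scores resolve to the
#' 5'-most placement (lowest `up_start`, then shortest spacer).
#'
#' @param window Promoter sequence (5'->3'; for a minus-strand promoter pass
#'   the reverse complement).
#' @param model A `txa_sigma_model`.
#' @param null_dist Optional precomputed [score_distribution()] of the two
#'   blocks (saves recomputation in genome-wide scans).
#' @param best_only If `FALSE`, return every passing placement instead of
#'   the single best.
#' @return Tibble of hits: `sigma_name`, `up_start`, `down_start`, `spacer`,
#'   `score`, `pvalue` (positions are 1-based within `window`).
#' @export
scan_window <- function(window, model, null_dist = NULL, best_only = TRUE) {
  w_up <- model$pwm_up$width
  w_down <- model$pwm_down$width
  min_len <- w_up + min(model$spacer_lengths) + w_down
  empty <- tibble(sigma_name = character(), up_start = integer(),
                  down_start = integer(), spacer = integer(),
                  score = numeric(), pvalue = numeric())
  if (nchar(window) < min_len) {
    warn(sprintf("window of %d nt shorter than minimum placement %d nt",
                 nchar(window), min_len))
    return(empty)
  }
  if (is.null(null_dist)) null_dist <- model_null(model)
  sc_up <- score_positions(window, model$pwm_up)
  sc_down <- score_positions(window, model$pwm_down)
  n <- nchar(window)
  rows <- list()
  for (k in seq_along(model$spacer_lengths)) {
    sp <- model$spacer_lengths[k]
    prior <- log2(model$spacer_prior[[k]])
    up_starts <- seq_len(max(0L, n - (w_up + sp + w_down) + 1L))
    if (length(up_starts) == 0L) next
    down_starts <- up_starts + w_up + sp
    block <- sc_up[up_starts] + sc_down[down_starts]
    total <- block + prior
    if (model$tg_bonus) {
      tg_at <- down_starts - 2L
      has_tg <- tg_at >= 1L &
        substring(window, tg_at, tg_at + 1L) == "TG"
      total <- total + ifelse(has_tg, 1, 0)
      block <- block + ifelse(has_tg, 1, 0)
    }
    rows[[k]] <- tibble(sigma_name = model$sigma_name,
                        up_start = up_starts, down_start = down_starts,
                        spacer = sp, score = total, block_score = block)
  }
  hits <- dplyr::bind_rows(rows)
  if (nrow(hits) == 0L) return(empty)
  hits$pvalue <- vapply(hits$block_score, function(s)
    pvalue_from_distribution(null_dist, s), numeric(1))
  hits <- hits[hits$score >= model$score_threshold &
                 hits$pvalue <= model$pvalue_threshold, , drop = FALSE]
  hits <- dplyr::select(hits, -"block_score")
  if (nrow(hits) == 0L) return(empty)
  hits <- dplyr::arrange(hits, dplyr::desc(.data$score), .data$up_start,
                         .data$spacer)
  if (best_only) hits[1, , drop = FALSE] else hits
}

# 50 nt immediately upstream of a site position, strand-aware, inclusive of
# position -1; truncated (with flag) at genome ends.
promoter_window <- function(genome, position, strand, len = 50L) {
  if (strand == "+") {
    lo <- position - len; hi <- position - 1L
  } else {
    lo <- position + 1L; hi <- position + len
  }
  seq <- genome_window(genome, lo, hi, strand)
  list(seq = seq, truncated = nchar(seq) < len)
}

#' Assign sigma-factor motifs to TSS promoters
#'
#' Scans the `promoter_len` nt upstream of every TSS (strand-aware,
#' inclusive of position -1) independently with each sigma model; a TSS may
#' therefore carry hits for several sigma factors. Windows truncated at the
#' genome edge are flagged and scanned as-is.
#'
#' @param tss_sites Tibble with `site_id`, `position`, `strand`.
#' @param genome A `txa_genome`.
#' @param models Named list from [sigma_models()].
#' @param promoter_len Promoter window length (nt upstream of the TSS).
#' @return A list: `hits` tibble (`site_id`, `sigma_name`, `up_start`,
#'   `down_start`, `spacer`, `score`, `pvalue`, `truncated`; window-relative
#'   positions), and `proportions` tibble (`sigma_name`, `n_hits`,
#'   `proportion` of total motifs, plus a `no_motif` row giving the fraction
#'   of TSSs with no hit at all).
#' @export
assign_sigma <- function(tss_sites, genome, models = sigma_models(),
                         promoter_len = 50L) {
  nulls <- lapply(models, model_null)
  rows <- list()
  for (i in seq_len(nrow(tss_sites))) {
    win <- promoter_window(genome, tss_sites$position[i],
                           tss_sites$strand[i], promoter_len)
    for (m in names(models)) {
      min_len <- models[[m]]$pwm_up$width +
        min(models[[m]]$spacer_lengths) + models[[m]]$pwm_down$width
      if (nchar(win$seq) < min_len) next
      h <- scan_window(win$seq, models[[m]], null_dist = nulls[[m]])
      if (nrow(h)) {
        h$site_id <- tss_sites$site_id[i]
        h$truncated <- win$truncated
        rows[[length(rows) + 1L]] <- h
      }
    }
  }
  hits <- dplyr::bind_rows(rows)
  if (nrow(hits) == 0L) {
    hits <- tibble(site_id = character(), sigma_name = character(),
                   up_start = integer(), down_start = integer(),
                   spacer = integer(), score = numeric(), pvalue = numeric(),
                   truncated = logical())
  } else {
    hits <- dplyr::relocate(hits, "site_id")
  }
  n_total <- nrow(hits)
  props <- hits |>
    dplyr::count(.data$sigma_name, name = "n_hits") |>
    dplyr::mutate(proportion = .data$n_hits / max(1L, n_total))
  n_no_motif <- nrow(tss_sites) - length(unique(hits$site_id))
  props <- dplyr::bind_rows(
    props,
    tibble(sigma_name = "no_motif", n_hits = n_no_motif,
           proportion = n_no_motif / max(1L, nrow(tss_sites))))
  list(hits = hits, proportions = props)
}

#' Genome-wide upstream scan with one sigma model
#'
#' FIMO-style scan of the `upstream_len` nt upstream of every annotated
#' gene 5' end (strand-aware, truncated at genome ends; neighbouring genes
#' are not trimmed out of the window). Every placement with p-value at or
#' below the threshold is reported, positioned relative to the gene start
#' (`-1` = the nt immediately upstream).
#'
#' @param annotation A `txa_annotation`.
#' @param genome A `txa_genome`.
#' @param model A `txa_sigma_model`.
#' @param upstream_len Window length (nt).
#' @param pvalue_threshold Hit cutoff (overrides the model's threshold).
#' @return Tibble: `locus_tag`, `up_start_rel`, `down_start_rel`, `spacer`,
#'   `score`, `pvalue`.
#' @export
scan_upstream_genome <- function(annotation, genome, model,
                                 upstream_len = 200L,
                                 pvalue_threshold = model$pvalue_threshold) {
  model2 <- model
  model2$pvalue_threshold <- pvalue_threshold
  null_dist <- model_null(model)
  rows <- list()
  for (i in seq_len(nrow(annotation))) {
    fp <- annotation$five_prime[i]
    strand <- annotation$strand[i]
    win <- promoter_window(genome, fp, strand, upstream_len)
    wlen <- nchar(win$seq)
    min_len <- model$pwm_up$width + min(model$spacer_lengths) +
      model$pwm_down$width
    if (wlen < min_len) next
    h <- scan_window(win$seq, model2, null_dist = null_dist,
                     best_only = FALSE)
    if (nrow(h) == 0L) next
    h$locus_tag <- annotation$locus_tag[i]
    # window position w (1-based, 5'->3') is -(wlen - w + 1) relative to the
    # gene start
    h$up_start_rel <- -(wlen - h$up_start + 1L)
    h$down_start_rel <- -(wlen - h$down_start + 1L)
    rows[[length(rows) + 1L]] <-
      dplyr::select(h, "locus_tag", "up_start_rel", "down_start_rel",
                    "spacer", "score", "pvalue")
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(locus_tag = character(), up_start_rel = integer(),
                  down_start_rel = integer(), spacer = integer(),
                  score = numeric(), pvalue = numeric())
  }
  out
}
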