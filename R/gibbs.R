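#' De novo motif discovery by ZOOPS Gibbs sampling
#'
#' A zero-or-one-occurrence-per-sequence Gibbs site sampler: sites are
#' initialized at random, then repeatedly resampled one sequence at a time
#' from the posterior given a PWM estimated from all other sequences'
#' current sites (leave-one-out), with a "no site" option weighted by
#' `1 - zoops_prior`. The best complete-data log-likelihood state across
#' all restarts is returned. Bit-reproducible for a fixed
#' `params$seed`.
#'
#' @param seqs Character vector of ACGT sequences (>= 10 recommended).
#' @param params A [gibbs_params()] object.
#' @return A list: `pwm` (`txa_pwm` estimated from the best sites),
#'   `sites` tibble (`seq_index`, `start`, `site`; one row per sequence
#'   carrying a site), `log_lik` of the best state.
#' @export
gibbs_discover <- function(seqs, params = gibbs_params()) {
  w <- params$width
  if (w > min(nchar(seqs))) abort("width exceeds shortest sequence length")
  enc <- encode_seqs(seqs)
  if (any(vapply(enc, anyNA, logical(1)))) {
    abort("sequences must contain only A/C/G/T")
  }
  n <- length(seqs)
  # 0-order background from all scanned residues
  bg_counts <- tabulate(unlist(enc), nbins = 4)
  bg <- setNames(bg_counts / sum(bg_counts), BASES)
  n_starts <- vapply(enc, length, integer(1)) - w + 1L
  withr::with_seed(params$seed, {
    best <- list(log_lik = -Inf, starts = NULL)
    for (r in seq_len(params$restarts)) {
      starts <- vapply(n_starts, function(k) sample.int(k, 1L), integer(1))
      has_site <- rep(TRUE, n)
      counts <- site_counts(enc, starts, has_site, w)
      for (it in seq_len(params$iterations)) {
        for (i in seq_len(n)) {
          if (has_site[i]) {
            counts <- counts - site_count_one(enc[[i]], starts[i], w)
          }
          probs <- sweep(counts + params$pwm_pseudocount, 2,
                         sum(has_site) - has_site[i] +
                           4 * params$pwm_pseudocount, "/")
          lo <- log(sweep(probs, 1, bg, "/"))
          s <- site_logodds(enc[[i]], lo, w)
          # ZOOPS posterior: no-site mass vs site at each start, combined
          # in log space to keep the calibration exact
          lw <- c(log(1 - params$zoops_prior + 1e-12),
                  log(params$zoops_prior) + s - log(n_starts[i]))
          wts <- exp(lw - max(lw))
          pick <- sample.int(length(wts), 1L, prob = wts)
          if (pick == 1L) {
            has_site[i] <- FALSE
          } else {
            has_site[i] <- TRUE
            starts[i] <- pick - 1L
            counts <- counts + site_count_one(enc[[i]], starts[i], w)
          }
        }
        # phase-shift move: slide all sites together by +-1 when that
        # improves the joint likelihood (escapes shifted-register optima)
        ll <- zoops_log_lik(enc, starts, has_site, w, bg,
                            params$zoops_prior, params$pwm_pseudocount)
        for (delta in c(-2L, -1L, 1L, 2L)) {
          cand <- starts + delta
          ok <- !has_site | (cand >= 1L & cand <= n_starts)
          if (!all(ok)) next
          ll2 <- zoops_log_lik(enc, cand, has_site, w, bg,
                               params$zoops_prior, params$pwm_pseudocount)
          if (ll2 > ll) {
            starts <- cand
            ll <- ll2
            counts <- site_counts(enc, starts, has_site, w)
          }
        }
        if (ll > best$log_lik) {
          best <- list(log_lik = ll, starts = starts, has_site = has_site)
        }
      }
    }
  })
  keep <- which(best$has_site)
  sites <- vapply(keep, function(i)
    substr(seqs[i], best$starts[i], best$starts[i] + w - 1L), character(1))
  out_pwm <- estimate_pwm(sites, pseudocount = params$pwm_pseudocount,
                          background = bg)
  list(
    pwm = out_pwm,
    sites = tibble(seq_index = keep, start = best$starts[keep],
                   site = sites),
    log_lik = best$log_lik
  )
}

site_count_one <- function(code, start, w) {
  m <- matrix(0L, 4, w)
  idx <- cbind(code[start:(start + w - 1L)], seq_len(w))
  m[idx] <- 1L
  m
}

site_counts <- function(enc, starts, has_site, w) {
  m <- matrix(0L, 4, w, dimnames = list(BASES, NULL))
  for (i in which(has_site)) {
    m <- m + site_count_one(enc[[i]], starts[i], w)
  }
  m
}

site_logodds <- function(code, lo, w) {
  n <- length(code) - w + 1L
  s <- numeric(n)
  for (j in seq_len(w)) {
    s <- s + lo[cbind(code[j:(n + j - 1L)], j)]
  }
  s
}

zoops_log_lik <- function(enc, starts, has_site, w, bg, q, pc) {
  keep <- which(has_site)
  if (length(keep) < 2L) return(-Inf)
  counts <- site_counts(enc, starts, has_site, w)
  probs <- sweep(counts + pc, 2, length(keep) + 4 * pc, "/")
  lo <- log(sweep(probs, 1, bg, "/"))
  ll <- 0
  for (i in keep) {
    idx <- cbind(enc[[i]][starts[i]:(starts[i] + w - 1L)], seq_len(w))
    ll <- ll + sum(lo[idx]) + log(q)
  }
  ll + sum(!has_site) * log(1 - q + 1e-12)
}

#' Discover a bipartite promoter model from fixed-width promoter windows
#'
#' Two-stage discovery for sigma-factor-like motifs with variable spacers:
#' stage 1 runs [gibbs_discover()] on the `down_region` nt nearest the TSS
#' (the -10-side block); stage 2 anchors each sequence on its -10 hit and
#' searches the spacer band upstream for the -35-side block. The spacer
#' prior is the empirical histogram of observed spacers.
#'
#' @param promoter_seqs Equal-length promoter windows, TSS at the right
#'   (3') end.
#' @param params A [gibbs_params()] for the downstream block; the upstream
#'   block reuses it with `width = up_width`.
#' @param up_width Upstream block width (nt).
#' @param down_region Window (nt, nearest the TSS) searched in stage 1.
#' @param spacer_range Allowed spacer lengths `c(min, max)` searched in
#'   stage 2.
#' @param ic_floor Minimum mean per-column information content (bits) for a
#'   stage to count as having found a motif.
#' @param sigma_name Label for the returned model.
#' @return A `txa_sigma_model` with empirically estimated blocks and spacer
#'   prior.
#' @export
discover_bipartite <- function(promoter_seqs, params = gibbs_params(width = 4L),
                               up_width = 4L, down_region = 20L,
                               spacer_range = c(12L, 22L),
                               ic_floor = 1.0, sigma_name = "discovered") {
  lens <- unique(nchar(promoter_seqs))
  if (length(lens) != 1L) abort("promoter windows must have equal length")
  L <- lens
  w_down <- params$width
  down_seqs <- substr(promoter_seqs, L - down_region + 1L, L)
  stage1 <- gibbs_discover(down_seqs, params)
  ic1 <- mean(information_content(stage1$pwm))
  if (ic1 < ic_floor) {
    abort(sprintf(
      "stage 1 (-10 block): motif information content %.2f below floor %.2f",
      ic1, ic_floor))
  }
  # absolute -10 start within the full window
  d10 <- (L - down_region) + stage1$sites$start
  smin <- spacer_range[1]; smax <- spacer_range[2]
  band_lo <- d10 - smax - up_width
  band_hi <- d10 - smin - 1L
  ok <- band_lo >= 1L
  usable <- stage1$sites$seq_index[ok]
  band_lo <- band_lo[ok]
  band_hi <- band_hi[ok]
  d10_ok <- d10[ok]
  if (length(usable) < 2L) abort("stage 2 (-35 block): too few usable sequences")
  band_seqs <- substr(promoter_seqs[usable], band_lo, band_hi)
  params_up <- params
  params_up$width <- as.integer(up_width)
  params_up$seed <- params$seed + 1L
  stage2 <- gibbs_discover(band_seqs, params_up)
  ic2 <- mean(information_content(stage2$pwm))
  if (ic2 < ic_floor) {
    abort(sprintf(
      "stage 2 (-35 block): motif information content %.2f below floor %.2f",
      ic2, ic_floor))
  }
  # map stage-2 starts back to spacers
  idx2 <- stage2$sites$seq_index
  up_abs <- band_lo[idx2] + stage2$sites$start - 1L
  spacer <- d10_ok[idx2] - (up_abs + up_width)
  spacer <- spacer[spacer >= smin & spacer <= smax]
  h <- table(spacer)
  keep <- h / sum(h) >= 0.1   # drop stray alignments
  spacer_lengths <- as.integer(names(h))[keep]
  spacer_weights <- as.numeric(h[keep])
  sigma_model(sigma_name, stage2$pwm, stage1$pwm,
              spacer_lengths, spacer_weights)
}
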