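#' Synthetic transcriptome-architecture configuration
#'
#' Study conditions for the generator: a random genome at acetogen-like GC
#' content carries non-overlapping genes on both strands, each with a
#' planted sigma-factor promoter, a 5'-UTR drawn from a short-mode/long-tail
#' mixture (mode 20-29 nt, median ~45 nt), an AG-rich RBS just upstream of
#' the start codon, a 3'-UTR with median ~64 nt, and an intrinsic
#' terminator (GC stem, 4-nt loop, U-tract) ending at the TEP. 5'-end TEX+
#' counts are negative-binomial at true TSSs with TEX- depleted by
#' `tex_enrichment`; processed 5' ends are TEX-enriched the other way
#' round; Term-seq counts mark TEPs; RNA-seq coverage is a noisy plateau
#' across each transcription unit; Poisson background covers everything.
#'
#' @param genome_len Genome length (nt).
#' @param n_genes Number of genes.
#' @param gc_content Genomic GC fraction.
#' @param gene_len_range Gene length range (nt), drawn uniformly.
#' @param sigma_fractions Named promoter mix over the six sigma models
#'   (normalized internally).
#' @param tss_height_mean,tss_height_dispersion Negative-binomial mean and
#'   size for TEX+ 5'-end counts at true TSSs.
#' @param expression_sdlog,expression_floor Per-gene expression multiplier
#'   (lognormal sdlog, truncated below at the floor) shared by the gene's
#'   TSS, TEP and coverage signal across replicates and conditions; this
#'   cross-site dynamic range is what makes replicate height correlations
#'   high, as in real end-sequencing data. The floor keeps every planted
#'   site above the calling threshold so the truth tables stay complete.
#' @param tep_height_mean Negative-binomial mean for Term-seq counts at
#'   TEPs.
#' @param tex_enrichment TEX+/TEX- height ratio at true TSSs.
#' @param processed_site_rate Processed (TEX-depleted) 5' ends per kb.
#' @param background_rate_per_nt Poisson background rate per position per
#'   end-count track.
#' @param jitter_sd SD (nt) of the site-level positional smear, applied
#'   once per site and shared across replicates and conditions.
#' @param n_replicates Replicates per condition.
#' @param conditions Condition labels.
#' @param condition_specific_fraction Fraction of genes active in only one
#'   condition.
#' @param tu_coverage_rpm RNA-seq plateau height (RPM) across active TUs.
#' @param riboswitch_rate Fraction of long-UTR genes given a premature
#'   (cis-regulatory) TEP inside the 5'-UTR.
#' @param library_size Mapped reads per library (RPM denominator).
#' @param seed Master seed; all draws flow from it in a fixed order
#'   (genome, placement, architecture, heights, noise).
#' @return A `txa_synth_config` list.
#' @export
synthetic_config <- function(genome_len = 100000L,
                             n_genes = 80L,
                             gc_content = 0.474,
                             gene_len_range = c(300L, 800L),
                             sigma_fractions = c(SigA = 0.698, SigH = 0.161,
                                                 SigF = 0.087, SigE = 0.026,
                                                 SigK = 0.016, SigL = 0.012),
                             tss_height_mean = 50,
                             tss_height_dispersion = 30,
                             expression_sdlog = 2,
                             expression_floor = 0.5,
                             tep_height_mean = 50,
                             tex_enrichment = 5,
                             processed_site_rate = 0.2,
                             background_rate_per_nt = 0.05,
                             jitter_sd = 0.5,
                             n_replicates = 2L,
                             conditions = c("CO2", "betaine"),
                             condition_specific_fraction = 0.4,
                             tu_coverage_rpm = 10,
                             riboswitch_rate = 0.05,
                             library_size = 5e6,
                             seed = 7L) {
  stopifnot(gc_content > 0, gc_content < 1, n_genes >= 1,
            condition_specific_fraction >= 0,
            condition_specific_fraction <= 1,
            background_rate_per_nt >= 0, jitter_sd >= 0,
            n_replicates >= 1, length(conditions) >= 1,
            tex_enrichment > 1, library_size > 0)
  sigma_fractions <- sigma_fractions / sum(sigma_fractions)
  structure(list(
    genome_len = as.integer(genome_len), n_genes = as.integer(n_genes),
    gc_content = gc_content, gene_len_range = as.integer(gene_len_range),
    sigma_fractions = sigma_fractions,
    tss_height_mean = tss_height_mean,
    tss_height_dispersion = tss_height_dispersion,
    expression_sdlog = expression_sdlog,
    expression_floor = expression_floor,
    tep_height_mean = tep_height_mean,
    tex_enrichment = tex_enrichment,
    processed_site_rate = processed_site_rate,
    background_rate_per_nt = background_rate_per_nt,
    jitter_sd = jitter_sd, n_replicates = as.integer(n_replicates),
    conditions = conditions,
    condition_specific_fraction = condition_specific_fraction,
    tu_coverage_rpm = tu_coverage_rpm,
    riboswitch_rate = riboswitch_rate,
    library_size = library_size, seed = as.integer(seed)
  ), class = "txa_synth_config")
}

# 5'-UTR mixture: 0.4 * DiscreteUniform(20,29) (the modal decade) +
# 0.6 * (30 + Geometric(p = 0.0114)) (the long tail), capped at 250 nt.
# Gives mode bin 20-29 and median ~45 nt.
draw_utr5 <- function(n) {
  pick <- runif(n) < 0.4
  v <- integer(n)
  v[pick] <- sample(20:29, sum(pick), replace = TRUE)
  v[!pick] <- 30L + rgeom(sum(!pick), prob = 0.0114)
  pmin(v, 250L)
}

# 3'-UTR: 20 + Gamma(shape 2, scale 26), capped; mode ~46, median ~64 nt.
draw_utr3 <- function(n) {
  pmin(20L + as.integer(round(rgamma(n, shape = 2, scale = 26))), 250L)
}

#' Simulate a planted transcriptome architecture with signal tracks
#'
#' Runs the full generator described in [synthetic_config()] and returns
#' the genome, annotation, per-library stranded tracks, library metadata
#' and ground-truth tables. Byte-reproducible for a fixed config.
#'
#' @param config A [synthetic_config()].
#' @return A `txa_simulation` list: `genome`, `annotation`, `signals`
#'   (named list of `txa_signal`), `libraries` (metadata tibble), `truth`
#'   (list of `tss`, `tep`, `tus`, `processed` tibbles), `config`.
#' @export
simulate_architecture <- function(config = synthetic_config()) {
  withr::with_seed(config$seed, simulate_impl(config))
}

simulate_impl <- function(config) {
  L <- config$genome_len
  gc <- config$gc_content
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  genome_chars <- sample(BASES, L, replace = TRUE, prob = base_probs)

  # --- architecture placement -------------------------------------------
  n <- config$n_genes
  placed <- FALSE
  for (try in 1:10) {
    glen <- sample(config$gene_len_range[1]:config$gene_len_range[2], n,
                   replace = TRUE)
    utr5 <- draw_utr5(n)
    utr3 <- draw_utr3(n)
    margin_up <- 60L   # promoter room upstream of the TSS
    margin_dn <- 20L   # spare room downstream of the TEP
    fp <- margin_up + utr5 + glen + utr3 + margin_dn
    slack <- L - sum(fp)
    if (slack >= n + 1L) { placed <- TRUE; break }
  }
  if (!placed) {
    abort("could not place genes after 10 tries; increase genome_len")
  }
  gap_w <- as.vector(stats::rmultinom(1, slack - (n + 1L), rep(1, n + 1L))) + 1L
  f0 <- cumsum(c(gap_w[1] + 1L, fp[-n] + gap_w[2:n]))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  sigma <- sample(names(config$sigma_fractions), n, replace = TRUE,
                  prob = config$sigma_fractions)

  tss <- tep <- gene_start <- gene_end <- integer(n)
  for (i in seq_len(n)) {
    if (strand[i] == "+") {
      tss[i] <- f0[i] + margin_up
      gene_start[i] <- tss[i] + utr5[i]
      gene_end[i] <- gene_start[i] + glen[i] - 1L
      tep[i] <- gene_end[i] + utr3[i]
    } else {
      tep[i] <- f0[i] + margin_dn
      gene_start[i] <- tep[i] + utr3[i]
      gene_end[i] <- gene_start[i] + glen[i] - 1L
      tss[i] <- gene_end[i] + utr5[i]
    }
  }
  five_prime <- ifelse(strand == "+", gene_start, gene_end)

  # --- plant sequence elements ------------------------------------------
  models <- sigma_models()
  plant <- function(chars, seq, at, strand) {
    # write `seq` (given 5'->3' on `strand`) at genomic positions starting
    # at `at` on the plus-strand coordinate of its 5'-most genomic position
    if (strand == "-") seq <- revcomp(seq)
    s <- strsplit(seq, "")[[1]]
    chars[at:(at + length(s) - 1L)] <- s
    chars
  }
  sample_pwm <- function(p) {
    paste(apply(p$probs, 2, function(col) sample(BASES, 1, prob = col)),
          collapse = "")
  }
  spacer_used <- integer(n)
  for (i in seq_len(n)) {
    m <- models[[sigma[i]]]
    sp <- if (length(m$spacer_lengths) == 1L) m$spacer_lengths else
      sample(m$spacer_lengths, 1L)
    spacer_used[i] <- sp
    up_seq <- sample_pwm(m$pwm_up)
    down_seq <- sample_pwm(m$pwm_down)
    w_up <- m$pwm_up$width; w_down <- m$pwm_down$width
    # downstream block ends 7 nt upstream of the TSS
    if (strand[i] == "+") {
      down_at <- tss[i] - 7L - w_down + 1L
      up_at <- down_at - sp - w_up
      genome_chars <- plant(genome_chars, up_seq, up_at, "+")
      genome_chars <- plant(genome_chars, down_seq, down_at, "+")
      if (m$tg_bonus) genome_chars <- plant(genome_chars, "TG", down_at - 2L, "+")
    } else {
      down_at <- tss[i] + 7L
      up_at <- down_at + sp + w_down
      genome_chars <- plant(genome_chars, down_seq, down_at, "-")
      genome_chars <- plant(genome_chars, up_seq, up_at, "-")
      if (m$tg_bonus) genome_chars <- plant(genome_chars, "TG", down_at + w_down, "-")
    }
    # start/stop codons and RBS
    if (strand[i] == "+") {
      genome_chars <- plant(genome_chars, "ATG", gene_start[i], "+")
      genome_chars <- plant(genome_chars, "TAA", gene_end[i] - 2L, "+")
      d <- sample(5:9, 1L)
      genome_chars <- plant(genome_chars, "AGGAGG", gene_start[i] - d - 6L, "+")
    } else {
      genome_chars <- plant(genome_chars, "ATG", gene_end[i] - 2L, "-")
      genome_chars <- plant(genome_chars, "TAA", gene_start[i], "-")
      d <- sample(5:9, 1L)
      genome_chars <- plant(genome_chars, "AGGAGG", gene_end[i] + d + 1L, "-")
    }
    # intrinsic terminator: 8-bp GC stem, 4-nt loop, 8-nt U tract at the TEP
    stem <- paste(sample(c("G", "C"), 8, replace = TRUE), collapse = "")
    loop <- paste(sample(BASES, 4, replace = TRUE), collapse = "")
    hp <- paste0(stem, loop, revcomp(stem), "TTTTTTTT")
    if (strand[i] == "+") {
      genome_chars <- plant(genome_chars, hp, tep[i] - nchar(hp) + 1L, "+")
    } else {
      genome_chars <- plant(genome_chars, hp, tep[i], "-")
    }
  }

  # --- activity, riboswitch TEPs, jitter --------------------------------
  n_cond <- length(config$conditions)
  specific <- runif(n) < config$condition_specific_fraction & n_cond > 1L
  active_cond <- lapply(seq_len(n), function(i) {
    if (specific[i]) sample(config$conditions, 1L) else config$conditions
  })
  ribo <- which(utr5 >= 45 & runif(n) < config$riboswitch_rate)
  ribo_pos <- integer(0)
  if (length(ribo)) {
    ribo_pos <- ifelse(strand[ribo] == "+",
                       five_prime[ribo] - utr5[ribo] %/% 2L,
                       five_prime[ribo] + utr5[ribo] %/% 2L)
  }
  expr_mult <- pmax(config$expression_floor,
                    stats::rlnorm(n, 0, config$expression_sdlog))
  jit <- function(k) as.integer(round(rnorm(k, 0, config$jitter_sd)))
  tss_obs <- tss + jit(n) * strand_sign(strand)
  tep_obs <- tep + jit(n) * strand_sign(strand)
  ribo_obs <- if (length(ribo)) ribo_pos + jit(length(ribo)) *
    strand_sign(strand[ribo]) else integer(0)

  locus <- sprintf("SYN_%04d", seq_len(n))
  annotation <- annotation_from_genes(tibble(
    locus_tag = locus, feature_type = "CDS", strand = strand,
    start = gene_start, end = gene_end))

  truth_tss <- tibble(
    gene = locus, position = tss, obs_position = tss_obs, strand = strand,
    sigma = sigma, spacer = spacer_used, category = "P",
    conditions = active_cond,
    condition_label = ifelse(specific,
                             paste0("condition-specific:",
                                    vapply(active_cond, `[`, "", 1)),
                             "constitutive"),
    utr5 = utr5)
  truth_tep <- tibble(
    gene = c(locus, locus[ribo]),
    position = c(tep, ribo_pos),
    obs_position = c(tep_obs, ribo_obs),
    strand = c(strand, strand[ribo]),
    category = c(rep("P", n), rep("C", length(ribo))),
    conditions = c(active_cond, active_cond[ribo]),
    condition_label = c(truth_tss$condition_label,
                        truth_tss$condition_label[ribo]),
    utr3 = c(utr3, rep(NA_integer_, length(ribo))))

  # truth TUs: each TSS paired with its nearest planted downstream TEP
  truth_tus <- purrr::map_dfr(seq_len(n), function(i) {
    sgn <- strand_sign(strand[i])
    d <- (truth_tep$position - tss[i]) * sgn
    same <- truth_tep$strand == strand[i] & d > 0
    if (!any(same)) return(NULL)
    j <- which(same)[which.min(d[same])]
    span <- sort(c(tss[i], truth_tep$position[j]))
    tibble(tss_gene = locus[i], tss_position = tss[i],
           tep_position = truth_tep$position[j],
           tep_category = truth_tep$category[j],
           strand = strand[i], start = span[1], end = span[2])
  })

  # processed (TEX-depleted) 5' ends inside transcribed spans
  n_proc <- rpois(1, config$processed_site_rate * L / 1000)
  proc_idx <- sample(seq_len(n), n_proc, replace = TRUE)
  proc_off <- vapply(proc_idx, function(i) {
    span <- sort(c(tss[i], tep[i]))
    sample(seq(span[1] + 30L, span[2] - 30L), 1L)
  }, integer(1))
  truth_processed <- tibble(position = proc_off,
                            strand = strand[proc_idx],
                            gene = locus[proc_idx])

  # --- signal tracks -----------------------------------------------------
  genome <- genome_from_seq(paste(genome_chars, collapse = ""), "synthetic")
  signals <- list()
  libraries <- list()
  add_lib <- function(meta, plus, minus) {
    sig <- stranded_signal(meta, plus, minus)
    signals[[meta$library_id]] <<- sig
    libraries[[meta$library_id]] <<- meta
  }
  nb <- function(k, mu) rnbinom(k, size = config$tss_height_dispersion,
                                mu = mu)
  bgv <- function() if (config$background_rate_per_nt > 0)
    rpois(L, config$background_rate_per_nt) else numeric(L)
  active_in <- function(cond) vapply(active_cond, function(a) cond %in% a,
                                     logical(1))

  for (cond in config$conditions) {
    act <- active_in(cond)
    for (r in seq_len(config$n_replicates)) {
      # dRNA-seq pair
      texp <- list("+" = bgv(), "-" = bgv())
      texm <- list("+" = bgv(), "-" = bgv())
      for (i in which(act)) {
        s <- strand[i]; p <- tss_obs[i]
        if (p < 1L || p > L) next
        mu <- config$tss_height_mean * expr_mult[i]
        texp[[s]][p] <- texp[[s]][p] + nb(1, mu)
        texm[[s]][p] <- texm[[s]][p] + nb(1, mu / config$tex_enrichment)
      }
      for (k in seq_len(nrow(truth_processed))) {
        s <- truth_processed$strand[k]; p <- truth_processed$position[k]
        texm[[s]][p] <- texm[[s]][p] + nb(1, config$tss_height_mean)
        texp[[s]][p] <- texp[[s]][p] + nb(1, config$tss_height_mean / 2.5)
      }
      add_lib(library_meta(sprintf("%s_TEXp_r%d", cond, r), cond,
                           "five_prime", "plus", r, config$library_size),
              texp[["+"]], texp[["-"]])
      add_lib(library_meta(sprintf("%s_TEXm_r%d", cond, r), cond,
                           "five_prime", "minus", r, config$library_size),
              texm[["+"]], texm[["-"]])
      # Term-seq
      ts <- list("+" = bgv(), "-" = bgv())
      for (k in seq_len(nrow(truth_tep))) {
        i <- match(truth_tep$gene[k], locus)
        if (!act[i]) next
        s <- truth_tep$strand[k]; p <- truth_tep$obs_position[k]
        if (p < 1L || p > L) next
        mu <- config$tep_height_mean * expr_mult[i] *
          if (truth_tep$category[k] == "C") 0.6 else 1
        ts[[s]][p] <- ts[[s]][p] + nb(1, mu)
      }
      add_lib(library_meta(sprintf("%s_term_r%d", cond, r), cond,
                           "three_prime", "na", r, config$library_size),
              ts[["+"]], ts[["-"]])
      # RNA-seq coverage plateau
      cov <- list("+" = bgv(), "-" = bgv())
      depth <- config$tu_coverage_rpm * config$library_size / 1e6
      for (i in which(act)) {
        s <- strand[i]
        span <- sort(c(tss[i], tep[i]))
        idx <- span[1]:span[2]
        cov[[s]][idx] <- cov[[s]][idx] +
          round(depth * expr_mult[i] *
                  stats::rlnorm(length(idx), 0, 0.2))
      }
      add_lib(library_meta(sprintf("%s_cov_r%d", cond, r), cond,
                           "coverage", "na", r, config$library_size),
              cov[["+"]], cov[["-"]])
    }
  }

  structure(list(
    genome = genome, annotation = annotation, signals = signals,
    libraries = dplyr::bind_rows(libraries),
    truth = list(tss = truth_tss, tep = truth_tep, tus = truth_tus,
                 processed = truth_processed),
    config = config
  ), class = "txa_simulation")
}

#' @export
print.txa_simulation <- function(x, ...) {
  cat(sprintf(
    "<txa_simulation> %s nt genome, %d genes, %d libraries, %d TSS / %d TEP planted\n",
    format(x$genome$length, big.mark = ","), nrow(x$annotation),
    length(x$signals), nrow(x$truth$tss), nrow(x$truth$tep)))
  invisible(x)
}

#' Write a simulation to disk as standard formats
#'
#' Emits `genome.fa`, `genes.gff3`, `libraries.tsv`, per-library bedGraph
#' pairs under `signals/`, and truth tables under `truth/`.
#'
#' @param sim A `txa_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(file.path(dir, "signals"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_genome(sim$genome, file.path(dir, "genome.fa"))
  write_annotation(sim$annotation, sim$genome, file.path(dir, "genes.gff3"))
  readr::write_tsv(sim$libraries, file.path(dir, "libraries.tsv"))
  for (id in names(sim$signals)) {
    write_signal(sim$signals[[id]], sim$genome,
                 file.path(dir, "signals", paste0(id, "_plus.bedgraph")),
                 file.path(dir, "signals", paste0(id, "_minus.bedgraph")))
  }
  flat <- function(df) {
    df$conditions <- vapply(df$conditions, paste, "", collapse = ",")
    df
  }
  readr::write_tsv(flat(sim$truth$tss), file.path(dir, "truth", "tss.tsv"))
  readr::write_tsv(flat(sim$truth$tep), file.path(dir, "truth", "tep.tsv"))
  readr::write_tsv(sim$truth$tus, file.path(dir, "truth", "tus.tsv"))
  readr::write_tsv(sim$truth$processed,
                   file.path(dir, "truth", "processed.tsv"))
  invisible(dir)
}
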