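test_that("planted SigA and SigL consensus promoters are detected", {
  models <- sigma_models()
  sigA_prom <- paste0(strrep("C", 8), "TTGACA", strrep("C", 15), "TG",
                      "TATAAT", strrep("C", 13))
  expect_equal(nchar(sigA_prom), 50L)
  h <- scan_window(sigA_prom, models$SigA)
  expect_equal(nrow(h), 1L)
  expect_equal(h$spacer, 17L)

  sigL_prom <- paste0(strrep("A", 20), "TGGCA", "GCGCGC", "TTGC",
                      strrep("A", 15))
  hL <- scan_window(sigL_prom, models$SigL)
  expect_equal(hL$spacer, 6L)
  expect_lte(hL$pvalue, 1e-4)
})

test_that("a TSS promoter can carry hits for several sigma factors", {
  g_seq <- paste0(
    strrep("C", 100),
    # SigH: AGGA -17- GAAT ending 8 nt before the TSS at 151
    paste0(strrep("C", 7), "AGGA", strrep("T", 17), "GAAT", strrep("C", 7),
           "A"),
    strrep("C", 100))
  g <- genome_from_seq(g_seq)
  tss <- make_sites(141L, "+")
  res <- assign_sigma(tss, g)
  expect_true("SigH" %in% res$hits$sigma_name)

  # random promoter sequence below threshold counts as no-motif
  set.seed(3)
  g2 <- genome_from_seq(random_dna(300))
  res2 <- assign_sigma(make_sites(200L, "+"), g2)
  total_hits <- nrow(res2$hits)
  no_motif <- res2$proportions$n_hits[res2$proportions$sigma_name ==
                                        "no_motif"]
  expect_equal(no_motif, as.integer(total_hits == 0))
})

test_that("independent per-model scans make multi-label counts consistent", {
  sim <- simulate_architecture(synthetic_config(
    genome_len = 30000L, n_genes = 20L, seed = 11L))
  tss <- make_sites(sim$truth$tss$position, sim$truth$tss$strand)
  res <- assign_sigma(tss, sim$genome)
  expect_gte(nrow(res$hits), length(unique(res$hits$site_id)))
  prop <- res$proportions[res$proportions$sigma_name != "no_motif", ]
  expect_equal(sum(prop$n_hits), nrow(res$hits))
  if (nrow(res$hits)) {
    expect_equal(sum(prop$proportion), 1, tolerance = 1e-9)
  }
})

test_that("genome-wide upstream scan equals a brute-force placement count", {
  set.seed(13)
  model <- sigma_models()$SigH
  g <- genome_from_seq(random_dna(5000))
  starts <- c(500L, 1500L, 3000L, 4200L)
  ann <- annotation_from_genes(tibble::tibble(
    locus_tag = sprintf("g%d", 1:4),
    strand = c("+", "-", "+", "-"),
    start = starts, end = starts + 300L))
  # plant an exact SigH site 80 nt upstream of g1 (its -10 block start)
  core <- paste0("AGGA", strrep("A", 17), "GAAT")
  gseq <- g$seq
  substr(gseq, 500L - 80L, 500L - 80L + nchar(core) - 1L) <- core
  g <- genome_from_seq(gseq)
  hits <- scan_upstream_genome(ann, g, model, upstream_len = 200L,
                               pvalue_threshold = 1e-4)
  expect_gte(nrow(hits), 1L)
  expect_true("g1" %in% hits$locus_tag)

  # brute force: score every placement in every upstream window directly
  word_score <- function(wd, pwms) {
    s <- 0
    k <- 1L
    for (p in pwms) for (j in seq_len(p$width)) {
      s <- s + log2(p$probs[substr(wd, k, k), j] / 0.25)
      k <- k + 1L
    }
    s
  }
  col_scores <- c(
    lapply(1:4, function(j) log2(model$pwm_up$probs[, j] / 0.25)),
    lapply(1:4, function(j) log2(model$pwm_down$probs[, j] / 0.25)))
  all_scores <- Reduce(function(a, b) as.vector(outer(a, b, "+")),
                       col_scores)
  brute_total <- 0L
  for (i in 1:4) {
    fp <- ann$five_prime[i]
    win <- if (ann$strand[i] == "+") {
      substr(g$seq, fp - 200L, fp - 1L)
    } else {
      txarch_revcomp <- function(s)
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      txarch_revcomp(substr(g$seq, fp + 1L, fp + 200L))
    }
    for (sp in model$spacer_lengths) {
      for (u in seq_len(nchar(win) - (4 + sp + 4) + 1L)) {
        wd <- paste0(substr(win, u, u + 3L),
                     substr(win, u + 4L + sp, u + 4L + sp + 3L))
        sc <- word_score(wd, list(model$pwm_up, model$pwm_down))
        pv <- mean(all_scores >= sc - 1e-9)
        if (pv <= 1e-4) brute_total <- brute_total + 1L
      }
    }
  }
  expect_equal(nrow(hits), brute_total)

  # a zero threshold empties the table
  expect_equal(nrow(scan_upstream_genome(ann, g, model,
                                         pvalue_threshold = 0)), 0L)
})
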