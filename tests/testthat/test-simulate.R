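small_cfg <- function(seed = 7L, ...) {
  synthetic_config(genome_len = 30000L, n_genes = 20L, seed = seed, ...)
}

test_that("the generator is byte-reproducible from its seed", {
  a <- simulate_architecture(small_cfg())
  b <- simulate_architecture(small_cfg())
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$truth, b$truth)
  expect_identical(a$signals[["CO2_TEXp_r1"]]$plus,
                   b$signals[["CO2_TEXp_r1"]]$plus)
  c2 <- simulate_architecture(small_cfg(seed = 8L))
  expect_false(identical(a$genome$seq, c2$genome$seq))
})

test_that("in the noise-free limit TEX+ signal sits only on planted TSSs", {
  sim <- simulate_architecture(small_cfg(
    background_rate_per_nt = 0, jitter_sd = 0, processed_site_rate = 0))
  sig <- sim$signals[["CO2_TEXp_r1"]]
  active <- vapply(sim$truth$tss$conditions, function(cc) "CO2" %in% cc,
                   logical(1))
  for (s in c("+", "-")) {
    nz <- which((if (s == "+") sig$plus else sig$minus) > 0)
    planted <- sim$truth$tss$position[sim$truth$tss$strand == s & active]
    expect_true(all(nz %in% planted))
  }
})

test_that("planted architecture is internally consistent", {
  sim <- simulate_architecture(small_cfg())
  tr <- sim$truth
  # every TU references planted sites
  expect_true(all(tr$tus$tss_position %in% tr$tss$position))
  expect_true(all(tr$tus$tep_position %in% tr$tep$position))
  # gene bookkeeping: one primary TSS/TEP per gene
  expect_equal(sort(tr$tss$gene), sort(sim$annotation$locus_tag))
  # condition-specific fraction is recorded per site
  spec_n <- sum(grepl("^condition-specific", tr$tss$condition_label))
  expect_equal(spec_n,
               sum(vapply(tr$tss$conditions, length, 1L) == 1L))
  # planted UTR lengths match the coordinates
  fp <- sim$annotation$five_prime[match(tr$tss$gene,
                                        sim$annotation$locus_tag)]
  expect_equal(abs(fp - tr$tss$position), tr$tss$utr5)
})

test_that("generator UTR lengths hit the configured medians", {
  withr::with_seed(1, {
    u5 <- txarch:::draw_utr5(20000)
    u3 <- txarch:::draw_utr3(20000)
  })
  expect_lt(abs(median(u5) - 45), 3)
  expect_lt(abs(median(u3) - 64), 3)
  # modal decade of the 5'-UTR distribution is 20-29 nt
  decade <- table(u5 %/% 10L)
  expect_equal(names(which.max(decade)), "2")
})

test_that("simulation files round-trip through standard formats", {
  sim <- simulate_architecture(synthetic_config(
    genome_len = 12000L, n_genes = 6L, seed = 3L))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  g <- read_genome(file.path(dir, "genome.fa"))
  expect_equal(g$seq, sim$genome$seq)
  ann <- read_annotation(file.path(dir, "genes.gff3"), g)
  expect_equal(ann$start, sim$annotation$start)
  expect_equal(ann$five_prime, sim$annotation$five_prime)
  libs <- readr::read_tsv(file.path(dir, "libraries.tsv"),
                          show_col_types = FALSE)
  id <- libs$library_id[1]
  meta <- library_meta(id, libs$condition[1], libs$role[1],
                       libs$tex_status[1], libs$replicate[1],
                       libs$total_mapped_reads[1])
  back <- read_signal(file.path(dir, "signals", paste0(id, "_plus.bedgraph")),
                      meta, g,
                      minus_path = file.path(dir, "signals",
                                             paste0(id, "_minus.bedgraph")))
  expect_equal(back$plus, sim$signals[[id]]$plus)
  expect_equal(back$minus, sim$signals[[id]]$minus)
})

test_that("score_recovery implements the greedy matching contract", {
  sim <- simulate_architecture(small_cfg())
  truth <- sim$truth
  perfect <- list(
    tss = make_sites(truth$tss$position, truth$tss$strand) |>
      dplyr::mutate(condition_label = truth$tss$condition_label),
    tep = make_sites(truth$tep$position, truth$tep$strand,
                     site_class = "TEP") |>
      dplyr::mutate(condition_label = truth$tep$condition_label),
    tus = NULL)
  r <- score_recovery(truth, perfect)
  expect_equal(r$tss$recall, 1.0)
  expect_equal(r$tss$precision, 1.0)
  expect_equal(r$tss$label_agreement, 1.0)

  # empty calls: recall 0, precision reported 1 with a zero-calls flag
  none <- list(tss = perfect$tss[0, ], tep = perfect$tep[0, ], tus = NULL)
  r0 <- score_recovery(truth, none)
  expect_equal(r0$tss$recall, 0)
  expect_equal(r0$tss$precision, 1.0)
  expect_true(r0$tss$zero_calls)

  # a call 2 nt off with tolerance 1 stays unmatched
  one_truth <- list(tss = truth$tss[1, ], tep = truth$tep[0, ],
                    tus = truth$tus[0, ], processed = truth$processed)
  off <- list(tss = make_sites(truth$tss$position[1] + 2L,
                               truth$tss$strand[1]),
              tep = perfect$tep[0, ], tus = NULL)
  r2 <- score_recovery(one_truth, off, tolerance_nt = 1L)
  expect_equal(r2$tss$recall, 0)
  expect_equal(r2$tss$precision, 0)
})

test_that("TSS recall degrades monotonically as background noise grows", {
  lo <- simulate_architecture(small_cfg())
  hi <- simulate_architecture(small_cfg(background_rate_per_nt = 0.5))
  rec_lo <- score_recovery(lo$truth, run_pipeline(lo))
  rec_hi <- score_recovery(hi$truth, run_pipeline(hi))
  expect_lte(rec_hi$tss$recall, rec_lo$tss$recall)
  expect_gte(rec_lo$tss$recall, 0.9)
})
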