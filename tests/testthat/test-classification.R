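cp <- classification_params()

simple_ann <- annotation_from_genes(tibble::tibble(
  locus_tag = c("gA", "gB"),
  strand = c("+", "-"),
  start = c(500L, 2000L),
  end = c(1000L, 2600L)))

test_that("sole upstream TSS is primary with the expected UTR length", {
  s <- make_sites(450L, "+", height = 30)
  ann <- classify_tss(s, simple_ann, cp)
  expect_equal(ann$category, "P")
  expect_equal(ann$gene, "gA")
  expect_equal(ann$utr_len, 50L)

  # minus-strand gene: 5' end is the high coordinate
  s2 <- make_sites(2650L, "-", height = 30)
  ann2 <- classify_tss(s2, simple_ann, cp)
  expect_equal(ann2$category, "P")
  expect_equal(ann2$utr_len, 50L)
})

test_that("higher peak wins primary, the lower becomes secondary", {
  s <- dplyr::bind_rows(make_sites(450L, "+", height = 40),
                        make_sites(420L, "+", height = 10))
  ann <- classify_tss(s, simple_ann, cp)
  expect_equal(ann$category[ann$position == 450], "P")
  expect_equal(ann$category[ann$position == 420], "S")
  expect_equal(sort(ann$utr_len), c(50L, 80L))
})

test_that("internal, antisense and intergenic categories follow position", {
  s <- dplyr::bind_rows(
    make_sites(700L, "+", height = 5),    # inside gA, sense
    make_sites(800L, "-", height = 5),    # inside gA, antisense
    make_sites(1500L, "+", height = 5))   # between genes, far from both 5'
  ann <- classify_tss(s, simple_ann, cp)
  expect_equal(ann$category[ann$position == 700], "I")
  expect_equal(ann$category[ann$position == 800], "A")
  expect_equal(ann$category[ann$position == 1500], "N")
})

test_that("TEP classification adds the cis-regulatory category", {
  tss <- classify_tss(make_sites(380L, "+", height = 30), simple_ann, cp)
  teps <- dplyr::bind_rows(
    make_sites(1060L, "+", height = 20, site_class = "TEP"),  # 60 nt 3'-UTR
    make_sites(450L, "+", height = 8, site_class = "TEP"),    # inside 5'-UTR
    make_sites(9000L, "+", height = 8, site_class = "TEP"))   # far away
  ann <- classify_tep(teps, simple_ann, tss, cp)
  expect_equal(ann$category[ann$position == 1060], "P")
  expect_equal(ann$utr_len[ann$position == 1060], 60L)
  expect_equal(ann$category[ann$position == 450], "C")
  expect_equal(ann$category[ann$position == 9000], "N")
})

test_that("category counts always partition the site list", {
  set.seed(5)
  for (k in 1:20) {
    sites <- random_layout(n_sites = 25L)
    ann <- classify_tss(sites, simple_ann, cp)
    expect_equal(sum(table(ann$category)), nrow(sites))
    expect_true(all(ann$category %in% c("P", "S", "I", "A", "N")))
    ps <- ann$category %in% c("P", "S")
    expect_true(all(!is.na(ann$utr_len[ps])))
    expect_true(all(ann$utr_len[ps] >= 0))
  }
})

test_that("classification equals the brute-force oracle on random layouts", {
  set.seed(17)
  for (k in 1:60) {
    sites <- random_layout()
    starts <- sort(sample(seq(100L, 9000L), 6))
    ann_tbl <- annotation_from_genes(tibble::tibble(
      locus_tag = sprintf("g%02d", 1:6),
      strand = sample(c("+", "-"), 6, replace = TRUE),
      start = starts,
      end = starts + sample(150:600, 6)))
    got <- classify_tss(sites, ann_tbl, cp)
    want <- oracle_classify(sites, ann_tbl, cp, "TSS")
    expect_equal(got$category, want$category)
    expect_equal(got$utr_len, want$utr_len)

    teps <- random_layout(n_sites = 15L, site_class = "TEP")
    got_tep <- classify_tep(teps, ann_tbl, got, cp)
    want_tep <- oracle_classify(teps, ann_tbl, cp, "TEP",
                                tss_annotated = got)
    expect_equal(got_tep$category, want_tep$category)
    expect_equal(got_tep$utr_len, want_tep$utr_len)
  }
})

test_that("mirror-genome symmetry preserves categories and UTR lengths", {
  set.seed(23)
  L <- 10000L
  for (k in 1:10) {
    sites <- random_layout()
    ann_tbl <- annotation_from_genes(tibble::tibble(
      locus_tag = c("g1", "g2", "g3"),
      strand = sample(c("+", "-"), 3, replace = TRUE),
      start = c(1000L, 4000L, 7000L),
      end = c(1000L, 4000L, 7000L) + sample(200:800, 3)))
    fwd <- classify_tss(sites, ann_tbl, cp)
    mirrored_sites <- sites
    mirrored_sites$position <- L + 1L - sites$position
    mirrored_sites$strand <- ifelse(sites$strand == "+", "-", "+")
    rev <- classify_tss(mirrored_sites, mirror_ann(ann_tbl, L), cp)
    expect_equal(rev$category, fwd$category)
    expect_equal(rev$utr_len, fwd$utr_len)
  }
})

test_that("utr_stats reports medians, bins and the leaderless boundary", {
  mk_ann <- function(utrs) {
    tibble::tibble(category = "P", utr_len = as.integer(utrs))
  }
  s <- utr_stats(mk_ann(45))
  expect_equal(s$five$median, 45)
  expect_equal(utr_stats(mk_ann(c(20, 45, 64)))$five$median, 45)

  lb <- utr_stats(mk_ann(c(5, 45)))
  expect_equal(lb$five$leaderless_count, 1L)
  expect_equal(lb$five$leadered_count, 1L)
  # boundary value 10 is leaderless ("longer than 10 nt" means leadered)
  expect_equal(utr_stats(mk_ann(10))$five$leaderless_count, 1L)

  h <- utr_stats(mk_ann(c(0, 9, 10, 19, 23)))$five$histogram
  expect_equal(h$count[h$bin_start == 0], 2L)
  expect_equal(h$count[h$bin_start == 10], 2L)
  expect_equal(h$count[h$bin_start == 20], 1L)

  expect_equal(utr_stats(mk_ann(integer(0)))$five$n, 0L)
})

test_that("composition extracts strand-aware bases around +1", {
  g <- genome_from_seq("AACGT")
  plus_site <- make_sites(3L, "+")
  comp <- composition(plus_site, g)
  expect_equal(comp$C[comp$offset == 1], 1)   # +1 base is C
  expect_equal(comp$A[comp$offset == -1], 1)
  expect_equal(comp$G[comp$offset == 2], 1)

  minus_site <- make_sites(3L, "-")
  comp_m <- composition(minus_site, g)
  expect_equal(comp_m$G[comp_m$offset == 1], 1)   # complement of C
  expect_equal(comp_m$C[comp_m$offset == -1], 1)  # complement of G at pos 4

  # +1 bases C and G at two full-window sites
  comp2 <- composition(make_sites(c(3L, 4L), c("+", "+")), g)
  expect_equal(comp2$C[comp2$offset == 1], 0.5)
  expect_equal(comp2$G[comp2$offset == 1], 0.5)
  expect_true(all(abs(rowSums(comp2[, c("A", "C", "G", "T")]) - 1) < 1e-9))
})

test_that("rbs_scan finds planted Shine-Dalgarno motifs in leadered UTRs", {
  utr5 <- 40L
  lead <- paste0(strrep("C", 60), "AGGAGG", "CCCCCCC")   # RBS 7 nt upstream
  genome_seq <- paste0(lead, "ATG", strrep("GACT", 50))
  g <- genome_from_seq(genome_seq)
  fp <- nchar(lead) + 1L
  ann_tbl <- annotation_from_genes(tibble::tibble(
    locus_tag = "g1", strand = "+", start = fp, end = fp + 120L))
  tss <- classify_tss(make_sites(fp - utr5, "+", height = 20), ann_tbl, cp)
  res <- rbs_scan(tss, ann_tbl, g)
  expect_equal(res$fraction, 1.0)
  expect_true(res$per_utr$hit[1])

  # all-C upstream window: no AG-rich hit
  g2 <- genome_from_seq(paste0(strrep("C", 73), "ATG", strrep("GACT", 50)))
  ann2 <- annotation_from_genes(tibble::tibble(
    locus_tag = "g1", strand = "+", start = 74L, end = 194L))
  tss2 <- classify_tss(make_sites(74L - utr5, "+", height = 20), ann2, cp)
  res2 <- rbs_scan(tss2, ann2, g2)
  expect_equal(res2$fraction, 0.0)

  # fraction averages hits and misses
  both <- rbind(res$per_utr, res2$per_utr)
  expect_equal(mean(both$hit), 0.5)
})
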