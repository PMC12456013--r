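params_nosupp <- peak_call_params(min_height_rpm = 5, enrichment_min = 2,
                                  pseudocount = 1, local_max_window = 2,
                                  downstream_support_min_cov = 0)

test_that("TSS calling applies height, enrichment and local-max rules", {
  len <- 50L
  texp <- make_signal(len, plus = c("20" = 20, "21" = 3), tex = "plus")
  texm <- make_signal(len, plus = c("20" = 4, "21" = 3), id = "l2",
                      tex = "minus")
  peaks <- call_tss_peaks(list(texp), list(texm), NULL, params_nosupp)
  expect_equal(nrow(peaks), 1L)
  expect_equal(peaks$position, 20L)
  expect_equal(peaks$enrichment, (20 + 1) / (4 + 1))
  expect_equal(peaks$height_rpm, 20)
  expect_equal(peaks$site_class, "TSS")

  # stricter enrichment excludes the peak
  strict <- params_nosupp; strict$enrichment_min <- 10
  expect_equal(nrow(call_tss_peaks(list(texp), list(texm), NULL, strict)), 0L)

  # nothing passes on an empty track
  zero <- make_signal(len)
  expect_equal(nrow(call_tss_peaks(list(zero), list(texm), NULL,
                                   params_nosupp)), 0L)
})

test_that("TSS local-maximum ties break to the 5'-most position per strand", {
  len <- 60L
  texp <- make_signal(len, plus = c("30" = 10, "31" = 10),
                      minus = c("40" = 10, "41" = 10))
  texm <- make_signal(len, id = "l2", tex = "minus")
  peaks <- call_tss_peaks(list(texp), list(texm), NULL, params_nosupp)
  expect_equal(peaks$position[peaks$strand == "+"], 30L)
  expect_equal(peaks$position[peaks$strand == "-"], 41L)
})

test_that("TEP calling skips enrichment and ties to the 3'-most position", {
  len <- 60L
  ts <- make_signal(len, plus = c("30" = 8, "31" = 9),
                    role = "three_prime", tex = "na")
  peaks <- call_tep_peaks(list(ts), NULL, params_nosupp)
  expect_equal(peaks$position, 31L)
  expect_true(is.na(peaks$enrichment))

  tie <- make_signal(len, plus = c("30" = 9, "31" = 9),
                     role = "three_prime", tex = "na")
  peaks <- call_tep_peaks(list(tie), NULL, params_nosupp)
  expect_equal(peaks$position, 31L)

  expect_equal(nrow(call_tep_peaks(list(make_signal(len, role = "three_prime",
                                                    tex = "na")),
                                   NULL, params_nosupp)), 0L)
})

test_that("coverage support filter gates isolated peaks", {
  len <- 200L
  texp <- make_signal(len, plus = c("50" = 30, "150" = 30))
  texm <- make_signal(len, id = "l2", tex = "minus")
  # coverage only downstream of position 50
  covp <- numeric(len); covp[50:120] <- 10
  cov <- stranded_signal(
    library_meta("cov", "CO2", "coverage", total_mapped_reads = 1e6),
    covp, numeric(len))
  p <- peak_call_params(min_height_rpm = 5, enrichment_min = 2,
                        downstream_support_len = 50,
                        downstream_support_min_cov = 1)
  peaks <- call_tss_peaks(list(texp), list(texm), cov, p)
  expect_equal(peaks$position, 50L)
})

test_that("replicate fraction controls peak acceptance", {
  len <- 50L
  t1 <- make_signal(len, plus = c("20" = 20))
  t2 <- make_signal(len, id = "l3", rep = 2L)   # empty second replicate
  m1 <- make_signal(len, id = "l2", tex = "minus")
  m2 <- make_signal(len, id = "l4", tex = "minus", rep = 2L)
  half <- params_nosupp; half$replicate_min_fraction <- 0.5
  both <- params_nosupp; both$replicate_min_fraction <- 1.0
  expect_equal(call_tss_peaks(list(t1, t2), list(m1, m2), NULL,
                              half)$position, 20L)
  expect_equal(nrow(call_tss_peaks(list(t1, t2), list(m1, m2), NULL, both)),
               0L)
  expect_error(call_tss_peaks(list(t1), list(m2), NULL, half),
               "no TEX")
})

test_that("reproducibility matches hand-computed Pearson correlations", {
  len <- 100L
  sites <- make_sites(c(10L, 20L, 30L), rep("+", 3))
  s1 <- make_signal(len, plus = c("10" = 1, "20" = 2, "30" = 4))
  s2 <- make_signal(len, plus = c("10" = 2, "20" = 3, "30" = 9), id = "l2")
  rep1 <- reproducibility(list(s1, s1), sites)
  expect_equal(rep1$median_r, 1.0)

  s0 <- make_signal(len, plus = c("10" = 1, "20" = 2, "30" = 3), id = "l0")
  s3 <- make_signal(len, plus = c("10" = 3, "20" = 2, "30" = 1), id = "l3")
  expect_equal(reproducibility(list(s0, s3), sites)$median_r, -1.0)

  # direct formula on (1,2,4) vs (2,3,9): 102/sqrt(42*258)
  expect_equal(reproducibility(list(s1, s2), sites)$median_r,
               102 / sqrt(42 * 258), tolerance = 1e-12)

  # zero-variance pair is excluded with a warning
  s4 <- make_signal(len, plus = c("10" = 5, "20" = 5, "30" = 5), id = "l4")
  w <- testthat::capture_warnings(r <- reproducibility(list(s1, s2, s4),
                                                       sites))
  expect_true(all(grepl("zero-variance", w)))
  expect_equal(nrow(r$pairs), 1L)
})

test_that("merge_sites merges within tolerance and labels conditions", {
  a <- make_sites(100L, "+", height = 30, condition = "CO2")
  b <- make_sites(103L, "+", height = 20, condition = "betaine")
  m <- merge_sites(dplyr::bind_rows(a, b), merge_params(5))
  expect_equal(nrow(m), 1L)
  expect_equal(m$position, 100L)            # highest member wins
  expect_equal(m$condition_label, "constitutive")
  expect_setequal(m$conditions[[1]], c("CO2", "betaine"))

  b7 <- make_sites(107L, "+", height = 20, condition = "betaine")
  m2 <- merge_sites(dplyr::bind_rows(a, b7), merge_params(5))
  expect_equal(nrow(m2), 2L)
  expect_true(all(grepl("^condition-specific", m2$condition_label)))

  # single condition -> all condition-specific
  m3 <- merge_sites(a, merge_params(5))
  expect_equal(m3$condition_label, "condition-specific:CO2")
})

test_that("merge_sites chains transitively and keeps member positions", {
  chain <- dplyr::bind_rows(
    make_sites(100L, "+", height = 5, condition = "CO2"),
    make_sites(104L, "+", height = 9, condition = "betaine"),
    make_sites(108L, "+", height = 7, condition = "CO2"))
  m <- merge_sites(chain, merge_params(5))
  expect_equal(nrow(m), 1L)
  expect_equal(m$position, 104L)
  expect_true(m$position %in% chain$position)
})

test_that("merge_sites is idempotent and permutation-invariant", {
  set.seed(31)
  peaks <- dplyr::bind_rows(lapply(c("CO2", "betaine"), function(cc) {
    make_sites(sort(sample(1:2000, 60)),
               sample(c("+", "-"), 60, replace = TRUE),
               height = sample(5:50, 60, replace = TRUE), condition = cc)
  }))
  m <- merge_sites(peaks, merge_params(5))
  expect_equal(merge_sites(m, merge_params(5)), m)
  for (k in 1:5) {
    shuffled <- peaks[sample(nrow(peaks)), ]
    expect_equal(merge_sites(shuffled, merge_params(5)), m)
  }
  # strictly increasing positions per strand
  for (s in c("+", "-")) {
    expect_true(all(diff(m$position[m$strand == s]) > 0))
  }
  expect_error(merge_sites(dplyr::bind_rows(
    make_sites(10L, "+", site_class = "TSS"),
    make_sites(20L, "+", site_class = "TEP"))), "mixed")
})
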