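test_that("read_genome parses, normalizes case, and maps odd characters to N", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g", "ACGT"), f)
  g <- read_genome(f)
  expect_s3_class(g, "txa_genome")
  expect_equal(g$length, 4L)
  expect_equal(g$seq, "ACGT")

  writeLines(c(">g", "acgt"), f)
  expect_equal(read_genome(f)$seq, "ACGT")

  writeLines(c(">g", "ACXRT"), f)
  expect_equal(read_genome(f)$seq, "ACNNT")
})

test_that("read_genome rejects empty and multi-record files", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">b", "GGGG"), f)
  expect_error(read_genome(f), "expected 1 record, found 2")
  writeLines(character(0), f)
  expect_error(read_genome(f))
})

test_that("read_annotation derives strand-aware gene ends and checks bounds", {
  g <- genome_from_seq(strrep("ACGT", 200))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\ttest\tCDS\t100\t400\t.\t+\t0\tID=fwd;locus_tag=fwd",
    "chr\ttest\tCDS\t500\t700\t.\t-\t0\tID=rev;locus_tag=rev"), f)
  ann <- read_annotation(f, g)
  expect_equal(ann$five_prime[ann$locus_tag == "fwd"], 100L)
  expect_equal(ann$three_prime[ann$locus_tag == "fwd"], 400L)
  expect_equal(ann$five_prime[ann$locus_tag == "rev"], 700L)
  expect_equal(ann$three_prime[ann$locus_tag == "rev"], 500L)

  writeLines(c(
    "##gff-version 3",
    "chr\ttest\tCDS\t100\t1000000000\t.\t+\t0\tID=x;locus_tag=x"), f)
  expect_error(read_annotation(f, g), "exceeds genome length")
})

test_that("bedGraph ingestion expands 0-based half-open intervals", {
  g <- genome_from_seq(strrep("A", 10))
  meta <- library_meta("l1", "CO2", "coverage", total_mapped_reads = 1e6)
  f1 <- withr::local_tempfile(fileext = ".bedgraph")
  f2 <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr\t0\t3\t5.0", f1)
  writeLines(character(0), f2)
  sig <- read_signal(f1, meta, g, minus_path = f2)
  expect_equal(sig$plus, c(5, 5, 5, rep(0, 7)))
  expect_equal(sig$minus, rep(0, 10))

  # clipped with warning beyond genome end
  writeLines("chr\t8\t15\t2", f1)
  expect_warning(sig <- read_signal(f1, meta, g, minus_path = f2),
                 "clipped")
  expect_equal(sig$plus[9:10], c(2, 2))

  # signed dialect: negative values carry the minus strand
  writeLines(c("chr\t0\t2\t4", "chr\t5\t6\t-7"), f1)
  sig <- read_signal(f1, meta, g, dialect = "signed")
  expect_equal(sig$plus[1:2], c(4, 4))
  expect_equal(sig$minus[6], 7)

  # negative value in unsigned dialect is an error
  writeLines("chr\t0\t2\t-4", f1)
  expect_error(read_signal(f1, meta, g, minus_path = f2), "negative")
})

test_that("signal round trip through bedGraph preserves nonzero positions", {
  g <- genome_from_seq(strrep("C", 50))
  set.seed(11)
  pv <- numeric(50); pv[sample(50, 8)] <- sample(1:20, 8)
  mv <- numeric(50); mv[sample(50, 5)] <- sample(1:20, 5)
  meta <- library_meta("l1", "CO2", "three_prime", total_mapped_reads = 1e6)
  sig <- stranded_signal(meta, pv, mv)
  fp <- withr::local_tempfile(); fm <- withr::local_tempfile()
  write_signal(sig, g, fp, fm)
  back <- read_signal(fp, meta, g, minus_path = fm)
  expect_equal(back$plus, pv)
  expect_equal(back$minus, mv)
})

test_that("site TSV/BED output round-trips and BED is 0-based", {
  sites <- make_sites(c(100L, 250L), c("+", "-"), height = c(40, 9.5))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_sites(sites, tsv, bed)
  back <- read_sites(tsv)
  expect_equal(back$position, sites$position)
  expect_equal(back$conditions, sites$conditions, ignore_attr = TRUE)
  expect_equal(back$per_condition_height, sites$per_condition_height,
               ignore_attr = TRUE)
  bed_df <- read.table(bed, sep = "\t")
  expect_equal(bed_df$V2, sites$position - 1L)
  expect_equal(bed_df$V3, sites$position)

  # empty input still writes a header-only TSV
  write_sites(sites[0, ], tsv, NULL)
  expect_equal(nrow(read_sites(tsv)), 0L)
})

test_that("TU GFF3/TSV output round-trips with declared feature types", {
  tus <- tibble::tibble(
    tu_id = c("TU_0001", "TU_0002"), tss_ref = c("a", "b"),
    tep_ref = c("c", "d"), strand = c("+", "-"),
    start = c(100L, 900L), end = c(600L, 1500L), length = c(501L, 601L),
    support_fraction = c(1, 0.95), genes = list(c("g1", "g2"), character(0)))
  cl <- cluster_tus(tus)
  gff <- withr::local_tempfile(fileext = ".gff3")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tus(tus, cl, gff, tsv)
  lines <- readLines(gff)
  expect_true(any(grepl("\ttranscription_unit\t", lines)))
  expect_true(any(grepl("\tTU_cluster\t", lines)))
  back <- read_tus(tsv)
  expect_equal(back$tu_id, tus$tu_id)
  expect_equal(back$genes, tus$genes, ignore_attr = TRUE)
})
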