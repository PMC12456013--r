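#' Read a single-chromosome genome from FASTA
#'
#' Reads one genome record, uppercases it, and maps any character outside
#' A/C/G/T/N to N. The pipeline assumes a single (bacterial) chromosome;
#' multi-record files are rejected. Circularity is not modelled: windows that
#' run off either end are truncated.
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @return A `txa_genome` object: list with `seq_id`, `seq` (single uppercase
#'   string over ACGTN) and `length` (nt).
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) abort("empty FASTA: no records found")
  if (length(seqs) != 1L) {
    abort(sprintf("expected 1 record, found %d", length(seqs)))
  }
  residues <- toupper(as.character(seqs[[1]]))
  residues <- gsub("[^ACGTN]", "N", residues)
  new_genome(names(seqs)[1], residues)
}

new_genome <- function(seq_id, seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0L) abort("genome length must be > 0")
  structure(
    list(seq_id = unname(seq_id), seq = seq, length = n),
    class = "txa_genome"
  )
}

#' Construct a genome object from a sequence string
#'
#' Mostly useful for tests and simulations; [read_genome()] is the file-based
#' entry point.
#'
#' @param seq A character scalar over A/C/G/T/N (lowercase accepted).
#' @param seq_id Sequence identifier.
#' @return A `txa_genome` object.
#' @export
genome_from_seq <- function(seq, seq_id = "chr") {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) seq <- gsub("[^ACGTN]", "N", seq)
  new_genome(seq_id, seq)
}

#' @export
print.txa_genome <- function(x, ...) {
  cat(sprintf("<txa_genome> %s: %s nt\n", x$seq_id,
              format(x$length, big.mark = ",")))
  invisible(x)
}

#' Write a genome to FASTA
#'
#' @param genome A `txa_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$seq)
  names(set) <- genome$seq_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Extract [start, end] (1-based inclusive) from the given strand, truncating
# at genome ends. Minus-strand sequence is reverse-complemented so it always
# reads 5'->3'. Returns "" when the window is entirely off-genome.
genome_window <- function(genome, start, end, strand = "+") {
  check_strand(strand)
  start <- max(1L, as.integer(start))
  end <- min(genome$length, as.integer(end))
  if (end < start) return("")
  s <- substr(genome$seq, start, end)
  if (strand == "-") s <- revcomp(s)
  s
}

revcomp <- function(s) {
  if (nchar(s) == 0L) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Read a gene annotation from GFF3
#'
#' Keeps CDS, tRNA, rRNA and ncRNA features (gene features are used when a
#' type lacks its own rows) and derives the strand-aware transcriptional
#' 5'/3' ends of each gene. Coordinates are 1-based inclusive throughout the
#' package (GFF3 convention); BED/bedGraph are converted at the boundary.
#'
#' @param path Path to a GFF3 file.
#' @param genome A `txa_genome`; features beyond its length are rejected.
#' @return A `txa_annotation`: tibble with columns `locus_tag`,
#'   `feature_type`, `strand`, `start`, `end`, `five_prime`, `three_prime`.
#' @export
read_annotation <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  keep_types <- c("CDS", "tRNA", "rRNA", "ncRNA")
  df <- df[as.character(df$type) %in% keep_types, , drop = FALSE]
  if (nrow(df) == 0L) abort("no CDS/tRNA/rRNA/ncRNA features found in GFF3")
  locus <- if ("locus_tag" %in% names(df)) as.character(df$locus_tag) else
    rep(NA_character_, nrow(df))
  if ("ID" %in% names(df)) {
    locus <- ifelse(is.na(locus), as.character(df$ID), locus)
  }
  missing <- is.na(locus)
  if (any(missing)) {
    warn(sprintf("%d features lack locus_tag; synthesized stable ids",
                 sum(missing)))
    locus[missing] <- sprintf("feat_%s_%d_%d",
                              as.character(df$strand)[missing],
                              df$start[missing], df$end[missing])
  }
  ann <- annotation_from_genes(tibble(
    locus_tag = locus,
    feature_type = as.character(df$type),
    strand = as.character(df$strand),
    start = as.integer(df$start),
    end = as.integer(df$end)
  ))
  if (any(ann$end > genome$length)) {
    abort(sprintf("feature end %d exceeds genome length %d",
                  max(ann$end), genome$length))
  }
  ann
}

#' Build an annotation from a gene table
#'
#' @param genes Data frame with columns `locus_tag`, `strand`, `start`, `end`
#'   and optionally `feature_type` (default `"CDS"`).
#' @return A `txa_annotation` tibble sorted by `start`.
#' @export
annotation_from_genes <- function(genes) {
  genes <- as_tibble(genes)
  if (!"feature_type" %in% names(genes)) genes$feature_type <- "CDS"
  check_strand(genes$strand)
  if (any(genes$end < genes$start)) abort("gene end < start")
  if (anyDuplicated(genes$locus_tag)) abort("locus_tags must be unique")
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$five_prime <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$three_prime <- ifelse(genes$strand == "+", genes$end, genes$start)
  genes <- genes[order(genes$start, genes$end), c(
    "locus_tag", "feature_type", "strand", "start", "end",
    "five_prime", "three_prime")]
  class(genes) <- c("txa_annotation", class(genes))
  genes
}

#' Write an annotation as GFF3
#'
#' @param annotation A `txa_annotation`.
#' @param genome A `txa_genome` (provides the seqid).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, genome, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genome$seq_id,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand,
    type = annotation$feature_type,
    phase = ifelse(annotation$feature_type == "CDS", 0L, NA_integer_),
    locus_tag = annotation$locus_tag,
    ID = annotation$locus_tag
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# Mirror an annotation through the reverse complement of its genome:
# positions p -> L + 1 - p, strands flip. Used by symmetry tests.
mirror_annotation <- function(annotation, genome_len) {
  annotation_from_genes(tibble(
    locus_tag = annotation$locus_tag,
    feature_type = annotation$feature_type,
    strand = ifelse(annotation$strand == "+", "-", "+"),
    start = genome_len + 1L - annotation$end,
    end = genome_len + 1L - annotation$start
  ))
}
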