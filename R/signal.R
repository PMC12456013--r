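#' Describe one sequencing library
#'
#' Metadata for a stranded per-position track. `role` states what the track
#' counts: `five_prime` (dRNA-seq 5'-end counts), `three_prime` (Term-seq
#' 3'-end counts) or `coverage` (RNA-seq per-base depth). `tex_status`
#' records terminator-exonuclease treatment and is meaningful only for
#' 5'-end libraries.
#'
#' @param library_id Unique library identifier.
#' @param condition Growth condition label (e.g. `"CO2"`, `"betaine"`).
#' @param role One of `"five_prime"`, `"three_prime"`, `"coverage"`.
#' @param tex_status `"plus"`, `"minus"`, or `"na"` (required `"na"` unless
#'   `role = "five_prime"`).
#' @param replicate Replicate index (>= 1).
#' @param total_mapped_reads Library size used for RPM normalization. Taken
#'   from the mapping statistics, not the track sum, so partial tracks
#'   normalize correctly.
#' @return A one-row tibble of class `txa_library_meta`.
#' @export
library_meta <- function(library_id, condition, role,
                         tex_status = "na", replicate = 1L,
                         total_mapped_reads = 1e6) {
  role <- match.arg(role, c("five_prime", "three_prime", "coverage"))
  tex_status <- match.arg(tex_status, c("plus", "minus", "na"))
  if ((role == "five_prime") == (tex_status == "na")) {
    abort("tex_status must be plus/minus for five_prime libraries and 'na' otherwise")
  }
  if (total_mapped_reads <= 0) abort("total_mapped_reads must be > 0")
  if (replicate < 1) abort("replicate must be >= 1")
  meta <- tibble(
    library_id = as.character(library_id),
    condition = as.character(condition),
    role = role,
    tex_status = tex_status,
    replicate = as.integer(replicate),
    total_mapped_reads = as.numeric(total_mapped_reads)
  )
  class(meta) <- c("txa_library_meta", class(meta))
  meta
}

#' Construct a stranded signal from count vectors
#'
#' @param meta A [library_meta()] row.
#' @param plus,minus Non-negative per-position count vectors, one entry per
#'   genome position.
#' @return A `txa_signal` object.
#' @export
stranded_signal <- function(meta, plus, minus) {
  if (length(plus) != length(minus)) {
    abort("plus and minus vectors must have equal length")
  }
  if (any(plus < 0) || any(minus < 0)) abort("counts must be >= 0")
  structure(
    list(meta = meta, plus = as.numeric(plus), minus = as.numeric(minus)),
    class = "txa_signal"
  )
}

#' @export
print.txa_signal <- function(x, ...) {
  cat(sprintf("<txa_signal> %s [%s/%s tex=%s rep%d] %s nt, %g reads in track\n",
              x$meta$library_id, x$meta$condition, x$meta$role,
              x$meta$tex_status, x$meta$replicate,
              format(length(x$plus), big.mark = ","),
              sum(x$plus) + sum(x$minus)))
  invisible(x)
}

#' Read a stranded per-position track from bedGraph
#'
#' Two dialects are supported. `"paired"` expects two files (plus- and
#' minus-strand values, both non-negative); `"signed"` expects one file in
#' which negative values carry the minus strand. bedGraph intervals are
#' 0-based half-open and are expanded to the package's 1-based per-position
#' vectors; unlisted positions are zero. Intervals running past the genome
#' end are clipped with a warning.
#'
#' @param path Plus-strand file (`"paired"`) or the single signed file.
#' @param meta A [library_meta()] row.
#' @param genome A `txa_genome` fixing the vector length.
#' @param minus_path Minus-strand file, required for the `"paired"` dialect.
#' @param dialect `"paired"` or `"signed"`.
#' @return A `txa_signal`.
#' @export
read_signal <- function(path, meta, genome, minus_path = NULL,
                        dialect = c("paired", "signed")) {
  dialect <- match.arg(dialect)
  if (dialect == "paired") {
    if (is.null(minus_path)) abort("paired dialect requires minus_path")
    plus <- bedgraph_to_vector(path, genome$length, allow_negative = FALSE)
    minus <- bedgraph_to_vector(minus_path, genome$length,
                                allow_negative = FALSE)
  } else {
    v <- bedgraph_to_vector(path, genome$length, allow_negative = TRUE)
    plus <- pmax(v, 0)
    minus <- pmax(-v, 0)
  }
  stranded_signal(meta, plus, minus)
}

bedgraph_to_vector <- function(path, genome_len, allow_negative = FALSE) {
  vec <- numeric(genome_len)
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0L) return(vec)
  df <- utils::read.table(path, header = FALSE, sep = "",
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "integer", "integer",
                                         "numeric"),
                          comment.char = "#")
  if (nrow(df) == 0L) return(vec)
  if (!allow_negative && any(df$value < 0)) {
    abort("negative values in unsigned bedGraph dialect")
  }
  # 0-based half-open -> 1-based inclusive
  start1 <- df$start + 1L
  end1 <- df$end
  over <- end1 > genome_len
  if (any(over)) {
    warn(sprintf("%d bedGraph intervals extend past genome end; clipped",
                 sum(over)))
    end1 <- pmin(end1, genome_len)
  }
  keep <- start1 <= end1 & start1 >= 1L
  for (i in which(keep)) {
    idx <- start1[i]:end1[i]
    prev <- vec[idx]
    hit <- prev != 0 & prev != df$value[i]
    if (any(hit)) {
      abort("overlapping bedGraph intervals with conflicting values")
    }
    vec[idx] <- df$value[i]
  }
  vec
}

vector_to_bedgraph <- function(vec, chrom, path, strand_sign = 1) {
  r <- rle(vec)
  ends <- cumsum(r$lengths)
  starts0 <- ends - r$lengths        # 0-based starts
  keep <- r$values != 0
  df <- data.frame(chrom = chrom, start = starts0[keep], end = ends[keep],
                   value = r$values[keep] * strand_sign)
  utils::write.table(df, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a stranded signal as a pair of bedGraph files
#'
#' Zero runs are omitted; a nonzero-position round trip through
#' [read_signal()] is lossless.
#'
#' @param signal A `txa_signal`.
#' @param genome A `txa_genome` (names the chromosome).
#' @param plus_path,minus_path Output paths.
#' @return Character vector of the two paths, invisibly.
#' @export
write_signal <- function(signal, genome, plus_path, minus_path) {
  vector_to_bedgraph(signal$plus, genome$seq_id, plus_path)
  vector_to_bedgraph(signal$minus, genome$seq_id, minus_path)
  invisible(c(plus_path, minus_path))
}

# Reads-per-million normalization against the library size recorded in the
# metadata (not the track sum).
signal_rpm <- function(signal) {
  f <- 1e6 / signal$meta$total_mapped_reads
  list(plus = signal$plus * f, minus = signal$minus * f)
}

rpm_factor <- function(signal) 1e6 / signal$meta$total_mapped_reads

strand_vec <- function(track, strand) if (strand == "+") track$plus else track$minus
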