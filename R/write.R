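#' Write merged/classified sites as TSV and BED6
#'
#' The TSV has fixed columns (`site_id`, `position`, `strand`,
#' `site_class`, `height_rpm`, `n_conditions`, `conditions`,
#' `condition_label`, `per_condition_height`, and `category`/`gene`/
#' `utr_len` when classified); list columns are collapsed as
#' comma-separated and `cond:height` strings. The BED6 `chromStart` is
#' `position - 1` (0-based), the score is the RPM height capped at 1000.
#' [read_sites()] restores records exactly.
#'
#' @param sites A [merge_sites()] / [classify_tss()] tibble.
#' @param tsv_path,bed_path Output paths (either may be `NULL` to skip).
#' @param chrom Chromosome name for the BED output.
#' @return Invisibly, the written paths.
#' @export
write_sites <- function(sites, tsv_path, bed_path = NULL, chrom = "chr") {
  flat <- as_tibble(sites)
  if ("conditions" %in% names(flat)) {
    flat$conditions <- vapply(flat$conditions, paste, "", collapse = ",")
  }
  if ("per_condition_height" %in% names(flat)) {
    flat$per_condition_height <- vapply(
      flat$per_condition_height,
      function(h) paste(sprintf("%s:%.10g", names(h), h), collapse = ","),
      "")
  }
  if (!is.null(tsv_path)) readr::write_tsv(flat, tsv_path)
  if (!is.null(bed_path)) {
    bed <- data.frame(
      chrom = chrom,
      start = sites$position - 1L,
      end = sites$position,
      name = sites$site_id,
      score = pmin(1000, round(sites$height_rpm)),
      strand = sites$strand
    )
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(c(tsv_path, bed_path))
}

#' Read a site TSV written by [write_sites()]
#'
#' @param tsv_path Path to the TSV.
#' @return The site tibble with list columns restored.
#' @export
read_sites <- function(tsv_path) {
  flat <- readr::read_tsv(tsv_path, show_col_types = FALSE,
                          progress = FALSE)
  if ("conditions" %in% names(flat)) {
    flat$conditions <- strsplit(as.character(flat$conditions), ",",
                                fixed = TRUE)
  }
  if ("per_condition_height" %in% names(flat)) {
    flat$per_condition_height <- lapply(
      strsplit(as.character(flat$per_condition_height), ",", fixed = TRUE),
      function(parts) {
        kv <- strsplit(parts, ":", fixed = TRUE)
        setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
                 vapply(kv, `[`, "", 1))
      })
  }
  flat$position <- as.integer(flat$position)
  flat
}

#' Write transcription units and clusters as GFF3 and TSV
#'
#' The GFF3 uses feature types `transcription_unit` and `TU_cluster`; the
#' TSVs collapse list columns comma-separated. [read_tus()] restores the TU
#' TSV exactly.
#'
#' @param tus [assemble_tus()] output.
#' @param clusters [cluster_tus()] output.
#' @param gff_path,tu_tsv_path,cluster_tsv_path Output paths (any may be
#'   `NULL`).
#' @param chrom Chromosome name for the GFF3.
#' @return Invisibly, the written paths.
#' @export
write_tus <- function(tus, clusters, gff_path = NULL, tu_tsv_path = NULL,
                      cluster_tsv_path = NULL, chrom = "chr") {
  if (!is.null(gff_path)) {
    lines <- c("##gff-version 3")
    for (k in seq_len(nrow(tus))) {
      lines <- c(lines, paste(
        chrom, "txarch", "transcription_unit", tus$start[k], tus$end[k],
        ".", tus$strand[k], ".",
        sprintf("ID=%s;tss=%s;tep=%s;genes=%s", tus$tu_id[k],
                tus$tss_ref[k], tus$tep_ref[k],
                paste(tus$genes[[k]], collapse = ",")),
        sep = "\t"))
    }
    for (k in seq_len(nrow(clusters))) {
      lines <- c(lines, paste(
        chrom, "txarch", "TU_cluster", clusters$start[k], clusters$end[k],
        ".", ifelse(clusters$strand[k] == "*", ".", clusters$strand[k]),
        ".",
        sprintf("ID=%s;members=%s", clusters$cluster_id[k],
                paste(clusters$members[[k]], collapse = ",")),
        sep = "\t"))
    }
    writeLines(lines, gff_path)
  }
  if (!is.null(tu_tsv_path)) {
    flat <- tus
    flat$genes <- vapply(flat$genes, paste, "", collapse = ",")
    readr::write_tsv(flat, tu_tsv_path)
  }
  if (!is.null(cluster_tsv_path)) {
    flat <- clusters
    flat$members <- vapply(flat$members, paste, "", collapse = ",")
    readr::write_tsv(flat, cluster_tsv_path)
  }
  invisible(c(gff_path, tu_tsv_path, cluster_tsv_path))
}

#' Read a TU TSV written by [write_tus()]
#'
#' @param tu_tsv_path Path to the TU TSV.
#' @return The TU tibble with the `genes` list column restored.
#' @export
read_tus <- function(tu_tsv_path) {
  flat <- readr::read_tsv(tu_tsv_path, show_col_types = FALSE,
                          progress = FALSE)
  flat$genes <- lapply(strsplit(
    ifelse(is.na(flat$genes), "", as.character(flat$genes)), ",",
    fixed = TRUE), function(g) g[nzchar(g)])
  flat$start <- as.integer(flat$start)
  flat$end <- as.integer(flat$end)
  flat$length <- as.integer(flat$length)
  flat
}
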