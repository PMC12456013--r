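BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param probs 4 x width numeric matrix of per-position base probabilities
#'   (rows A, C, G, T; each column sums to 1).
#' @param background Named base distribution of the null model.
#' @param pseudocount Pseudocount used when the PWM was estimated (recorded
#'   for provenance).
#' @return A `txa_pwm` object.
#' @export
pwm <- function(probs, background = c(A = .25, C = .25, G = .25, T = .25),
                pseudocount = 0) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) abort("probs must have 4 rows (A,C,G,T)")
  dimnames(probs) <- list(BASES, NULL)
  if (any(abs(colSums(probs) - 1) > 1e-9)) {
    abort("each PWM position must sum to 1")
  }
  background <- background[BASES]
  structure(list(probs = probs, width = ncol(probs),
                 background = background, pseudocount = pseudocount),
            class = "txa_pwm")
}

#' @export
print.txa_pwm <- function(x, ...) {
  cat(sprintf("<txa_pwm> width %d, consensus %s, IC %.2f bits\n",
              x$width, pwm_consensus(x), sum(information_content(x))))
  invisible(x)
}

#' Estimate a PWM from aligned sites
#'
#' Per-position probabilities are `(count + pseudocount) / (n + 4 *
#' pseudocount)`.
#'
#' @param aligned_sites Character vector of equal-length ACGT sequences.
#' @param pseudocount Pseudocount per base.
#' @param background Null base distribution attached to the PWM.
#' @return A `txa_pwm`.
#' @export
estimate_pwm <- function(aligned_sites, pseudocount = 0.5,
                         background = c(A = .25, C = .25, G = .25, T = .25)) {
  if (length(aligned_sites) < 1L) abort("need at least one site")
  w <- unique(nchar(aligned_sites))
  if (length(w) != 1L) abort("aligned sites must have equal lengths")
  mat <- count_matrix(aligned_sites, w)
  probs <- sweep(mat + pseudocount, 2,
                 length(aligned_sites) + 4 * pseudocount, "/")
  pwm(probs, background, pseudocount)
}

count_matrix <- function(sites, w) {
  m <- matrix(0L, nrow = 4, ncol = w, dimnames = list(BASES, NULL))
  enc <- encode_seqs(sites)
  for (j in seq_len(w)) {
    tj <- tabulate(vapply(enc, `[`, integer(1), j), nbins = 4)
    m[, j] <- tj
  }
  m
}

#' Build a PWM from an IUPAC consensus string
#'
#' Each position puts `match_total` probability mass on the bases the IUPAC
#' code allows (split evenly) and the remainder on the others — a convenient
#' way to express a consensus motif such as `TTGHHW` as a scorable model.
#'
#' @param consensus IUPAC consensus (ACGT plus ambiguity codes RYSWKMBDHVN).
#' @param match_total Probability mass on allowed bases per position.
#' @param background Null base distribution.
#' @return A `txa_pwm`.
#' @export
consensus_pwm <- function(consensus, match_total = 0.94,
                          background = c(A = .25, C = .25, G = .25, T = .25)) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = BASES)
  chars <- strsplit(toupper(consensus), "")[[1]]
  cols <- lapply(chars, function(ch) {
    allowed <- iupac[[ch]]
    if (is.null(allowed)) abort(sprintf("unknown IUPAC code '%s'", ch))
    if (length(allowed) == 4L) return(setNames(rep(0.25, 4), BASES))
    p <- setNames(rep((1 - match_total) / (4 - length(allowed)), 4), BASES)
    p[allowed] <- match_total / length(allowed)
    p
  })
  pwm(do.call(cbind, cols), background)
}

pwm_consensus <- function(x) {
  paste(BASES[apply(x$probs, 2, which.max)], collapse = "")
}

#' Per-position information content of a PWM
#'
#' @param x A `txa_pwm`.
#' @return Numeric vector, bits per position (relative to the PWM's
#'   background).
#' @export
information_content <- function(x) {
  lo <- log2(sweep(x$probs, 1, x$background, "/"))
  lo[x$probs == 0] <- 0
  colSums(x$probs * lo)
}

log_odds <- function(x) {
  lo <- log2(sweep(pmax(x$probs, 1e-12), 1, x$background, "/"))
  rownames(lo) <- BASES
  lo
}

encode_seqs <- function(seqs) {
  lapply(strsplit(toupper(seqs), ""), function(ch) {
    match(ch, BASES)
  })
}

# Log-odds score (bits) of every width-w placement in a sequence; windows
# containing non-ACGT characters score -Inf.
score_positions <- function(seq, x) {
  lo <- log_odds(x)
  code <- match(strsplit(toupper(seq), "")[[1]], BASES)
  n <- length(code)
  w <- x$width
  if (n < w) return(numeric(0))
  nak <- is.na(code)
  code[nak] <- 1L
  sc <- numeric(n - w + 1L)
  bad <- logical(n - w + 1L)
  for (j in seq_len(w)) {
    idx <- j:(n - w + j)
    sc <- sc + lo[cbind(code[idx], j)]
    bad <- bad | nak[idx]
  }
  sc[bad] <- -Inf
  sc
}

#' Exact PWM score distribution under the background model
#'
#' Discretizes per-position log-odds scores to integer units of
#' `1/resolution` bits and convolves position by position, giving the exact
#' null distribution of the discretized score of a background-random word —
#' the same construction FIMO uses for its p-values.
#'
#' @param x A `txa_pwm` (or a list of PWMs, whose score distributions are
#'   convolved — the null for a summed multi-block score).
#' @param resolution Integer score units per bit (>= 10).
#' @return A `txa_score_dist` list: `resolution`, `min_units`, `tail`
#'   (vector of `P(score >= t)` indexed from `min_units`).
#' @export
score_distribution <- function(x, resolution = 1e4) {
  if (resolution < 10) abort("resolution must be >= 10 bins")
  pwms <- if (inherits(x, "txa_pwm")) list(x) else x
  ilo_cols <- list()
  bgs <- list()
  for (p in pwms) {
    lo <- log_odds(p)
    for (j in seq_len(p$width)) {
      ilo_cols[[length(ilo_cols) + 1L]] <- as.integer(round(lo[, j] * resolution))
      bgs[[length(bgs) + 1L]] <- p$background
    }
  }
  mins <- vapply(ilo_cols, min, integer(1))
  maxs <- vapply(ilo_cols, max, integer(1))
  min_total <- sum(mins); max_total <- sum(maxs)
  span <- max_total - min_total + 1L
  probs <- numeric(span)
  probs[1] <- 1    # empty prefix at offset min_total... built incrementally
  cur_min <- 0L
  cur <- 1
  for (k in seq_along(ilo_cols)) {
    ilo <- ilo_cols[[k]]
    bg <- bgs[[k]]
    new_min <- cur_min + min(ilo)
    new_len <- (cur_min + length(cur) - 1L + max(ilo)) - new_min + 1L
    nxt <- numeric(new_len)
    for (b in 1:4) {
      off <- cur_min + ilo[b] - new_min
      idx <- (off + 1L):(off + length(cur))
      nxt[idx] <- nxt[idx] + bg[b] * cur
    }
    cur <- nxt
    cur_min <- new_min
  }
  tail <- rev(cumsum(rev(cur)))
  structure(list(resolution = resolution, min_units = cur_min, tail = tail,
                 n_cols = length(ilo_cols)),
            class = "txa_score_dist")
}

pvalue_from_distribution <- function(dist, score) {
  if (is.infinite(score) && score < 0) return(1)
  # per-column rounding can drift an integerized word total up to half a
  # unit per column below the float score; shift the query down by that
  # slack so the p-value is never underestimated at distribution atoms
  slack <- ceiling(dist$n_cols / 2)
  t <- round(score * dist$resolution) - slack
  idx <- t - dist$min_units + 1
  if (idx <= 1) return(1)
  if (idx > length(dist$tail)) return(0)
  dist$tail[idx]
}

#' Exact p-value of a PWM score
#'
#' Probability that a background-random word of the PWM's width attains at
#' least the given log-odds score, from the discretized exact distribution
#' of [score_distribution()]. Monotone non-increasing in `score`.
#'
#' @param x A `txa_pwm`.
#' @param score Log-odds score in bits.
#' @param resolution Integer score units per bit (>= 10).
#' @return A probability in `[0, 1]`.
#' @export
pwm_pvalue <- function(x, score, resolution = 1e4) {
  if (is.na(score)) abort("score must be finite or -Inf")
  dist <- score_distribution(x, resolution)
  pvalue_from_distribution(dist, score)
}

#' Write PWMs in minimal MEME motif format
#'
#' @param pwms Named list of `txa_pwm` objects (or a single PWM; bipartite
#'   models can be serialized via their `pwm_up`/`pwm_down` blocks).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "txa_pwm")) pwms <- list(motif = pwms)
  bg <- pwms[[1]]$background
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
             "Background letter frequencies",
             sprintf("A %.5f C %.5f G %.5f T %.5f",
                     bg["A"], bg["C"], bg["G"], bg["T"]), "")
  for (nm in names(pwms)) {
    p <- pwms[[nm]]
    lines <- c(lines, sprintf("MOTIF %s", nm),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       p$width),
               apply(p$probs, 2, function(col)
                 sprintf(" %.6f %.6f %.6f %.6f", col[1], col[2], col[3],
                         col[4])),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read PWMs from minimal MEME motif format
#'
#' @param path Path to a MEME-format motif file.
#' @return Named list of `txa_pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- c(A = .25, C = .25, G = .25, T = .25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, 8, by = 2)])
    bg <- setNames(vals, toks[seq(1, 7, by = 2)])[BASES]
  }
  starts <- grep("^MOTIF ", lines)
  out <- list()
  for (s in starts) {
    nm <- strsplit(lines[s], "\\s+")[[1]][2]
    hdr <- s + 1L
    w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    probs <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    out[[nm]] <- pwm(t(probs), bg)
  }
  out
}
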