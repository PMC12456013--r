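# shared builders and independent oracles for the test suite

# sparse stranded signal: counts given as position -> count maps
make_signal <- function(len, plus = numeric(0), minus = numeric(0),
                        id = "lib1", condition = "CO2",
                        role = "five_prime", tex = "plus", rep = 1L,
                        total = 1e6) {
  pv <- numeric(len); mv <- numeric(len)
  if (length(plus)) pv[as.integer(names(plus))] <- plus
  if (length(minus)) mv[as.integer(names(minus))] <- minus
  stranded_signal(
    library_meta(id, condition, role,
                 tex_status = if (role == "five_prime") tex else "na",
                 replicate = rep, total_mapped_reads = total),
    pv, mv)
}

flat_coverage <- function(len, rpm, id = "cov", condition = "CO2",
                          total = 1e6) {
  depth <- rpm * total / 1e6
  stranded_signal(
    library_meta(id, condition, "coverage", replicate = 1L,
                 total_mapped_reads = total),
    rep(depth, len), rep(depth, len))
}

make_sites <- function(position, strand, height = 10,
                       site_class = "TSS", condition = "CO2") {
  tibble::tibble(
    site_id = sprintf("%s_%s_%07d", site_class,
                      ifelse(strand == "+", "p", "m"), position),
    position = as.integer(position), strand = strand,
    site_class = site_class,
    height_rpm = rep_len(height, length(position)),
    n_conditions = 1L,
    conditions = replicate(length(position), condition, simplify = FALSE),
    condition_label = paste0("condition-specific:", condition),
    per_condition_height = lapply(rep_len(height, length(position)),
                                  function(h) setNames(h, condition))
  )
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

planted_seqs <- function(n = 50, len = 50, motif = "TATAAT", seed = 99) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      s <- random_dna(len)
      off <- sample(seq_len(len - nchar(motif) + 1L), 1)
      paste0(substr(s, 1, off - 1), motif,
             substr(s, off + nchar(motif), len))
    }, character(1))
  })
}

# probe points for checking a score distribution's tail function: midpoints
# of well-separated gaps between adjacent attained scores, where
# discretization cannot reorder words around the probe
score_probes <- function(all_scores, min_gap = 0.02, n_probes = 5) {
  v <- sort(unique(round(all_scores, 9)))
  gaps <- diff(v)
  ok <- which(gaps > min_gap)
  mid <- (v[ok] + v[ok + 1]) / 2
  mid[unique(pmax(1L, round(seq(1, length(mid),
                                length.out = n_probes))))]
}

# ---- independent oracles --------------------------------------------------

# brute-force site classifier: literal restatement of the category rules,
# evaluated gene by gene with no shared code with classify_sites()
oracle_classify <- function(sites, ann, params, site_class,
                            tss_annotated = NULL) {
  n <- nrow(sites)
  out <- character(n)
  utr <- rep(NA_integer_, n)
  assigned <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    pos <- sites$position[i]
    best_g <- NA_integer_; best_d <- Inf
    for (g in seq_len(nrow(ann))) {
      if (ann$strand[g] != sites$strand[i]) next
      sg <- if (ann$strand[g] == "+") 1L else -1L
      if (site_class == "TSS") {
        d <- (ann$five_prime[g] - pos) * sg    # upstream distance
        inside <- d >= -params$tss_downstream_nt & d <= params$tss_upstream_nt
        ad <- abs(ann$five_prime[g] - pos)
      } else {
        d <- (pos - ann$three_prime[g]) * sg   # downstream distance
        inside <- d >= 0 & d <= params$tep_downstream_nt
        ad <- abs(ann$three_prime[g] - pos)
      }
      if (inside && (ad < best_d ||
                     (ad == best_d && ann$start[g] < ann$start[best_g]))) {
        best_g <- g; best_d <- ad
      }
    }
    assigned[i] <- best_g
  }
  for (g in unique(assigned[!is.na(assigned)])) {
    members <- which(assigned == g)
    sg <- if (ann$strand[g] == "+") 1L else -1L
    anchor <- if (site_class == "TSS") ann$five_prime[g] else
      ann$three_prime[g]
    key5 <- sites$position[members] * sg * (if (site_class == "TSS") 1 else -1)
    ord <- order(-sites$height_rpm[members],
                 abs(anchor - sites$position[members]), key5)
    members <- members[ord]
    out[members[1]] <- "P"
    if (length(members) > 1) out[members[-1]] <- "S"
    d <- if (site_class == "TSS") (anchor - sites$position[members]) * sg
      else (sites$position[members] - anchor) * sg
    utr[members] <- pmax(0L, as.integer(d))
  }
  for (i in which(out == "")) {
    pos <- sites$position[i]
    if (site_class == "TEP" && !is.null(tss_annotated)) {
      done <- FALSE
      prim <- tss_annotated[tss_annotated$category %in% "P", , drop = FALSE]
      for (j in seq_len(nrow(prim))) {
        g <- match(prim$gene[j], ann$locus_tag)
        if (is.na(g) || ann$strand[g] != sites$strand[i]) next
        # inside the 5'-UTR: downstream of the primary TSS, upstream of the
        # gene start (no C call when the TSS lies inside the gene)
        between <- if (ann$strand[g] == "+") {
          pos > prim$position[j] && pos < ann$five_prime[g]
        } else {
          pos < prim$position[j] && pos > ann$five_prime[g]
        }
        if (between) { out[i] <- "C"; done <- TRUE; break }
      }
      if (done) next
    }
    sense_body <- any(ann$strand == sites$strand[i] &
                        ann$start <= pos & pos <= ann$end)
    anti_flank <- any(ann$strand != sites$strand[i] &
                        ann$start - params$antisense_flank_nt <= pos &
                        pos <= ann$end + params$antisense_flank_nt)
    out[i] <- if (sense_body) "I" else if (anti_flank) "A" else "N"
  }
  list(category = out, utr_len = utr)
}

# brute-force hairpin: enumerate every (stem start, stem length, loop
# length) with full complementary pairing and score it
oracle_hairpin <- function(window, stem_min, loop_range) {
  pair_sc <- function(a, b) {
    key <- paste0(a, b)
    if (key %in% c("GC", "CG")) 3
    else if (key %in% c("AT", "TA")) 2
    else if (key %in% c("GT", "TG")) 1
    else 0
  }
  s <- strsplit(window, "")[[1]]
  n <- length(s)
  best <- list(score = 0, stem_len = 0L, loop_len = 0L)
  for (stem in seq(1L, n %/% 2)) {
    for (l in seq(loop_range[1], loop_range[2])) {
      span <- 2L * stem + l
      if (span > n) next
      for (a in seq_len(n - span + 1L)) {
        sc <- 0; ok <- TRUE
        for (k in seq_len(stem)) {
          p <- pair_sc(s[a + stem - k], s[a + stem + l + k - 1L])
          if (p == 0) { ok <- FALSE; break }
          sc <- sc + p
        }
        if (ok && stem >= stem_min && sc > best$score) {
          best <- list(score = sc, stem_len = stem, loop_len = l)
        }
      }
    }
  }
  best
}

# brute-force connected components over >=1 nt same-strand span overlap
oracle_clusters <- function(tus) {
  n <- nrow(tus)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- tus$strand[i] == tus$strand[j] &&
      tus$start[i] <= tus$end[j] && tus$start[j] <= tus$end[i]
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        m <- min(comp[i], comp[j]); comp[i] <- m; comp[j] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(tus$tu_id, comp)
}

mirror_ann <- function(ann, L) {
  annotation_from_genes(tibble::tibble(
    locus_tag = ann$locus_tag, feature_type = ann$feature_type,
    strand = ifelse(ann$strand == "+", "-", "+"),
    start = L + 1L - ann$end, end = L + 1L - ann$start))
}

# random gene layout + sites for classification oracle tests
random_layout <- function(genome_len = 10000L, n_genes = 8L,
                          n_sites = 20L, site_class = "TSS") {
  starts <- sort(sample(seq(100L, genome_len - 600L), n_genes))
  len <- sample(150:400, n_genes, replace = TRUE)
  ann <- annotation_from_genes(tibble::tibble(
    locus_tag = sprintf("g%02d", seq_len(n_genes)),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    start = starts, end = pmin(starts + len, genome_len)))
  pos <- sample(seq_len(genome_len), n_sites)
  make_sites(pos, sample(c("+", "-"), n_sites, replace = TRUE),
             height = sample(5:100, n_sites, replace = TRUE),
             site_class = site_class)
}
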