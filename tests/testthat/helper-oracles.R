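# Independent oracles and small fixture builders used across tests.

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

rc_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Optimal local alignment score under the affine scheme, both strands,
# via Biostrings dynamic programming (independent of the package path).
oracle_best_local_score <- function(q, s, scoring = scoring_scheme()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  sc <- function(a, b) {
    Biostrings::pairwiseAlignment(a, b, type = "local",
                                  substitutionMatrix = mat,
                                  gapOpening = scoring$gap_open,
                                  gapExtension = scoring$gap_extend,
                                  scoreOnly = TRUE)
  }
  max(sc(q, s), sc(rc_chr(q), s))
}

# Exhaustive motif-run enumeration + merge, written against gregexpr.
oracle_scan_arrays <- function(seq, max_bridge = 6L) {
  runs <- list()
  for (m in c("TTAGGG", "CCCTAA")) {
    st <- if (m == "TTAGGG") "+" else "-"
    g <- gregexpr(m, seq, fixed = TRUE)[[1]]
    if (g[1] == -1) next
    pos <- as.integer(g) - 1L # 0-based
    # chain tandem occurrences at step 6
    i <- 1
    while (i <= length(pos)) {
      j <- i
      while (j < length(pos) && pos[j + 1] == pos[j] + 6L) j <- j + 1
      runs[[length(runs) + 1L]] <- list(start = pos[i], end = pos[j] + 6L,
                                        units = j - i + 1L, strand = st)
      i <- j + 1
    }
  }
  if (!length(runs)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), n_units = integer(),
                          interruptions = integer(), its_length = integer()))
  }
  runs <- runs[order(vapply(runs, `[[`, 0L, "start"))]
  merged <- list(c(runs[[1]], inter = 0L))
  for (r in runs[-1]) {
    p <- merged[[length(merged)]]
    gap <- r$start - p$end
    if (p$strand == r$strand && gap >= 0 && gap <= max_bridge) {
      p$end <- r$end; p$units <- p$units + r$units; p$inter <- p$inter + 1L
      merged[[length(merged)]] <- p
    } else {
      merged[[length(merged) + 1L]] <- c(r, inter = 0L)
    }
  }
  tibble::tibble(
    start = as.integer(vapply(merged, function(x) x$start, 0)),
    end = as.integer(vapply(merged, function(x) x$end, 0)),
    strand = vapply(merged, function(x) x$strand, ""),
    n_units = as.integer(vapply(merged, function(x) x$units, 0)),
    interruptions = as.integer(vapply(merged, function(x) x$inter, 0)),
    its_length = as.integer(vapply(merged, function(x) x$end - x$start, 0))
  )
}

# Brute-force in-frame register: try all 6 phases of the hexamer ring.
oracle_inframe <- function(terc_3p, its_first) {
  ring <- strrep("TTAGGG", 6)
  nl <- nchar(terc_3p)
  for (k in 3:1) {
    if (k > nl) next
    cand <- paste0(substr(terc_3p, nl - k + 1, nl),
                   substr(its_first, 1, min(6, nchar(its_first))))
    hitp <- FALSE
    for (p in 0:5) {
      w <- substr(ring, p + 1, p + nchar(cand))
      if (w == cand) hitp <- TRUE
    }
    if (hitp) return(k)
  }
  0L
}

# Brute-force suffix/prefix scan for microhomology.
oracle_microhomology <- function(ins, flank, max_len = 10L) {
  best <- 0L
  for (k in seq_len(min(max_len, nchar(ins), nchar(flank)))) {
    if (substr(ins, nchar(ins) - k + 1, nchar(ins)) == substr(flank, 1, k)) {
      best <- k
    }
  }
  best
}

# A pair of sequences sharing one planted homologous core. The first 15
# core bases stay mutation-free so an exact word seed always exists
# inside the shared region (the regime a word-11 seeded search covers).
make_homologous_pair <- function(core_len = 60L, n_mut = 2L,
                                 flank_a = 60L, flank_b = 60L) {
  core <- random_dna(core_len)
  mutate_k <- function(s, k) {
    if (k == 0 || nchar(s) <= 16) return(s)
    pos <- sample(16:nchar(s), min(k, nchar(s) - 15))
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  a <- paste0(random_dna(flank_a), mutate_k(core, n_mut), random_dna(flank_a))
  b <- paste0(random_dna(flank_b), mutate_k(core, n_mut), random_dna(flank_b))
  list(a = a, b = b)
}

# minimal hit row for attach/classify tests
fake_hit <- function(s_start, s_end, strand = "+", q_start = 100L,
                     q_end = NULL, score = 60L) {
  if (is.null(q_end)) q_end <- q_start + (s_end - s_start)
  tibble::tibble(
    query_id = "TERC", subject_id = "ctg",
    q_start = as.integer(q_start), q_end = as.integer(q_end),
    s_start = as.integer(s_start), s_end = as.integer(s_end),
    strand = strand, score = as.integer(score),
    length = as.integer(s_end - s_start),
    identities = as.integer(s_end - s_start), mismatches = 0L,
    gap_columns = 0L, aligned_query = "", aligned_subject = ""
  )
}
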