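#' blastn-style affine-gap scoring scheme
#'
#' The defaults reproduce the short-sequence blastn parameterisation used
#' for TERC-like searches: word size 11, match +2, mismatch -3, gap
#' existence 5, gap extension 2. A gap of length k costs
#' `gap_open + k * gap_extend`.
#'
#' @param match Positive match reward.
#' @param mismatch Negative mismatch score.
#' @param gap_open Non-negative gap-opening cost (charged once per gap).
#' @param gap_extend Gap-extension cost per gapped base (>= 1).
#' @param word_size Exact-match seed length (>= 4).
#' @return An object of class `tercits_scoring`.
#' @export
#' @examples
#' scoring_scheme()
scoring_scheme <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                           gap_extend = 2L, word_size = 11L) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 1,
            word_size >= 4)
  structure(
    list(match = as.integer(match), mismatch = as.integer(mismatch),
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         word_size = as.integer(word_size)),
    class = "tercits_scoring"
  )
}

#' @export
print.tercits_scoring <- function(x, ...) {
  cat(sprintf(
    "<scoring> match %+d / mismatch %+d, gap open %d + extend %d per base, word size %d\n",
    x$match, x$mismatch, x$gap_open, x$gap_extend, x$word_size))
  invisible(x)
}

#' Find exact word seeds between two sequences
#'
#' Reports every exact word match of length `word_size` on either strand.
#' A `-` strand seed means the subject matches the reverse complement of
#' the query; `qpos` is given on the original (forward) query. Words
#' containing `N` never seed.
#'
#' @param query,subject Nucleotide strings.
#' @param word_size Seed length; if longer than either sequence the
#'   result is empty.
#' @return Tibble with 0-based columns `qpos`, `spos` and `strand`.
#' @export
find_word_seeds <- function(query, subject, word_size = 11L) {
  as_tibble(cpp_find_seeds(query, subject, as.integer(word_size)))
}

#' Gapped x-drop extension of one seed
#'
#' Extends an exact word seed in both directions with affine-gap dynamic
#' programming, abandoning paths whose running score falls more than
#' `xdrop` below the best seen; the returned hit is trimmed to the
#' maximal-scoring extent. Deterministic for fixed inputs.
#'
#' @param query,subject Nucleotide strings.
#' @param qpos,spos 0-based seed start positions (`qpos` on the forward
#'   query, as returned by [find_word_seeds()]).
#' @param strand `"+"` or `"-"`.
#' @param scoring A [scoring_scheme()].
#' @param xdrop x-drop termination threshold.
#' @return One-row tibble describing the hit; `aligned_query` and
#'   `aligned_subject` are gapped strings in subject orientation (the
#'   query segment is reverse-complemented for `-` hits).
#' @export
extend_seed <- function(query, subject, qpos, spos, strand,
                        scoring = scoring_scheme(), xdrop = 30L) {
  h <- cpp_extend_seed(query, subject, as.integer(qpos), as.integer(spos),
                       strand, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend,
                       scoring$word_size, as.integer(xdrop))
  as_tibble(h)
}

#' Seed-and-extend search for TERC-like fragments
#'
#' Finds word seeds on both strands, extends each with [extend_seed()]
#' semantics, collapses subject-overlapping same-strand hits to the
#' highest-scoring representative (ties: leftmost subject start, then
#' `+` strand) and returns hits with `score >= min_score`, sorted by
#' subject coordinate.
#'
#' @param query One-row tibble (`id`, `seq`) or a single named/unnamed
#'   string: the TERC gene sequence.
#' @param subject Tibble of contigs (`id`, `seq`) or a character vector.
#' @param scoring A [scoring_scheme()].
#' @param min_score Minimum raw score of a reported hit.
#' @param xdrop x-drop threshold for the gapped extension.
#' @return Tibble of hits with columns `query_id`, `subject_id`,
#'   `q_start`, `q_end`, `s_start`, `s_end` (0-based half-open),
#'   `strand`, `score`, `length`, `identities`, `mismatches`,
#'   `gap_columns`, `aligned_query`, `aligned_subject`.
#' @export
search_terc_like <- function(query, subject, scoring = scoring_scheme(),
                             min_score = 30L, xdrop = 30L) {
  q <- as_record(query, "query")
  s <- as_records(subject, "subject")
  out <- purrr::map2_dfr(s$id, s$seq, function(sid, sseq) {
    df <- as_tibble(cpp_search(q$seq, sseq, scoring$match, scoring$mismatch,
                               scoring$gap_open, scoring$gap_extend,
                               scoring$word_size, as.integer(xdrop),
                               as.integer(min_score)))
    if (nrow(df)) dplyr::mutate(df, query_id = q$id, subject_id = sid) else df
  })
  if (!nrow(out)) {
    return(empty_hits())
  }
  dplyr::select(out, "query_id", "subject_id", dplyr::everything())
}

empty_hits <- function() {
  tibble(query_id = character(), subject_id = character(),
         q_start = integer(), q_end = integer(),
         s_start = integer(), s_end = integer(), strand = character(),
         score = integer(), length = integer(), identities = integer(),
         mismatches = integer(), gap_columns = integer(),
         aligned_query = character(), aligned_subject = character())
}

# normalise a query/subject argument to (id, seq)
as_record <- function(x, what) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop(what, " must be a single record")
    list(id = x$id, seq = x$seq)
  } else if (is.character(x) && length(x) == 1L) {
    list(id = names(x) %||% what, seq = unname(x))
  } else stop(what, " must be a one-row tibble or a single string")
}

as_records <- function(x, what) {
  if (is.data.frame(x)) {
    x[, c("id", "seq")]
  } else if (is.character(x)) {
    tibble(id = names(x) %||% paste0(what, seq_along(x)), seq = unname(x))
  } else stop(what, " must be a tibble or character vector")
}

#' Recompute an alignment score from its gapped strings
#'
#' Audit helper: walks the two gapped strings and applies the affine-gap
#' scheme (a gap of length k costs `gap_open + k * gap_extend`; `N`
#' never matches). Every hit emitted by [search_terc_like()] satisfies
#' `score == alignment_score(aligned_query, aligned_subject, scoring)`.
#'
#' @param aligned_query,aligned_subject Equal-length gapped strings.
#' @param scoring A [scoring_scheme()].
#' @return Integer score vector.
#' @export
alignment_score <- function(aligned_query, aligned_subject,
                            scoring = scoring_scheme()) {
  stopifnot(length(aligned_query) == length(aligned_subject))
  purrr::map2_int(aligned_query, aligned_subject, function(ga, gb) {
    a <- strsplit(ga, "")[[1]]
    b <- strsplit(gb, "")[[1]]
    stopifnot(length(a) == length(b))
    score <- 0L
    in_gap <- FALSE
    for (k in seq_along(a)) {
      if (a[k] == "-" || b[k] == "-") {
        score <- score - scoring$gap_extend - (if (!in_gap) scoring$gap_open else 0L)
        in_gap <- TRUE
      } else {
        in_gap <- FALSE
        score <- score +
          (if (a[k] == b[k] && a[k] != "N") scoring$match else scoring$mismatch)
      }
    }
    score
  })
}

#' Write hits as tabular blast-style TSV
#'
#' Emits the canonical 12 tabular columns with `score` in place of the
#' evalue/bitscore pair; the mapping is documented in the header line.
#' Coordinates are printed 1-based inclusive; minus-strand hits have
#' `sstart > send`, following the blast convention.
#'
#' @param hits Tibble from [search_terc_like()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  gapopen <- purrr::map2_int(hits$aligned_query, hits$aligned_subject,
                             function(a, b) {
    g <- grepl("-", strsplit(a, "")[[1]], fixed = TRUE) |
         grepl("-", strsplit(b, "")[[1]], fixed = TRUE)
    sum(diff(c(FALSE, g)) == 1L)
  })
  minus <- hits$strand == "-"
  out <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = round(100 * hits$identities / hits$length, 2),
    length = hits$length, mismatch = hits$mismatches, gapopen = gapopen,
    qstart = hits$q_start + 1L, qend = hits$q_end,
    sstart = ifelse(minus, hits$s_end, hits$s_start + 1L),
    send = ifelse(minus, hits$s_start + 1L, hits$s_end),
    score = hits$score
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# qseqid sseqid pident length mismatch gapopen qstart ",
                    "qend sstart send score (raw alignment score replaces ",
                    "evalue/bitscore)"), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
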