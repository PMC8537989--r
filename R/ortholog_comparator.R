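#' Locate the orthologous locus of a 1-kb window in another genome
#'
#' The two flanks of the focal window (default 500 bp each) are placed
#' independently in the ortholog genome with the seed-and-extend
#' aligner. A placement is accepted when both flanks land on the same
#' contig and strand, in order, within `max_span`, each with identity
#' `>= min_flank_identity` over `>= min_flank_aligned` aligned columns.
#' The status is `occupied` when the intervening ortholog sequence
#' itself contains a TERC-like hit adjacent to a telomeric array,
#' `empty` when it does not, and `not_found` when the flanks cannot be
#' placed.
#'
#' @param locus_window One-row tibble from [extract_window()] (the
#'   locus widened by `flank` on each side).
#' @param ortholog_genome Tibble of contigs (`id`, `seq`).
#' @param terc TERC record or string, used for the occupied check.
#' @param annotation A [terc_annotation()] (template masking for the
#'   occupied check).
#' @param scoring A [scoring_scheme()].
#' @param flank Flank length used when the window was built.
#' @param min_flank_identity Minimum per-flank identity fraction.
#' @param min_flank_aligned Minimum aligned columns per flank.
#' @param max_span Maximum ortholog span between flank start and end.
#' @param min_score,xdrop,adjacency_window,max_bridge Passed to the
#'   occupied check.
#' @return One-row tibble: `status`, `contig`, `strand`, `o_start`,
#'   `o_end` (0-based half-open span of the placed flanks),
#'   `flank_identity` (mean of the two flank identity fractions; `NA`
#'   when not found), `mid_start`, `mid_end` (the intervening ortholog
#'   interval).
#' @export
locate_ortholog <- function(locus_window, ortholog_genome, terc, annotation,
                            scoring = scoring_scheme(), flank = 500L,
                            min_flank_identity = 0.6,
                            min_flank_aligned = 200L, max_span = 20000L,
                            min_score = 30L, xdrop = 30L,
                            adjacency_window = 30L, max_bridge = 6L) {
  not_found <- tibble(status = "not_found", contig = NA_character_,
                      strand = NA_character_, o_start = NA_integer_,
                      o_end = NA_integer_, flank_identity = NA_real_,
                      mid_start = NA_integer_, mid_end = NA_integer_)
  wseq <- locus_window$seq
  wlen <- nchar(wseq)
  if (wlen < 2 * flank) return(not_found)
  f1 <- substr(wseq, 1L, flank)
  f2 <- substr(wseq, wlen - flank + 1L, wlen)
  # a flank placement needs a sizeable alignment; seed extension with a
  # generous x-drop tolerates divergence without splitting the flank
  flank_xdrop <- max(xdrop, 2L * scoring$gap_open + 20L)
  best_hit <- function(fl) {
    hits <- search_terc_like(fl, ortholog_genome, scoring,
                             min_score = min_score, xdrop = flank_xdrop)
    if (!nrow(hits)) return(NULL)
    hits[order(-hits$score, hits$subject_id, hits$s_start), ][1, ]
  }
  h1 <- best_hit(f1)
  h2 <- best_hit(f2)
  if (is.null(h1) || is.null(h2)) return(not_found)
  if (h1$subject_id != h2$subject_id || h1$strand != h2$strand) {
    return(not_found)
  }
  plus <- h1$strand == "+"
  in_order <- if (plus) h1$s_end <= h2$s_start else h2$s_end <= h1$s_start
  if (!in_order) return(not_found)
  o_start <- min(h1$s_start, h2$s_start)
  o_end <- max(h1$s_end, h2$s_end)
  if (o_end - o_start > max_span) return(not_found)
  id1 <- h1$identities / h1$length
  id2 <- h2$identities / h2$length
  if (h1$length < min_flank_aligned || h2$length < min_flank_aligned ||
      id1 < min_flank_identity || id2 < min_flank_identity) {
    return(not_found)
  }
  mid_start <- if (plus) h1$s_end else h2$s_end
  mid_end <- if (plus) h2$s_start else h1$s_start
  oseq <- contig_seq(ortholog_genome, h1$subject_id)
  mid <- substr(oseq, mid_start + 1L, mid_end)
  occupied <- FALSE
  if (nchar(mid) >= scoring$word_size) {
    if (!plus) mid <- revcomp(mid)
    mhits <- search_terc_like(terc, mid, scoring, min_score = min_score,
                              xdrop = xdrop)
    if (nrow(mhits)) {
      marr <- scan_telomere_arrays(mid, max_bridge = max_bridge)
      cand <- attach_its(mhits, marr, mid,
                         adjacency_window = adjacency_window,
                         template_interval = annotation$template)
      occupied <- nrow(cand) > 0L
    }
  }
  tibble(status = if (occupied) "occupied" else "empty",
         contig = h1$subject_id, strand = h1$strand,
         o_start = o_start, o_end = o_end,
         flank_identity = mean(c(id1, id2)),
         mid_start = mid_start, mid_end = mid_end)
}

#' Type the break-site modifications at an insertion junction
#'
#' Compares the focal locus window with its empty ortholog window. The
#' focal left flank is aligned to the ortholog anchored at the shared
#' left window edge (score ties pushed maximally toward the junction)
#' and the right flank anchored at the right edge (ties pushed
#' minimally), both with affine-gap extension. The unaligned ortholog
#' segment between the two placements is the deletion; focal junction
#' bases outside the inserted core and outside both flank alignments
#' are the random insertion. Junction bases that continue the telomeric
#' repeat register contiguously from the core edge are attributed to
#' the ITS, not to the random insertion.
#'
#' @param locus_window One-row tibble from [extract_window()] around the
#'   focal locus.
#' @param empty_ortholog_window Ortholog window sequence (string or
#'   one-row tibble), oriented to match the focal window.
#' @param core_start,core_end 0-based half-open interval of the inserted
#'   core (TERC-like fragment + ITS) inside the focal window.
#' @param scoring A [scoring_scheme()].
#' @param flank Flank length of the window.
#' @param max_microhomology Maximum microhomology length searched.
#' @return One-row tibble: `deletion_len`, `insertion_len`, `category`
#'   (`none`, `deletion`, `insertion`, `deletion_and_insertion`),
#'   `microhomology_len`, `microhomology_seq`, `inserted_start`,
#'   `inserted_end` (full junction span on the focal window, 0-based
#'   half-open), `flank_left_end`, `flank_right_start` (focal), `o_left_end`,
#'   `o_right_start` (ortholog).
#' @export
type_modifications <- function(locus_window, empty_ortholog_window,
                               core_start, core_end,
                               scoring = scoring_scheme(), flank = 500L,
                               max_microhomology = 10L) {
  fseq <- if (is.data.frame(locus_window)) locus_window$seq else locus_window
  oseq <- if (is.data.frame(empty_ortholog_window)) empty_ortholog_window$seq
          else empty_ortholog_window
  flen <- nchar(fseq)
  olen <- nchar(oseq)
  stopifnot(flen >= 2 * flank, core_start >= flank, core_end <= flen - flank)
  big_drop <- 10000L
  f1 <- substr(fseq, 1L, flank)
  L <- cpp_anchored_extend(f1, oseq, scoring$match, scoring$mismatch,
                           scoring$gap_open, scoring$gap_extend,
                           big_drop, 1L)
  f2 <- substr(fseq, flen - flank + 1L, flen)
  Rv <- cpp_anchored_extend(str_rev(f2), str_rev(oseq), scoring$match,
                            scoring$mismatch, scoring$gap_open,
                            scoring$gap_extend, big_drop, 0L)
  fL <- L$a_len                      # focal left-flank alignment end
  oL <- L$b_len
  fR <- flen - Rv$a_len              # focal right-flank alignment start
  oR <- olen - Rv$b_len
  deletion_len <- max(0L, oR - oL)
  # focal junction bases outside the core and outside both alignments
  jl <- max(fL, 0L); jr <- min(fR, flen)
  extra_left <- max(0L, core_start - jl)
  extra_right <- max(0L, jr - core_end)
  # register continuation: junction bases that extend the telomeric
  # repeat phase contiguously from the core edge belong to the ITS
  extra_left <- extra_left - register_run_left(fseq, core_start, extra_left)
  extra_right <- extra_right - register_run_right(fseq, core_end, extra_right)
  insertion_len <- max(0L, extra_left) + max(0L, extra_right)
  category <- if (deletion_len == 0L && insertion_len == 0L) "none"
    else if (deletion_len > 0L && insertion_len == 0L) "deletion"
    else if (deletion_len == 0L && insertion_len > 0L) "insertion"
    else "deletion_and_insertion"
  inserted_seq <- substr(fseq, jl + 1L, jr)
  break_right <- substr(fseq, jr + 1L, flen)
  mh <- microhomology(inserted_seq, break_right, max_len = max_microhomology)
  tibble(deletion_len = deletion_len, insertion_len = insertion_len,
         category = category,
         microhomology_len = mh$length, microhomology_seq = mh$seq,
         inserted_start = jl, inserted_end = jr,
         flank_left_end = fL, flank_right_start = fR,
         o_left_end = oL, o_right_start = oR)
}

str_rev <- function(x) {
  paste(rev(strsplit(x, "")[[1]]), collapse = "")
}

# bases immediately right of `pos` (0-based) continuing the hexamer ring
# phase read from the 6 bases ending at pos; at most `limit` bases
register_run_right <- function(seq, pos, limit) {
  if (limit <= 0L || pos < 6L) return(0L)
  tail6 <- substr(seq, pos - 5L, pos)
  ring <- if (grepl(tail6, "TTAGGGTTAGGG", fixed = TRUE)) "TTAGGG"
          else if (grepl(tail6, "CCCTAACCCTAA", fixed = TRUE)) "CCCTAA"
          else return(0L)
  big <- strrep(ring, 6)
  run <- 0L
  while (run < limit) {
    cand <- paste0(tail6, substr(seq, pos + 1L, pos + run + 1L))
    if (!grepl(cand, big, fixed = TRUE)) break
    run <- run + 1L
  }
  run
}

register_run_left <- function(seq, pos, limit) {
  if (limit <= 0L) return(0L)
  head6 <- substr(seq, pos + 1L, pos + 6L)
  if (nchar(head6) < 6L) return(0L)
  ring <- if (grepl(head6, "TTAGGGTTAGGG", fixed = TRUE)) "TTAGGG"
          else if (grepl(head6, "CCCTAACCCTAA", fixed = TRUE)) "CCCTAA"
          else return(0L)
  big <- strrep(ring, 6)
  run <- 0L
  while (run < limit && pos - run - 1L >= 0L) {
    cand <- paste0(substr(seq, pos - run, pos + 6L))
    if (!grepl(cand, big, fixed = TRUE)) break
    run <- run + 1L
  }
  run
}

#' Microhomology between an inserted sequence and the break site
#'
#' The longest `k <= max_len` such that the last `k` bases of the
#' inserted sequence equal the first `k` bases of the right break-site
#' flank (`k = 0` allowed). Both arguments are given in focal-genome
#' orientation.
#'
#' @param inserted_seq Inserted sequence.
#' @param break_right_flank Sequence 3' of the insertion point.
#' @param max_len Maximum length searched.
#' @return List with `length` and `seq`.
#' @export
#' @examples
#' microhomology("CCTTAG", "TAGCAAT") # length 3, "TAG"
microhomology <- function(inserted_seq, break_right_flank, max_len = 10L) {
  ni <- nchar(inserted_seq)
  nf <- nchar(break_right_flank)
  for (k in rev(seq_len(min(max_len, ni, nf)))) {
    suf <- substr(inserted_seq, ni - k + 1L, ni)
    pre <- substr(break_right_flank, 1L, k)
    if (suf == pre) return(list(length = k, seq = suf))
  }
  list(length = 0L, seq = "")
}
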