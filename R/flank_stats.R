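#' GC content of a nucleotide sequence
#'
#' `100 * (G + C) / (A + C + G + T)`; `N` is excluded from the
#' denominator. Vectorised.
#'
#' @param seq Character vector of sequences.
#' @return Numeric percentage(s) in `[0, 100]`.
#' @export
#' @examples
#' gc_content("ACGTN") # 50
gc_content <- function(seq) {
  gc <- stringr::str_count(seq, "[GC]")
  at <- stringr::str_count(seq, "[AT]")
  if (any(gc + at == 0)) {
    stop("GC content undefined: sequence has no non-N bases")
  }
  100 * gc / (gc + at)
}

#' Repeat-annotation context of the regions flanking a locus
#'
#' Computes the fraction of the 2-kb windows upstream and downstream of
#' a locus (the locus itself excluded, windows clamped at contig ends)
#' covered by annotated mobile elements, overall and per class.
#' Overlapping annotations of different classes count once toward the
#' overall fraction (union) but separately per class. Distances are
#' edge-to-edge gap distances (0 when abutting, -1 when the contig has
#' no annotation).
#'
#' @param annotations Tibble with columns `contig`, `start`, `end`
#'   (0-based half-open) and `class` (`DNA`, `LINE`, `SINE`, `LTR`).
#' @param contig Contig of the locus.
#' @param start,end 0-based half-open locus interval.
#' @param flank Flank window size in bp.
#' @param contig_length Optional contig length for right clamping.
#' @return One-row tibble: `gc_windows` is not included (see
#'   [gc_content()]); columns `repeat_fraction`, `frac_DNA`,
#'   `frac_LINE`, `frac_SINE`, `frac_LTR`, `nearest_distance`,
#'   `inside_element`, `inside_class`, `window_bp`.
#' @export
repeat_context <- function(annotations, contig, start, end, flank = 2000L,
                           contig_length = NULL) {
  ann <- annotations[annotations$contig == contig, , drop = FALSE]
  up <- c(max(0L, start - flank), start)
  dn_hi <- if (is.null(contig_length)) end + flank
           else min(contig_length, end + flank)
  dn <- c(end, dn_hi)
  windows <- list(up, dn)
  win_bp <- sum(vapply(windows, function(w) max(0, w[2] - w[1]), numeric(1)))
  clip_len <- function(iv_start, iv_end) {
    sum(vapply(windows, function(w) {
      tot <- 0L
      lo <- pmax(iv_start, w[1]); hi <- pmin(iv_end, w[2])
      sum(pmax(0L, hi - lo))
    }, numeric(1)))
  }
  cover <- function(rows) {
    if (!nrow(rows)) return(0)
    ir <- IRanges::reduce(IRanges::IRanges(rows$start + 1L, rows$end))
    clip_len(BiocGenerics::start(ir) - 1L, BiocGenerics::end(ir))
  }
  classes <- c("DNA", "LINE", "SINE", "LTR")
  per_class <- vapply(classes, function(cl) {
    cover(ann[ann$class == cl, , drop = FALSE])
  }, numeric(1))
  total <- cover(ann)
  nearest <- if (!nrow(ann)) -1L else {
    gaps <- ifelse(ann$end <= start, start - ann$end,
                   ifelse(ann$start >= end, ann$start - end, 0L))
    as.integer(min(gaps))
  }
  inside <- which(ann$start < start & ann$end > end)
  tibble(
    repeat_fraction = if (win_bp > 0) total / win_bp else 0,
    frac_DNA = if (win_bp > 0) per_class[["DNA"]] / win_bp else 0,
    frac_LINE = if (win_bp > 0) per_class[["LINE"]] / win_bp else 0,
    frac_SINE = if (win_bp > 0) per_class[["SINE"]] / win_bp else 0,
    frac_LTR = if (win_bp > 0) per_class[["LTR"]] / win_bp else 0,
    nearest_distance = nearest,
    inside_element = length(inside) > 0L,
    inside_class = if (length(inside)) ann$class[inside[1]] else NA_character_,
    window_bp = win_bp
  )
}
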