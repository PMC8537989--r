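#' Scan a sequence for telomeric hexamer arrays
#'
#' Finds maximal runs of exact tandem `TTAGGG` (strand `+`) or `CCCTAA`
#' (strand `-`) hexamers. Same-strand runs separated by at most
#' `max_bridge` non-motif bases are merged into one array, counting one
#' interruption per merge; opposite-strand runs never merge. `its_length`
#' is the full merged interval length in bp, so bridged arrays have
#' lengths that are not multiples of 6.
#'
#' @param seq Nucleotide string.
#' @param max_bridge Maximum number of non-motif bases bridged inside an
#'   array.
#' @return Tibble sorted by `start` with 0-based half-open columns
#'   `start`, `end` plus `strand`, `n_units`, `interruptions`,
#'   `its_length`.
#' @export
#' @examples
#' scan_telomere_arrays("AATTAGGGTTAGGGAA")
scan_telomere_arrays <- function(seq, max_bridge = 6L) {
  as_tibble(cpp_scan_arrays(seq, as.integer(max_bridge)))
}

#' Pair TERC-like hits with adjacent telomeric arrays
#'
#' Each hit is paired with every array whose nearest edge lies within
#' `adjacency_window` bases of the hit (on either side); a hit with no
#' array in range produces no candidate locus. Hits whose query interval
#' lies fully inside the annotated telomeric-repeat template of TERC are
#' excluded: they are the template matching genomic telomeric repeats,
#' not evidence of a retrotranscribed TERC fragment. Likewise, an array
#' fully contained inside a hit's subject interval (the template region
#' of a TERC pseudogene) is not flanking evidence and never pairs.
#'
#' @param hits Tibble from [search_terc_like()], one contig.
#' @param arrays Tibble from [scan_telomere_arrays()] on the same contig
#'   coordinate system.
#' @param seq The contig sequence (used to record junction bases).
#' @param adjacency_window Maximum hit-to-array gap in bp.
#' @param template_interval Optional 0-based half-open interval of the
#'   repeat template on the TERC query.
#' @return Tibble of candidate loci: the hit columns plus a list-column
#'   `arrays` (the attached array rows, sorted by start), `gap_to_its`
#'   (bp between the hit and the nearest attached array) and
#'   `junction_bases` (the intervening sequence).
#' @export
attach_its <- function(hits, arrays, seq, adjacency_window = 30L,
                       template_interval = NULL) {
  if (!nrow(hits)) return(empty_candidates())
  if (!is.null(template_interval)) {
    keep <- !(hits$q_start >= template_interval[1] &
              hits$q_end <= template_interval[2])
    hits <- hits[keep, , drop = FALSE]
  }
  if (!nrow(hits) || !nrow(arrays)) return(empty_candidates())
  rows <- purrr::map_dfr(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    gap <- dplyr::case_when(
      arrays$end <= h$s_start ~ h$s_start - arrays$end,
      arrays$start >= h$s_end ~ arrays$start - h$s_end,
      TRUE ~ 0L
    )
    contained <- arrays$start >= h$s_start & arrays$end <= h$s_end
    sel <- gap <= adjacency_window & !contained
    if (!any(sel)) return(NULL)
    att <- arrays[sel, , drop = FALSE]
    att <- att[order(att$start), , drop = FALSE]
    g <- min(gap[sel])
    nearest <- which(sel)[which.min(gap[sel])]
    jb <- junction_between(seq, h$s_start, h$s_end,
                           arrays$start[nearest], arrays$end[nearest])
    dplyr::mutate(h, arrays = list(att), gap_to_its = g, junction_bases = jb)
  })
  if (is.null(rows) || !nrow(rows)) empty_candidates() else rows
}

junction_between <- function(seq, hs, he, as_, ae) {
  if (ae <= hs) substr(seq, ae + 1L, hs) # array left of hit
  else if (as_ >= he) substr(seq, he + 1L, as_)
  else ""
}

empty_candidates <- function() {
  dplyr::mutate(empty_hits(), arrays = list(), gap_to_its = integer(),
                junction_bases = character())
}

#' Export telomeric arrays as BED6
#'
#' The name field is `n_units:interruptions`, the score is `its_length`
#' and the strand column carries the array orientation.
#'
#' @param arrays Tibble from [scan_telomere_arrays()].
#' @param contig Contig name for column 1.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arrays_bed <- function(arrays, contig, path) {
  bed <- data.frame(
    chrom = contig, start = arrays$start, end = arrays$end,
    name = paste0(arrays$n_units, ":", arrays$interruptions),
    score = arrays$its_length, strand = arrays$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
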