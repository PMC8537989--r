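#' Read a FASTA file into a tibble of sequence records
#'
#' Sequences are uppercased and any character outside the `{A,C,G,T,N}`
#' alphabet is converted to `N` (a message reports how many). Record ids
#' are the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `seq`, one row per record, in
#'   file order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgt"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("FASTA record with empty sequence: ",
         paste(ids[empty], collapse = ", "))
  }
  cleaned <- gsub("[^ACGTN]", "N", seqs)
  n_conv <- sum(nchar(seqs)) - sum(stringr::str_count(seqs, "[ACGTN]"))
  if (n_conv > 0) {
    message(n_conv, " non-ACGTN character(s) converted to N in ", path)
  }
  tibble(id = unname(ids), seq = unname(cleaned))
}

#' Write sequence records to a FASTA file
#'
#' @param records Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  set <- Biostrings::BStringSet(stats::setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse-complement nucleotide sequences
#'
#' Vectorised; `N` maps to `N`. Characters outside `{A,C,G,T,N}` are an
#' error.
#'
#' @param seq Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("TTAGGG") # "CCCTAA"
revcomp <- function(seq) {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  unname(out)
}

#' Extract a genomic window around an interval
#'
#' Widens the 0-based half-open interval `[start, end)` by `flank` bases
#' on each side, clamped at the contig boundaries; clamping is recorded
#' in the returned columns.
#'
#' @param genome Tibble of contigs with columns `id` and `seq`.
#' @param contig Contig id.
#' @param start,end 0-based half-open interval on the contig.
#' @param flank Number of bases to add on each side.
#' @return One-row tibble with columns `id`, `seq`, `contig`, `start`,
#'   `end` (the realised window, 0-based half-open), `clamped_left`,
#'   `clamped_right`.
#' @export
extract_window <- function(genome, contig, start, end, flank = 0L) {
  i <- match(contig, genome$id)
  if (is.na(i)) stop("unknown contig: ", contig)
  len <- nchar(genome$seq[i])
  if (start < 0 || end > len || end <= start) {
    stop("interval [", start, ",", end, ") does not resolve on contig ",
         contig, " (length ", len, ")")
  }
  ws <- max(0L, start - flank)
  we <- min(len, end + flank)
  cl <- ws > start - flank
  cr <- we < end + flank
  tibble(
    id = paste0(contig, ":", ws + 1L, "-", we),
    seq = substr(genome$seq[i], ws + 1L, we),
    contig = contig, start = ws, end = we,
    clamped_left = cl, clamped_right = cr
  )
}

# internal: fetch one contig sequence
contig_seq <- function(genome, contig) {
  i <- match(contig, genome$id)
  if (is.na(i)) stop("unknown contig: ", contig)
  genome$seq[i]
}

#' Convert between 0-based half-open and 1-based inclusive coordinates
#'
#' Internal coordinates are 0-based half-open (BED convention); reports
#' print 1-based inclusive positions. These helpers perform the
#' round-trippable conversion.
#'
#' @param start,end Interval in the source convention.
#' @return A two-column tibble `start`, `end` in the target convention.
#' @export
to_report_coords <- function(start, end) {
  tibble(start = start + 1L, end = end)
}

#' @rdname to_report_coords
#' @export
to_internal_coords <- function(start, end) {
  tibble(start = start - 1L, end = end)
}
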