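#' TERC domain annotation
#'
#' Describes the layout of a telomerase RNA: total length, the
#' telomeric-repeat template (CR1) interval, and named structural
#' domains. All intervals are 0-based half-open on the TERC sequence.
#' Domain order is preserved and breaks ties in [map_to_terc()].
#'
#' @param terc_length TERC length in nt.
#' @param template 0-based half-open interval `c(start, end)` of the
#'   repeat template.
#' @param domains Named list of 0-based half-open intervals; typical
#'   names are `pseudoknot`, `J2a/3`, `CR4/CR5`, `scaRNA`.
#' @return An object of class `terc_annotation`.
#' @export
terc_annotation <- function(terc_length, template, domains = list()) {
  stopifnot(terc_length > 0, length(template) == 2,
            template[1] >= 0, template[2] <= terc_length,
            template[2] > template[1])
  for (d in domains) {
    stopifnot(length(d) == 2, d[1] >= 0, d[2] <= terc_length, d[2] > d[1])
  }
  structure(list(terc_length = as.integer(terc_length),
                 template = as.integer(template),
                 domains = lapply(domains, as.integer)),
            class = "terc_annotation")
}

#' @export
print.terc_annotation <- function(x, ...) {
  cat(sprintf("<terc_annotation> %d nt, template %d-%d (1-based)\n",
              x$terc_length, x$template[1] + 1L, x$template[2]))
  for (nm in names(x$domains)) {
    d <- x$domains[[nm]]
    cat(sprintf("  %-12s %d-%d\n", nm, d[1] + 1L, d[2]))
  }
  invisible(x)
}

#' Read a TERC domain annotation from a key=value config file
#'
#' The file holds one `key = value` pair per line; `terc_length` is an
#' integer, every other key is an interval written `a-b` in 1-based
#' inclusive coordinates (converted on ingest). The key `template` is
#' the repeat template; remaining keys become named domains in file
#' order. Lines starting with `#` are ignored. Two editable layouts,
#' `terc_human_like.cfg` and `terc_mouse_like.cfg`, ship with the
#' package (see [terc_annotation_default()]); coordinates for real
#' species should be supplied by the user.
#'
#' @param path Config file path.
#' @return A [terc_annotation()].
#' @export
read_terc_annotation <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  if (!"terc_length" %in% keys) stop("config lacks terc_length")
  if (!"template" %in% keys) stop("config lacks template interval")
  tl <- as.integer(vals[keys == "terc_length"][1])
  parse_iv <- function(v) {
    ab <- as.integer(strsplit(v, "-")[[1]])
    c(ab[1] - 1L, ab[2]) # 1-based inclusive -> 0-based half-open
  }
  template <- parse_iv(vals[keys == "template"][1])
  rest <- keys != "terc_length" & keys != "template"
  domains <- stats::setNames(lapply(vals[rest], parse_iv), keys[rest])
  terc_annotation(tl, template, domains)
}

#' Packaged synthetic TERC layouts
#'
#' Returns one of two editable, approximate domain layouts shipped with
#' the package: a 451-nt human-like TERC (long 5' pseudoknot domain) or
#' a 397-nt mouse-like TERC (truncated 5' end, 3' scaRNA domain). They
#' emulate the broad domain architecture of vertebrate telomerase RNAs
#' for simulation and testing; real species coordinates must come from
#' a curated source.
#'
#' @param layout `"human"` or `"mouse"`.
#' @return A [terc_annotation()].
#' @export
terc_annotation_default <- function(layout = c("human", "mouse")) {
  layout <- match.arg(layout)
  f <- system.file("extdata",
                   paste0("terc_", layout, "_like.cfg"),
                   package = "tercits", mustWork = TRUE)
  read_terc_annotation(f)
}

#' Map hits onto TERC coordinates and domains
#'
#' Adds the 1-based inclusive query interval (`terc_from`, `terc_to`,
#' printed like "8-32" in reports) and the label of the named domain
#' with maximal overlap (`domain_label`; ties go to the domain listed
#' first in the annotation, no overlap gives `"other"`).
#'
#' @param hits Tibble with `q_start`/`q_end` columns (0-based half-open
#'   on TERC).
#' @param annotation A [terc_annotation()].
#' @return `hits` with `terc_from`, `terc_to`, `domain_label` added.
#' @export
map_to_terc <- function(hits, annotation) {
  stopifnot(inherits(annotation, "terc_annotation"))
  if (nrow(hits)) {
    bad <- hits$q_start < 0 | hits$q_end > annotation$terc_length
    if (any(bad)) {
      stop("hit query interval outside [0, ", annotation$terc_length,
           ") on TERC")
    }
  }
  lab <- vapply(seq_len(nrow(hits)), function(i) {
    ov <- vapply(annotation$domains, function(d) {
      max(0L, min(hits$q_end[i], d[2]) - max(hits$q_start[i], d[1]))
    }, integer(1))
    if (!length(ov) || max(ov) == 0L) "other" else names(ov)[which.max(ov)]
  }, character(1))
  dplyr::mutate(hits, terc_from = .data$q_start + 1L, terc_to = .data$q_end,
                domain_label = lab)
}

#' In-frame 3' extension of a TERC-like fragment
#'
#' The largest `k <= 3` such that the last `k` bases of the TERC-like
#' fragment, concatenated with the start of the ITS, form a contiguous
#' substring of the infinite repeat `(TTAGGG)^n` in a single phase. Both
#' arguments are given in the orientation in which the ITS reads
#' `TTAGGG`.
#'
#' @param terc_like_3prime The trailing bases of the TERC-like fragment
#'   (at least the last 3 when available).
#' @param its_first_bases The first bases of the adjacent ITS.
#' @return Integer in `[0, 3]`.
#' @export
#' @examples
#' inframe_extension("GTT", "AGGGTT") # 3
#' inframe_extension("CCC", "TTAGGG") # 0
inframe_extension <- function(terc_like_3prime, its_first_bases) {
  ring_register_left(terc_like_3prime, its_first_bases, ring = "TTAGGG")
}

# largest k <= 3 with suffix_k(left) + prefix_6(right) inside the ring;
# ring = NULL infers TTAGGG vs CCCTAA from the right side
ring_register_left <- function(left, right, ring = NULL) {
  if (!nzchar(right)) return(0L)
  if (is.null(ring)) {
    head6 <- substr(right, 1, 6)
    ring <- if (startsWith("TTAGGGTTAGGG", head6) ||
                grepl(head6, "TTAGGGTTAGGG", fixed = TRUE)) "TTAGGG"
            else if (grepl(head6, "CCCTAACCCTAA", fixed = TRUE)) "CCCTAA"
            else return(0L)
  }
  big <- strrep(ring, 4)
  r <- substr(right, 1, 6)
  nl <- nchar(left)
  for (k in 3:1) {
    if (k > nl) next
    cand <- paste0(substr(left, nl - k + 1, nl), r)
    if (grepl(cand, big, fixed = TRUE)) return(k)
  }
  0L
}

# largest k <= 3 with suffix_6(left) + prefix_k(right) inside the ring
ring_register_right <- function(left, right, ring = NULL) {
  if (!nzchar(left)) return(0L)
  nl <- nchar(left)
  l <- substr(left, max(1, nl - 5), nl)
  if (is.null(ring)) {
    ring <- if (grepl(l, "TTAGGGTTAGGG", fixed = TRUE)) "TTAGGG"
            else if (grepl(l, "CCCTAACCCTAA", fixed = TRUE)) "CCCTAA"
            else return(0L)
  }
  big <- strrep(ring, 4)
  for (k in rev(seq_len(min(3L, nchar(right))))) {
    cand <- paste0(l, substr(right, 1, k))
    if (grepl(cand, big, fixed = TRUE)) return(k)
  }
  0L
}

#' Classify the structural organization of candidate loci
#'
#' Each locus is first put in canonical orientation: the strand of the
#' longest attached array (ties: leftmost) defines the direction in
#' which the ITS reads `TTAGGG`; for head-to-head array pairs the locus
#' is oriented so the TERC-like fragment lies 5' of the arrays. The
#' organization is then:
#'
#' * `A` - fragment 5' of the array, opposite orientation (hit strand
#'   `-`): repeats read off the template, fragment complementary to
#'   TERC;
#' * `B` - fragment 3' of the array, same orientation (hit strand `+`);
#' * `C` - fragment 5' of the array, same orientation, with two
#'   head-to-head repeat stretches (`CCCTAA` then `TTAGGG`).
#'
#' Any other configuration is assigned the nearest class and flagged
#' `nonstandard`. Head-to-head arrays with an opposite-orientation
#' fragment stay class `A` with `head_to_head = TRUE`. The in-frame 3'
#' extension is measured at the fragment/array boundary on the
#' canonical strand.
#'
#' @param candidates Tibble from [attach_its()] (one contig).
#' @param seq The contig sequence.
#' @return `candidates` with columns `organization`, `head_to_head`,
#'   `nonstandard`, `inframe_ext`, `its_length` (total bp of attached
#'   arrays), `n_arrays`, `locus_start`, `locus_end` added.
#' @export
classify_organization <- function(candidates, seq) {
  if (!nrow(candidates)) {
    return(dplyr::mutate(candidates, organization = character(),
                         head_to_head = logical(), nonstandard = logical(),
                         inframe_ext = integer(), its_length = integer(),
                         n_arrays = integer(), locus_start = integer(),
                         locus_end = integer()))
  }
  len <- nchar(seq)
  rcseq <- revcomp(seq)
  res <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    h <- candidates[i, ]
    att <- h$arrays[[1]]
    h2h <- length(unique(att$strand)) > 1L
    pi <- order(-att$its_length, att$start)[1]
    a_lo <- min(att$start); a_hi <- max(att$end)
    side <- if (h$s_end <= a_lo) "left"
            else if (h$s_start >= a_hi) "right"
            else if ((h$s_start + h$s_end) / 2 < (a_lo + a_hi) / 2) "left"
            else "right"
    flip <- if (h2h) side == "right" else att$strand[pi] == "-"
    oside <- if (flip) setdiff(c("left", "right"), side) else side
    ostrand <- if (flip) c("+" = "-", "-" = "+")[[h$strand]] else h$strand
    cls <- NULL; nonstd <- FALSE
    if (oside == "left" && ostrand == "-") cls <- "A"
    else if (oside == "right" && ostrand == "+") cls <- "B"
    else if (oside == "left" && ostrand == "+") {
      cls <- "C"; nonstd <- !h2h
    } else { cls <- "A"; nonstd <- TRUE }
    # oriented coordinates and sequence
    oseq <- if (flip) rcseq else seq
    oarr <- att
    if (flip) {
      oarr <- tibble(start = len - att$end, end = len - att$start,
                     strand = ifelse(att$strand == "+", "-", "+"),
                     n_units = att$n_units, interruptions = att$interruptions,
                     its_length = att$its_length)
      oarr <- oarr[order(oarr$start), , drop = FALSE]
    }
    if (cls == "C" && !nonstd) {
      std <- nrow(oarr) >= 2L && oarr$strand[1] == "-" &&
             oarr$strand[nrow(oarr)] == "+"
      nonstd <- !std
    }
    k <- if (oside == "left") {
      a0 <- oarr$start[1]
      ring_register_left(substr(oseq, max(1L, a0 - 2L), a0),
                         substr(oseq, a0 + 1L, a0 + 6L))
    } else {
      ae <- oarr$end[nrow(oarr)]
      ring_register_right(substr(oseq, max(1L, ae - 5L), ae),
                          substr(oseq, ae + 1L, ae + 3L))
    }
    dplyr::mutate(h, organization = cls, head_to_head = h2h,
                  nonstandard = nonstd, inframe_ext = as.integer(k),
                  its_length = sum(att$its_length),
                  n_arrays = nrow(att),
                  locus_start = min(h$s_start, a_lo),
                  locus_end = max(h$s_end, a_hi))
  })
  res
}

#' Classify candidate loci against a TERC annotation
#'
#' Convenience wrapper: [map_to_terc()] then [classify_organization()].
#'
#' @inheritParams classify_organization
#' @inheritParams map_to_terc
#' @return The fully annotated locus tibble.
#' @export
classify_loci <- function(candidates, annotation, seq) {
  classify_organization(map_to_terc(candidates, annotation), seq)
}
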