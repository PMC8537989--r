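#' Find TERC-ITS loci in a genome
#'
#' The full discovery pipeline: seed-and-extend search of the TERC
#' query against every contig, telomeric-array scan, pairing of hits
#' with adjacent arrays, and structural classification. Hits without an
#' adjacent telomeric hexamer but with a substantial TERC alignment are
#' reported separately as TERC pseudogenes (attribute `pseudogenes`).
#'
#' @param genome Tibble of contigs (`id`, `seq`), e.g. from
#'   [read_fasta()].
#' @param terc TERC record (one-row tibble or string).
#' @param annotation A [terc_annotation()].
#' @param scoring A [scoring_scheme()].
#' @param min_score Minimum hit score.
#' @param xdrop x-drop threshold.
#' @param max_bridge Array interruption bridging (see
#'   [scan_telomere_arrays()]).
#' @param adjacency_window Maximum hit-to-array distance in bp.
#' @param pseudogene_min_length Minimum alignment length for a
#'   hexamer-less hit to be reported as a pseudogene.
#' @return Tibble of loci (class `tercits_loci`), one row per locus,
#'   with 1-based `localization` matching the locus naming convention
#'   (`contig:start`), plus classification columns; the pseudogene
#'   report is attached as `attr(x, "pseudogenes")`.
#' @export
run_find <- function(genome, terc, annotation = terc_annotation_default("human"),
                     scoring = scoring_scheme(), min_score = 30L, xdrop = 30L,
                     max_bridge = 6L, adjacency_window = 30L,
                     pseudogene_min_length = 100L) {
  terc_rec <- as_record(terc, "terc")
  loci <- list()
  pseudo <- list()
  for (ci in seq_len(nrow(genome))) {
    contig <- genome$id[ci]
    seq <- genome$seq[ci]
    hits <- search_terc_like(terc_rec$seq, stats::setNames(seq, contig),
                             scoring, min_score = min_score, xdrop = xdrop)
    if (!nrow(hits)) next
    arrays <- scan_telomere_arrays(seq, max_bridge = max_bridge)
    cand <- attach_its(hits, arrays, seq,
                       adjacency_window = adjacency_window,
                       template_interval = annotation$template)
    cand <- chain_arrays(cand, arrays, adjacency_window)
    cls <- classify_loci(cand, annotation, seq)
    cls <- dedupe_loci(cls)
    if (nrow(cls)) loci[[length(loci) + 1L]] <- cls
    paired <- if (nrow(cls)) cls$s_start else integer(0)
    un <- hits[!(hits$s_start %in% paired) & hits$length >= pseudogene_min_length, ]
    if (nrow(un))

      pseudo[[length(pseudo) + 1L]] <-
        dplyr::mutate(un, localization = paste0(.data$subject_id, ":",
                                                .data$s_start + 1L))
  }
  out <- if (length(loci)) dplyr::bind_rows(loci) else
    classify_organization(map_to_terc(empty_candidates(), annotation), "")
  if (nrow(out)) {
    out <- dplyr::mutate(
      out,
      locus_id = paste0(.data$subject_id, ":", .data$locus_start + 1L),
      localization = paste0(.data$subject_id, ":", .data$s_start + 1L),
      terc_like_length = .data$q_end - .data$q_start
    )
    out <- dplyr::arrange(out, .data$subject_id, .data$locus_start)
    out <- dplyr::select(
      out, "locus_id", "subject_id", "localization", "locus_start",
      "locus_end", "s_start", "s_end", "strand", "terc_like_length",
      "terc_from", "terc_to", "domain_label", "its_length", "n_arrays",
      "organization", "head_to_head", "nonstandard", "inframe_ext",
      "gap_to_its", "junction_bases", "score", "identities", "mismatches",
      "gap_columns", "q_start", "q_end", "arrays"
    )
  } else {
    out <- dplyr::mutate(out,
      locus_id = character(0), localization = character(0),
      terc_like_length = integer(0))
  }
  attr(out, "pseudogenes") <- if (length(pseudo)) dplyr::bind_rows(pseudo)
                              else empty_hits()
  class(out) <- c("tercits_loci", class(out))
  out
}

# one locus per genomic site: candidates whose locus spans overlap are
# collapsed to the highest-scoring TERC-like hit (ties: leftmost)
dedupe_loci <- function(cls) {
  if (nrow(cls) < 2L) return(cls)
  cls <- cls[order(-cls$score, cls$locus_start), , drop = FALSE]
  keep <- rep(TRUE, nrow(cls))
  for (i in seq_len(nrow(cls))[-1]) {
    for (j in seq_len(i - 1L)) {
      if (keep[j] && cls$locus_start[i] < cls$locus_end[j] &&
          cls$locus_start[j] < cls$locus_end[i]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  cls[keep, , drop = FALSE]
}

# transitively attach arrays adjacent to already-attached arrays, so a
# head-to-head pair is one locus even when the far stretch lies beyond
# the hit's adjacency window
chain_arrays <- function(cand, arrays, adjacency_window) {
  if (!nrow(cand) || !nrow(arrays)) return(cand)
  cand$arrays <- purrr::map(cand$arrays, function(att) {
    repeat {
      lo <- min(att$start); hi <- max(att$end)
      gap <- dplyr::case_when(
        arrays$end <= lo ~ lo - arrays$end,
        arrays$start >= hi ~ arrays$start - hi,
        TRUE ~ 0L
      )
      add <- gap <= adjacency_window &
             !(arrays$start %in% att$start & arrays$end %in% att$end)
      if (!any(add)) break
      att <- dplyr::bind_rows(att, arrays[add, ])
      att <- att[order(att$start), , drop = FALSE]
    }
    att
  })
  cand
}

#' Compare discovered loci against an ortholog genome
#'
#' For each locus, extracts the 1-kb window (locus widened by `flank`
#' on each side), places the flanks in the ortholog genome with
#' [locate_ortholog()], and, when the ortholog is empty, types the
#' break-site modifications with [type_modifications()].
#'
#' @param loci Locus report from [run_find()].
#' @param focal_genome,ortholog_genome Contig tibbles.
#' @param terc,annotation As in [run_find()].
#' @param scoring A [scoring_scheme()].
#' @param flank Window flank size (bp).
#' @param max_microhomology Microhomology search cap.
#' @param ... Further arguments passed to [locate_ortholog()].
#' @return Tibble: one row per locus with `status`, `flank_identity`
#'   and the modification fields (NA unless `status == "empty"`).
#' @export
run_compare <- function(loci, focal_genome, ortholog_genome, terc,
                        annotation = terc_annotation_default("human"),
                        scoring = scoring_scheme(), flank = 500L,
                        max_microhomology = 10L, ...) {
  terc_rec <- as_record(terc, "terc")
  purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    win <- extract_window(focal_genome, l$subject_id, l$locus_start,
                          l$locus_end, flank = flank)
    oc <- locate_ortholog(win, ortholog_genome, terc_rec$seq, annotation,
                          scoring = scoring, flank = flank, ...)
    base <- tibble(locus_id = l$locus_id, status = oc$status,
                   ortholog_contig = oc$contig, ortholog_strand = oc$strand,
                   flank_identity = oc$flank_identity)
    if (oc$status != "empty") {
      return(dplyr::mutate(base, deletion_len = NA_integer_,
                           insertion_len = NA_integer_,
                           category = NA_character_,
                           microhomology_len = NA_integer_,
                           microhomology_seq = NA_character_))
    }
    oseq <- substr(contig_seq(ortholog_genome, oc$contig),
                   oc$o_start + 1L, oc$o_end)
    if (oc$strand == "-") oseq <- revcomp(oseq)
    core_start <- l$locus_start - win$start
    core_end <- l$locus_end - win$start
    mods <- type_modifications(win, oseq, core_start, core_end,
                               scoring = scoring, flank = flank,
                               max_microhomology = max_microhomology)
    dplyr::bind_cols(base, mods[, c("deletion_len", "insertion_len",
                                    "category", "microhomology_len",
                                    "microhomology_seq")])
  })
}

#' Summarize locus and comparison reports
#'
#' Builds the summary tables of a screen: modification-category counts
#' with one-decimal percentages over the informative (empty-ortholog)
#' loci, organization counts, per-species locus counts (from a
#' `species` column when present, otherwise the contig id), and ITS
#' length extremes.
#'
#' @param loci Locus tibble (from [run_find()] or a fixture) with
#'   optional columns `organization`, `its_length`, `species`.
#' @param comparison Optional comparison tibble from [run_compare()]
#'   (or a fixture) with a `category` column.
#' @return Object of class `tercits_summary`.
#' @export
summarize_tercits <- function(loci, comparison = NULL) {
  cat_levels <- c("none", "deletion", "insertion", "deletion_and_insertion")
  categories <- NULL
  n_informative <- 0L
  n_modified <- 0L
  if (!is.null(comparison)) {
    inf <- comparison[!is.na(comparison$category), , drop = FALSE]
    n_informative <- nrow(inf)
    counts <- table(factor(inf$category, levels = cat_levels))
    categories <- tibble(
      category = cat_levels,
      n = as.integer(counts),
      pct = if (n_informative > 0)
        round(100 * as.integer(counts) / n_informative, 1) else rep(NA_real_, 4)
    )
    n_modified <- n_informative - categories$n[categories$category == "none"]
  }
  organizations <- if ("organization" %in% names(loci)) {
    dplyr::count(dplyr::as_tibble(loci), .data$organization, name = "n")
  }
  species_col <- if ("species" %in% names(loci)) loci$species
                 else if ("subject_id" %in% names(loci)) loci$subject_id
  species <- if (!is.null(species_col)) {
    dplyr::count(tibble(species = species_col), .data$species, name = "n")
  }
  its <- if ("its_length" %in% names(loci) && nrow(loci)) {
    range(loci$its_length)
  } else c(NA_integer_, NA_integer_)
  structure(list(
    n_loci = nrow(loci), n_informative = n_informative,
    n_modified = n_modified, categories = categories,
    organizations = organizations, species = species,
    its_length_min = its[1], its_length_max = its[2]
  ), class = "tercits_summary")
}

#' @export
print.tercits_summary <- function(x, ...) {
  cat(sprintf("<tercits_summary> %d loci, %d informative, %d modified\n",
              x$n_loci, x$n_informative, x$n_modified))
  if (!is.null(x$categories)) {
    for (i in seq_len(nrow(x$categories))) {
      cat(sprintf("  %-24s %3d (%.1f%%)\n", x$categories$category[i],
                  x$categories$n[i], x$categories$pct[i]))
    }
  }
  if (!is.null(x$organizations)) {
    cat("  organization:",
        paste(x$organizations$organization, x$organizations$n,
              sep = "=", collapse = " "), "\n")
  }
  if (!is.na(x$its_length_min)) {
    cat(sprintf("  ITS length %d-%d bp\n", x$its_length_min, x$its_length_max))
  }
  invisible(x)
}

#' Tidy a summary into the category table
#'
#' @param x A `tercits_summary`.
#' @param ... Unused.
#' @return Tibble of category counts and percentages.
#' @export
tidy.tercits_summary <- function(x, ...) {
  x$categories %||% tibble(category = character(), n = integer(),
                           pct = double())
}

#' One-row overview of a summary
#'
#' @param x A `tercits_summary`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.tercits_summary <- function(x, ...) {
  tibble(n_loci = x$n_loci, n_informative = x$n_informative,
         n_modified = x$n_modified,
         its_length_min = x$its_length_min,
         its_length_max = x$its_length_max)
}

#' Plot the modification-category spectrum of a summary
#'
#' @param object A `tercits_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tercits_summary <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$category, levels = df$category),
    y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of informative loci",
                  title = "Break-site modification spectrum") +
    ggplot2::theme_minimal()
}

#' Plot organization counts of a locus report
#'
#' @param loci Locus tibble with an `organization` column.
#' @return A ggplot.
#' @export
plot_organization <- function(loci) {
  df <- dplyr::count(dplyr::as_tibble(loci), .data$organization)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$organization, y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "organization", y = "loci") +
    ggplot2::theme_minimal()
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "tercits", mustWork = TRUE)
}

#' Packaged locus table fixture
#'
#' A machine-readable transcription of the published 41-locus table:
#' locus number, species, chromosomal localization, 1-based starting
#' nucleotide and length of the TERC-like sequence, its position within
#' TERC (1-based inclusive), ITS length, and the species lists with a
#' conserved TERC-ITS or an identified empty ortholog (`ND` = not
#' determined, stored as `NA`). Values are stored verbatim; rows whose
#' TERC-like fragment is shorter than the search word size are flagged
#' in `below_word_size`.
#'
#' @param word_size Word size used for the `below_word_size` flag.
#' @return Tibble with 41 rows.
#' @export
load_table1 <- function(word_size = 11L) {
  t1 <- utils::read.delim(fixture_path("table1.tsv"), sep = "\t",
                          na.strings = "ND", check.names = FALSE,
                          stringsAsFactors = FALSE)
  t1 <- as_tibble(t1)
  dplyr::mutate(t1, below_word_size = .data$terc_like_length < word_size)
}

#' Packaged modification-category table fixture
#'
#' The published counts of flanking-sequence modifications over the 29
#' informative loci.
#'
#' @return Tibble with columns `category`, `n`, `pct`.
#' @export
load_table2 <- function() {
  as_tibble(utils::read.delim(fixture_path("table2.tsv"), sep = "\t",
                              stringsAsFactors = FALSE))
}

#' Packaged per-locus organization assignments
#'
#' Organization type (`A`, `B` or `C`) for each of the 41 loci: type B
#' at loci 1, 2, 39 and 41; type C at locus 38; type A elsewhere.
#'
#' @return Tibble with columns `number`, `organization`.
#' @export
load_organization_assignments <- function() {
  as_tibble(utils::read.delim(fixture_path("organization_assignments.tsv"),
                              sep = "\t", stringsAsFactors = FALSE))
}

#' Write a locus report as TSV
#'
#' @param loci Locus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locus_report <- function(loci, path) {
  flat <- dplyr::select(dplyr::as_tibble(loci), -dplyr::any_of("arrays"))
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
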