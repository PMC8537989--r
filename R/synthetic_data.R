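#' Configuration for one planted TERC-ITS locus
#'
#' Describes the anatomy of a simulated insertion: structural
#' organization, TERC fragment to retrotranscribe, number of telomeric
#' units, break-site modifications (deletion / random insertion /
#' microhomology), in-frame 3' extension, and neutral divergence
#' between the derived (focal) and ancestral (ortholog) contigs.
#'
#' @param id Unique locus id.
#' @param organization `"A"`, `"B"` or `"C"` (head-to-head; requires
#'   `its_units >= 2`).
#' @param its_units Number of telomeric hexamer units (>= 1).
#' @param fragment_start,fragment_end 0-based half-open interval on
#'   TERC to retrotranscribe; `NA` lets [simulate_cohort()] sample an
#'   interval of 25-98 nt outside the template region.
#' @param deletion_len Ancestral bases deleted at the junction.
#' @param insertion_len Random bases added at the junction.
#' @param microhomology_len Microhomology between the insert 3' end and
#'   the retained right flank.
#' @param inframe_ext In-frame 3' extension of the fragment, 0-3.
#' @param divergence Per-site substitution probability applied
#'   independently to each contig outside the insert, in `[0, 0.2]`.
#' @param contig_len Ancestral contig length (junction at the midpoint).
#' @param insert_side Side of the insert on which random bases are
#'   appended (`"right"` or `"left"`).
#' @return One-row tibble.
#' @export
locus_config <- function(id, organization = "A", its_units = 10L,
                         fragment_start = NA_integer_,
                         fragment_end = NA_integer_,
                         deletion_len = 0L, insertion_len = 0L,
                         microhomology_len = 0L, inframe_ext = 0L,
                         divergence = 0.02, contig_len = 4000L,
                         insert_side = "right") {
  stopifnot(organization %in% c("A", "B", "C"),
            its_units >= 1L, inframe_ext >= 0L, inframe_ext <= 3L,
            deletion_len >= 0L, insertion_len >= 0L,
            microhomology_len >= 0L,
            divergence >= 0, divergence <= 0.2,
            insert_side %in% c("right", "left"))
  if (organization == "C" && its_units < 2L) {
    stop("organization C needs its_units >= 2 (two head-to-head stretches)")
  }
  tibble(id = id, organization = organization,
         its_units = as.integer(its_units),
         fragment_start = as.integer(fragment_start),
         fragment_end = as.integer(fragment_end),
         deletion_len = as.integer(deletion_len),
         insertion_len = as.integer(insertion_len),
         microhomology_len = as.integer(microhomology_len),
         inframe_ext = as.integer(inframe_ext),
         divergence = divergence, contig_len = as.integer(contig_len),
         insert_side = insert_side)
}

BASES <- c("A", "C", "G", "T")

sample_bases <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

has_motif_near <- function(s, pos) {
  win <- substr(s, max(1L, pos - 5L), min(nchar(s), pos + 5L))
  grepl("TTAGGG", win, fixed = TRUE) || grepl("CCCTAA", win, fixed = TRUE)
}

# set position `pos` (1-based) to the first base not in `avoid` (and not
# the current base when change is mandatory) that does not create a
# telomeric hexamer around pos
safe_set <- function(s, pos, avoid, keep_current = TRUE) {
  cur <- substr(s, pos, pos)
  if (keep_current && !(cur %in% avoid)) return(s)
  for (b in setdiff(BASES, unique(c(avoid, cur)))) {
    cand <- s
    substr(cand, pos, pos) <- b
    if (!has_motif_near(cand, pos)) return(cand)
  }
  for (b in setdiff(BASES, unique(c(avoid, cur)))) { # accept motif if forced
    cand <- s
    substr(cand, pos, pos) <- b
    return(cand)
  }
  stop("cannot satisfy base constraints at position ", pos)
}

# remove every TTAGGG/CCCTAA occurrence outside `allowed` (0-based
# half-open) by mutating one mutable base per occurrence
scrub_motifs <- function(s, allowed = c(0L, 0L), protected = integer(0)) {
  for (iter in seq_len(2000L)) {
    hits <- c()
    for (m in c("TTAGGG", "CCCTAA")) {
      g <- gregexpr(m, s, fixed = TRUE)[[1]]
      if (g[1] != -1) hits <- c(hits, as.integer(g))
    }
    if (!length(hits)) return(s)
    hits <- sort(hits)
    done <- TRUE
    for (p in hits) { # p is 1-based start
      if (p - 1L >= allowed[1] && p + 5L <= allowed[2]) next # inside template
      mutable <- setdiff(p:(p + 5L), protected)
      mutable <- mutable[mutable - 1L < allowed[1] | mutable > allowed[2]]
      if (!length(mutable)) {
        stop("telomeric motif overlaps only protected positions")
      }
      q <- mutable[ceiling(length(mutable) / 2)]
      cur <- substr(s, q, q)
      repl <- setdiff(BASES, cur)[1]
      substr(s, q, q) <- repl
      done <- FALSE
      break
    }
    if (done) return(s)
  }
  stop("motif scrubbing did not converge")
}

# i.i.d. substitution divergence; `skip` is a 0-based half-open interval
# left untouched
mutate_diverge <- function(s, p, skip = NULL) {
  if (p <= 0) return(s)
  n <- nchar(s)
  idx <- which(stats::runif(n) < p)
  if (!is.null(skip)) idx <- idx[idx <= skip[1] | idx > skip[2]]
  if (!length(idx)) return(s)
  ch <- strsplit(s, "")[[1]]
  ch[idx] <- vapply(ch[idx],
                    function(b) sample(setdiff(BASES, b), 1L), "")
  paste(ch, collapse = "")
}

comp1 <- function(b) c(A = "T", C = "G", G = "C", T = "A", N = "N")[[b]]

#' Generate a synthetic TERC sequence
#'
#' A random sequence at the requested GC content whose template interval
#' carries the canonical telomeric-repeat template (a substring of the
#' `(CCCTAA)^n` ring, the complement of the repeats it templates).
#' Telomeric hexamers are scrubbed from the rest of the molecule so the
#' template is the only repeat-complementary stretch, and optional
#' per-position constraints (used by [simulate_cohort()] to pin
#' fragment-boundary bases) are honoured. Deterministic given `seed`.
#'
#' @param terc_length Length in nt (vertebrate range, 200-600).
#' @param template_interval 0-based half-open template interval.
#' @param background_gc GC fraction of the non-template sequence.
#' @param seed Integer seed.
#' @param constraints Optional list with data frames `equal` (`pos`
#'   0-based, `base`) and `forbid` (`pos`, `base`).
#' @return One-row tibble (`id = "TERC"`, `seq`).
#' @export
make_terc <- function(terc_length = 451L, template_interval = c(45L, 56L),
                      background_gc = 0.42, seed = 1L, constraints = NULL) {
  stopifnot(terc_length >= 200L, terc_length <= 600L)
  if (template_interval[1] < 0 || template_interval[2] > terc_length ||
      template_interval[2] <= template_interval[1]) {
    stop("template_interval outside the TERC sequence")
  }
  withr::with_seed(seed, {
    s <- sample_bases(terc_length, background_gc)
    tpl_len <- template_interval[2] - template_interval[1]
    ring <- strrep("CCCTAA", ceiling(tpl_len / 6) + 1L)
    tpl <- substr(ring, 3L, 2L + tpl_len) # CUAAC... phase
    substr(s, template_interval[1] + 1L, template_interval[2]) <- tpl
    protected <- integer(0)
    if (!is.null(constraints) && nrow(constraints$equal)) {
      eq <- constraints$equal
      dup <- duplicated(eq$pos)
      conf <- vapply(unique(eq$pos[dup]), function(p) {
        length(unique(eq$base[eq$pos == p])) > 1L
      }, logical(1))
      if (any(conf)) stop("conflicting base constraints between locus configs")
      for (r in seq_len(nrow(eq))) {
        if (eq$pos[r] >= template_interval[1] && eq$pos[r] < template_interval[2]) {
          stop("constraint inside the template interval")
        }
        substr(s, eq$pos[r] + 1L, eq$pos[r] + 1L) <- eq$base[r]
      }
      protected <- unique(eq$pos + 1L)
    }
    if (!is.null(constraints) && nrow(constraints$forbid)) {
      fb <- constraints$forbid
      for (p in unique(fb$pos)) {
        if (p < 0 || p >= terc_length) next
        avoid <- fb$base[fb$pos == p]
        if ((p + 1L) %in% protected) {
          if (substr(s, p + 1L, p + 1L) %in% avoid) {
            stop("conflicting base constraints between locus configs")
          }
        } else {
          s <- safe_set(s, p + 1L, avoid)
        }
      }
      protected <- unique(c(protected, fb$pos + 1L))
    }
    s <- scrub_motifs(s, allowed = template_interval, protected = protected)
    tibble(id = "TERC", seq = s)
  })
}

build_insert_core <- function(terc_seq, cfg) {
  frag <- substr(terc_seq, cfg$fragment_start + 1L, cfg$fragment_end)
  u <- cfg$its_units
  switch(cfg$organization,
    A = paste0(revcomp(frag), strrep("TTAGGG", u)),
    B = paste0(strrep("TTAGGG", u), frag),
    C = {
      a <- ceiling(u / 2); b <- u - a
      paste0(frag, strrep("CCCTAA", a), strrep("TTAGGG", b))
    })
}

#' Plant one TERC-ITS locus into an ancestral contig
#'
#' Builds the derived (focal) allele from the ancestral one: removes
#' `deletion_len` bases at the junction (the contig midpoint), inserts
#' the TERC-like fragment and telomeric array in the configured
#' organization, appends `insertion_len` random bases on the configured
#' side, forces the configured microhomology with the retained right
#' flank, and applies divergence outside the insert. Junction-adjacent
#' bases are constrained so that the planted anatomy is exactly
#' identifiable (alignment extension stops at the fragment boundary,
#' random bases never continue the telomeric register, the realised
#' microhomology equals the configured one). Uses the current RNG
#' stream; [simulate_cohort()] seeds one substream per locus.
#'
#' @param ancestral_seq Ancestral contig sequence (motif-free
#'   background, e.g. from [simulate_cohort()]'s internal generator).
#' @param terc_seq TERC sequence (string) whose fragment interval bases
#'   satisfy the in-frame constraints when `inframe_ext > 0` (see
#'   [make_terc()] constraints).
#' @param cfg One-row config from [locus_config()] with a resolved
#'   fragment interval.
#' @return List with `derived` (focal contig), `ancestral` (diverged
#'   ortholog contig) and `truth` (one-row tibble of planted values).
#' @export
plant_locus <- function(ancestral_seq, terc_seq, cfg) {
  n <- nchar(ancestral_seq)
  mid <- n %/% 2L
  d <- cfg$deletion_len
  i_len <- cfg$insertion_len
  if (mid + d > n - 600L || mid < 600L) {
    stop("deletion too long for the contig (flanks must keep >= 600 bases)")
  }
  s <- cfg$fragment_start; e <- cfg$fragment_end
  tlen <- nchar(terc_seq)
  anc <- ancestral_seq

  # left-flank extension stop: the 4 ancestral bases left of the
  # junction must not continue the fragment alignment
  if (cfg$insert_side == "right" || i_len == 0L) {
    for (j in 0:3) {
      pos <- mid - j # 1-based index of ancestral base mid-1-j (0-based)
      tp <- switch(cfg$organization,
                   A = if (e + j < tlen) comp1(substr(terc_seq, e + 1L + j, e + 1L + j)),
                   B = NULL,
                   C = if (s - 1L - j >= 0L) substr(terc_seq, s - j, s - j))
      if (!is.null(tp)) anc <- safe_set(anc, pos, tp)
    }
  }

  L <- substr(anc, 1L, mid)
  D <- substr(anc, mid + 1L, mid + d)
  R <- substr(anc, mid + d + 1L, n)

  core <- build_insert_core(terc_seq, cfg)
  rnd <- ""
  if (i_len > 0L) {
    rnd <- scrub_motifs(sample_bases(i_len, 0.5))
    if (cfg$insert_side == "right") {
      # random bases must not continue the telomeric register off the
      # core end, nor continue the fragment alignment (organization B)
      tail6 <- substr(core, nchar(core) - 5L, nchar(core))
      if (grepl(tail6, "TTAGGGTTAGGG", fixed = TRUE)) {
        nxt <- ring_next_char(tail6, "TTAGGG")
        rnd <- safe_set(rnd, 1L, nxt)
      }
      if (cfg$organization == "B") {
        for (j in 0:min(3L, i_len - 1L)) {
          if (e + j < tlen) {
            rnd <- safe_set(rnd, j + 1L, substr(terc_seq, e + 1L + j, e + 1L + j))
          }
        }
      }
      # right-flank anchoring must not run past the junction: the last
      # random bases mismatch their diagonal ancestral counterparts
      for (k in 0:(min(4L, i_len) - 1L)) {
        cp <- if (k < d) substr(D, d - k, d - k)
              else substr(L, mid - (k - d), mid - (k - d))
        rnd <- safe_set(rnd, i_len - k, cp)
      }
    } else {
      head6 <- substr(core, 1L, 6L)
      if (grepl(head6, "TTAGGGTTAGGG", fixed = TRUE)) {
        prv <- ring_prev_char(head6, "TTAGGG")
        rnd <- safe_set(rnd, i_len, prv)
      }
      for (j in 0:min(3L, i_len - 1L)) { # stop for fragment at core start
        tp <- switch(cfg$organization,
                     A = if (e + j < tlen) comp1(substr(terc_seq, e + 1L + j, e + 1L + j)),
                     B = NULL,
                     C = if (s - 1L - j >= 0L) substr(terc_seq, s - j, s - j))
        if (!is.null(tp)) rnd <- safe_set(rnd, i_len - j, tp)
      }
      for (k in 0:(min(4L, i_len) - 1L)) { # left-flank anchoring stop
        cp <- if (k < d) substr(D, k + 1L, k + 1L)
              else substr(R, k - d + 1L, k - d + 1L)
        rnd <- safe_set(rnd, k + 1L, cp)
      }
    }
  }
  # forbidden bases per R prefix position (alignment-extension stops);
  # honoured both when first applied and by the microhomology repair
  R_avoid <- rep(list(character(0)), 10L)
  if (i_len == 0L && cfg$insert_side == "right" &&
      cfg$organization == "B" && cfg$microhomology_len == 0L) {
    for (j in 0:3) { # fragment abuts R directly: stop the alignment there
      if (e + j < tlen && j < nchar(R)) {
        R_avoid[[j + 1L]] <- substr(terc_seq, e + 1L + j, e + 1L + j)
      }
    }
  }

  insert_full <- if (cfg$insert_side == "right") paste0(core, rnd)
                 else paste0(rnd, core)
  ilen <- nchar(insert_full)

  # force the configured microhomology with the retained right flank
  mh <- cfg$microhomology_len
  if (mh > 0L) {
    stopifnot(mh <= ilen, mh < nchar(R))
    substr(R, 1L, mh) <- substr(insert_full, ilen - mh + 1L, ilen)
  }
  for (p in seq_along(R_avoid)) {
    if (length(R_avoid[[p]])) R <- safe_set(R, p, R_avoid[[p]])
  }
  mh_cap <- max(10L, mh)
  for (rep_i in seq_len(100L)) {
    realised <- 0L
    for (k in seq_len(min(mh_cap, ilen))) {
      if (substr(insert_full, ilen - k + 1L, ilen) == substr(R, 1L, k)) {
        realised <- k
      }
    }
    if (realised <= mh) break
    avoid <- c(R_avoid[[realised]], substr(R, realised, realised))
    R <- safe_set(R, realised, avoid, keep_current = FALSE)
  }
  if (realised > mh) stop("could not pin the configured microhomology")

  derived <- paste0(L, insert_full, R)
  insert_start <- mid
  core_start <- insert_start + if (cfg$insert_side == "left") i_len else 0L
  truth <- tibble(
    id = cfg$id, organization = cfg$organization,
    insert_start = insert_start, insert_end = insert_start + ilen,
    core_start = core_start, core_end = core_start + nchar(core),
    fragment_start = s, fragment_end = e,
    its_units = cfg$its_units, its_length = 6L * cfg$its_units,
    deletion_len = d, insertion_len = i_len,
    microhomology_len = realised, inframe_ext = cfg$inframe_ext,
    ortholog_junction = mid, divergence = cfg$divergence
  )
  list(
    derived = mutate_diverge(derived, cfg$divergence,
                             skip = c(insert_start, insert_start + ilen)),
    ancestral = mutate_diverge(paste0(L, D, R), cfg$divergence),
    truth = truth
  )
}

ring_next_char <- function(tail6, ring) {
  big <- strrep(ring, 3)
  p <- regexpr(tail6, big, fixed = TRUE)[1]
  substr(big, p + 6L, p + 6L)
}

ring_prev_char <- function(head6, ring) {
  big <- strrep(ring, 3)
  p <- regexpr(head6, substr(big, 2L, nchar(big)), fixed = TRUE)[1] + 1L
  substr(big, p - 1L, p - 1L)
}

# deterministic 32-bit string hash for per-locus RNG substreams
sub_seed <- function(seed, ...) {
  key <- paste(..., sep = ":")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483563
  as.integer((as.numeric(seed) + h) %% 2147483563) + 1L
}

# constraints the TERC sequence must satisfy so every planted locus is
# exactly recoverable (in-frame register at the fragment boundary plus
# alignment-extension stops into the adjacent telomeric array)
terc_constraints_for <- function(cfg, terc_length) {
  s <- cfg$fragment_start; e <- cfg$fragment_end
  k <- cfg$inframe_ext
  eq <- list(); fb <- list()
  add_eq <- function(pos, base) {
    if (pos >= 0 && pos < terc_length) eq[[length(eq) + 1L]] <<- c(pos, base)
  }
  add_fb <- function(pos, base) {
    if (pos >= 0 && pos < terc_length) fb[[length(fb) + 1L]] <<- c(pos, base)
  }
  if (cfg$organization == "A") {
    if (k > 0) for (j in 0:(k - 1L)) add_eq(s + j, "C")
    if (k < 3) add_fb(s + k, "C")
    purrr::walk2(1:4, c("A", "A", "T", "C"), ~ add_fb(s - .x, .y))
  } else if (cfg$organization == "B") {
    if (k > 0) for (j in 0:(k - 1L)) add_eq(s + j, substr("TTA", j + 1L, j + 1L))
    if (k < 3) add_fb(s + k, substr("TTAG", k + 1L, k + 1L))
    purrr::walk2(1:4, c("G", "G", "G", "A"), ~ add_fb(s - .x, .y))
  } else {
    if (k > 0) for (j in seq_len(k)) {
      add_eq(e - j, substr("AAT", j, j)) # suffix of "TAA", inside out
    }
    if (k == 0) add_fb(e - 1L, "A")
    if (k == 1) add_fb(e - 2L, "A")
    if (k == 2) add_fb(e - 3L, "T")
    purrr::walk2(0:3, c("C", "C", "C", "T"), ~ add_fb(e + .x, .y))
  }
  list(equal = to_pos_df(eq), forbid = to_pos_df(fb))
}

to_pos_df <- function(lst) {
  if (!length(lst)) return(data.frame(pos = integer(), base = character()))
  data.frame(pos = as.integer(vapply(lst, `[`, "", 1)),
             base = vapply(lst, `[`, "", 2))
}

#' Simulate a cohort of orthologous contig pairs with planted loci
#'
#' One ancestral/derived contig pair per config row, a shared synthetic
#' TERC, and the full ground truth. Each locus draws from its own RNG
#' substream derived by hashing its id, so adding a locus does not
#' perturb the others; two runs with the same seed are byte-identical.
#'
#' @param configs Tibble of [locus_config()] rows with unique ids.
#' @param seed Integer master seed.
#' @param annotation A [terc_annotation()] defining TERC length,
#'   template and domains (default: packaged human-like layout).
#' @param background_gc Background GC fraction for contigs and TERC.
#' @return Object of class `tercits_cohort`: a list with tibbles
#'   `focal`, `ortholog`, `terc`, `truth` and the `annotation`.
#' @export
simulate_cohort <- function(configs, seed,
                            annotation = terc_annotation_default("human"),
                            background_gc = 0.42) {
  if (!is.data.frame(configs) || !nrow(configs)) {
    stop("configs must be a non-empty tibble of locus configurations")
  }
  if (anyDuplicated(configs$id)) stop("duplicate locus ids in configs")
  tlen <- annotation$terc_length
  tpl <- annotation$template
  # resolve fragment intervals outside the template (12 nt clearance)
  configs <- dplyr::rowwise(configs) |> dplyr::ungroup()
  for (r in seq_len(nrow(configs))) {
    if (is.na(configs$fragment_start[r])) {
      withr::with_seed(sub_seed(seed, configs$id[r], "frag"), {
        flen <- sample(25:98, 1L)
        lo <- 4L
        hi <- tlen - flen - 4L
        ok <- integer(0)
        if (hi >= lo) {
          cand <- lo:hi
          ok <- cand[cand >= tpl[2] + 12L | cand + flen <= tpl[1] - 12L]
        }
        if (!length(ok)) stop("no room for a fragment outside the template")
        st <- sample(ok, 1L)
        configs$fragment_start[r] <- st
        configs$fragment_end[r] <- st + flen
      })
    }
  }
  cons <- purrr::map(seq_len(nrow(configs)),
                     ~ terc_constraints_for(configs[.x, ], tlen))
  constraints <- list(
    equal = unique(dplyr::bind_rows(purrr::map(cons, "equal"))),
    forbid = unique(dplyr::bind_rows(purrr::map(cons, "forbid")))
  )
  terc <- make_terc(tlen, tpl, background_gc,
                    seed = sub_seed(seed, "TERC"), constraints = constraints)
  out <- purrr::map(seq_len(nrow(configs)), function(r) {
    cfg <- configs[r, ]
    withr::with_seed(sub_seed(seed, cfg$id, "locus"), {
      anc <- scrub_motifs(sample_bases(cfg$contig_len, background_gc))
      plant_locus(anc, terc$seq, cfg)
    })
  })
  structure(list(
    focal = tibble(id = configs$id,
                   seq = vapply(out, function(x) x$derived, "")),
    ortholog = tibble(id = configs$id,
                      seq = vapply(out, function(x) x$ancestral, "")),
    terc = terc,
    truth = dplyr::bind_rows(purrr::map(out, "truth")),
    annotation = annotation,
    configs = configs
  ), class = "tercits_cohort")
}

#' @export
print.tercits_cohort <- function(x, ...) {
  cat(sprintf("<tercits_cohort> %d locus pair(s), TERC %d nt\n",
              nrow(x$truth), nchar(x$terc$seq)))
  invisible(x)
}

#' Default cohort configurations from organization assignments
#'
#' Builds one default [locus_config()] per assignment row (`number`,
#' `organization`), cycling ITS unit counts over 2-20 and leaving
#' fragment intervals to be sampled by [simulate_cohort()].
#'
#' @param assignments Tibble with columns `number` and `organization`
#'   (e.g. [load_organization_assignments()]).
#' @param divergence Per-contig substitution probability.
#' @return Tibble of configs.
#' @export
default_cohort_configs <- function(assignments, divergence = 0.02) {
  purrr::map_dfr(seq_len(nrow(assignments)), function(i) {
    locus_config(
      id = sprintf("locus%02d", assignments$number[i]),
      organization = assignments$organization[i],
      its_units = 2L + (i - 1L) %% 19L,
      divergence = divergence
    )
  })
}

#' Write a cohort to FASTA and truth TSV files
#'
#' @param cohort A `tercits_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    focal = file.path(dir, "focal.fa"),
    ortholog = file.path(dir, "ortholog.fa"),
    terc = file.path(dir, "terc.fa"),
    truth = file.path(dir, "truth.tsv")
  )
  write_fasta(cohort$focal, paths$focal)
  write_fasta(cohort$ortholog, paths$ortholog)
  write_fasta(cohort$terc, paths$terc)
  utils::write.table(cohort$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
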