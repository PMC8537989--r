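test_that("scoring scheme validates its invariants", {
  sc <- scoring_scheme()
  expect_equal(unlist(sc[c("match", "mismatch", "gap_open", "gap_extend",
                           "word_size")]),
               c(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2,
                 word_size = 11))
  expect_error(scoring_scheme(match = 0))
  expect_error(scoring_scheme(mismatch = 1))
  expect_error(scoring_scheme(gap_extend = 0))
  expect_error(scoring_scheme(word_size = 3))
})

test_that("word seeds report exact matches on both strands", {
  q <- "TTAGGGTTAGG"
  s <- paste0("ACCA", q, "GGCATT")
  seeds <- find_word_seeds(q, s, 11)
  expect_equal(nrow(seeds), 1L)
  expect_equal(seeds$qpos, 0L)
  expect_equal(seeds$spos, 4L)
  expect_equal(seeds$strand, "+")

  q2 <- "ACGTACGATCGT"
  seeds2 <- find_word_seeds(q2, rc_chr(q2), 12)
  expect_true(all(seeds2$strand == "-"))
  expect_equal(nrow(seeds2), 1L)

  # word longer than the sequences: empty, not an error
  expect_equal(nrow(find_word_seeds("ACGT", "ACGT", 11)), 0L)
})

test_that("seed enumeration equals brute force on random pairs", {
  withr::local_seed(91)
  w <- 7L
  for (rep in 1:5) {
    q <- random_dna(100)
    s <- random_dna(100)
    got <- find_word_seeds(q, s, w)
    qrc <- rc_chr(q)
    want <- list()
    for (i in 0:(100 - w)) for (j in 0:(100 - w)) {
      if (substr(q, i + 1, i + w) == substr(s, j + 1, j + w)) {
        want[[length(want) + 1L]] <- c(i, j, 1L)
      }
      if (substr(qrc, i + 1, i + w) == substr(s, j + 1, j + w)) {
        want[[length(want) + 1L]] <- c(100L - w - i, j, 2L)
      }
    }
    wantm <- if (length(want)) do.call(rbind, want) else
      matrix(integer(), ncol = 3)
    gotm <- cbind(got$qpos, got$spos, ifelse(got$strand == "+", 1L, 2L))
    expect_equal(nrow(gotm), nrow(wantm))
    expect_setequal(apply(gotm, 1, paste, collapse = ","),
                    apply(wantm, 1, paste, collapse = ","))
    # strand mirror: seeds of (q, s) on + equal seeds of (q, rc(s)) on -
    got_rc <- find_word_seeds(q, rc_chr(s), w)
    plus <- got[got$strand == "+", ]
    minus_m <- got_rc[got_rc$strand == "-", ]
    expect_setequal(paste(plus$qpos, 100L - w - plus$spos),
                    paste(minus_m$qpos, minus_m$spos))
  }
})

test_that("x-drop extension scores a bare seed and clean extensions correctly", {
  withr::local_seed(5)
  # an 11-mer seed with inextensible context scores 11 * 2 = 22
  core <- "GATCGATCGAT"
  q <- core
  s <- paste0("CCCC", core, "CCCC") # q has no context to extend into
  h <- extend_seed(q, s, 0, 4, "+", xdrop = 30)
  expect_equal(h$score, 22L)
  expect_equal(h$identities, 11L)

  # 20 consecutive matches containing the seed
  twenty <- random_dna(20)
  s2 <- paste0("GGAATT", twenty, "AACCTT")
  q2 <- twenty
  h2 <- extend_seed(q2, s2, 4, 10, "+", xdrop = 30)
  expect_equal(h2$score, 40L)
  expect_equal(h2$identities, 20L)
  expect_equal(h2$mismatches, 0L)
})

test_that("search finds a planted reverse-complemented fragment exactly", {
  withr::local_seed(42)
  terc <- random_dna(400)
  frag <- substr(terc, 201, 250)
  bg <- random_dna(10000)
  sub <- paste0(substr(bg, 1, 5000), rc_chr(frag), substr(bg, 5001, 10000))
  hits <- search_terc_like(terc, sub, min_score = 40)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_gte(hits$identities, 50L)
  expect_equal(hits$s_start <= 5000 && hits$s_end >= 5050, TRUE)

  # negative control: nothing planted
  hits0 <- search_terc_like(terc, bg, min_score = 40)
  expect_equal(nrow(hits0), 0L)
})

test_that("mismatched planted fragments score as recomputed from the gapped strings", {
  withr::local_seed(77)
  terc <- random_dna(400)
  frag <- strsplit(substr(terc, 101, 150), "")[[1]]
  frag[c(10, 30)] <- vapply(frag[c(10, 30)],
                            function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  # the subject is exactly the 50-nt mutated fragment, so the alignment
  # cannot extend into flanking sequence by chance matches
  sub <- paste(frag, collapse = "")
  hits <- search_terc_like(terc, sub, min_score = 40)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identities, 48L)
  expect_equal(hits$mismatches, 2L)
  expect_equal(hits$score, 48L * 2L - 2L * 3L) # 90
  expect_equal(alignment_score(hits$aligned_query, hits$aligned_subject),
               hits$score)
})

test_that("search equals the exhaustive local-alignment score on homologous pairs", {
  withr::local_seed(2024)
  sc <- scoring_scheme()
  for (rep in 1:30) {
    p <- make_homologous_pair(core_len = sample(40:80, 1),
                              n_mut = sample(0:3, 1),
                              flank_a = sample(20:60, 1),
                              flank_b = sample(20:60, 1))
    hits <- search_terc_like(p$a, p$b, sc, min_score = 20,
                             xdrop = 2 * sc$gap_open + 20)
    expect_gt(nrow(hits), 0)
    expect_equal(max(hits$score), oracle_best_local_score(p$a, p$b, sc))
  }
})

test_that("search is strand symmetric", {
  withr::local_seed(13)
  for (rep in 1:5) {
    p <- make_homologous_pair()
    h1 <- search_terc_like(p$a, p$b, min_score = 25)
    h2 <- search_terc_like(p$a, rc_chr(p$b), min_score = 25)
    expect_equal(nrow(h1), nrow(h2))
    expect_setequal(h1$score, h2$score)
    n <- nchar(p$b)
    expect_setequal(paste(h1$s_start, h1$s_end, h1$strand),
                    paste(n - h2$s_end, n - h2$s_start,
                          ifelse(h2$strand == "+", "-", "+")))
  }
})

test_that("every emitted hit score is recomputable from its gapped strings", {
  withr::local_seed(19)
  co <- simulate_cohort(dplyr::bind_rows(
    locus_config("x1", "A", its_units = 5, divergence = 0.05),
    locus_config("x2", "B", its_units = 4, divergence = 0.05)
  ), seed = 3)
  for (i in 1:2) {
    hits <- search_terc_like(co$terc$seq, co$focal$seq[i])
    expect_gt(nrow(hits), 0)
    expect_equal(alignment_score(hits$aligned_query, hits$aligned_subject),
                 hits$score)
  }
})

test_that("tabular hit output has the documented 12-column layout", {
  withr::local_seed(10)
  p <- make_homologous_pair()
  hits <- search_terc_like(p$a, p$b, min_score = 25)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, tf)
  lines <- readLines(tf)
  expect_match(lines[1], "^# qseqid")
  expect_equal(length(strsplit(lines[2], "\t")[[1]]), 11L)
})
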