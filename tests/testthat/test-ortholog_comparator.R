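make_pair <- function(..., seed = 50) {
  co <- simulate_cohort(dplyr::bind_rows(...), seed = seed)
  loci <- run_find(co$focal, co$terc, co$annotation)
  list(co = co, loci = loci)
}

test_that("zero-divergence generator pairs give empty orthologs at identity 1", {
  x <- make_pair(locus_config("p1", "A", its_units = 6, divergence = 0))
  win <- extract_window(x$co$focal, "p1", x$loci$locus_start, x$loci$locus_end,
                        flank = 500)
  oc <- locate_ortholog(win, x$co$ortholog, x$co$terc$seq, x$co$annotation)
  expect_equal(oc$status, "empty")
  expect_equal(oc$flank_identity, 1.0)
  tr <- x$co$truth
  expect_true(oc$o_start < tr$ortholog_junction &&
              oc$o_end > tr$ortholog_junction)

  # self-comparison control: the focal genome itself is occupied
  oc2 <- locate_ortholog(win, x$co$focal, x$co$terc$seq, x$co$annotation)
  expect_equal(oc2$status, "occupied")
})

test_that("flanks landing on different contigs give not_found", {
  x <- make_pair(locus_config("p1", "A", its_units = 6, divergence = 0))
  win <- extract_window(x$co$focal, "p1", x$loci$locus_start, x$loci$locus_end,
                        flank = 500)
  anc <- x$co$ortholog$seq[1]
  split_genome <- tibble::tibble(
    id = c("left", "right"),
    seq = c(substr(anc, 1, 2000), substr(anc, 2001, nchar(anc))))
  oc <- locate_ortholog(win, split_genome, x$co$terc$seq, x$co$annotation)
  expect_equal(oc$status, "not_found")
})

test_that("type_modifications recovers the published junction magnitudes", {
  # the worked deletion (277 bp) and random insertion (17 bp) cases
  x <- make_pair(
    locus_config("none0", "A", its_units = 5, divergence = 0),
    locus_config("del277", "A", its_units = 5, deletion_len = 277,
                 divergence = 0),
    locus_config("ins17", "A", its_units = 5, insertion_len = 17,
                 divergence = 0),
    seed = 60)
  cmp <- run_compare(x$loci, x$co$focal, x$co$ortholog, x$co$terc,
                     x$co$annotation)
  cmp <- cmp[match(paste0(c("none0", "del277", "ins17"), ":2001"),
                   cmp$locus_id), ]
  expect_equal(cmp$status, rep("empty", 3))
  expect_equal(cmp$category, c("none", "deletion", "insertion"))
  expect_equal(cmp$deletion_len, c(0L, 277L, 0L))
  expect_equal(cmp$insertion_len, c(0L, 0L, 17L))
})

test_that("combined deletion and insertion is typed at 1% flank divergence", {
  x <- make_pair(locus_config("di", "A", its_units = 4, deletion_len = 12,
                              insertion_len = 5, divergence = 0.01),
                 seed = 61)
  cmp <- run_compare(x$loci, x$co$focal, x$co$ortholog, x$co$terc,
                     x$co$annotation)
  expect_equal(cmp$category, "deletion_and_insertion")
  expect_equal(cmp$deletion_len, 12L)
  expect_equal(cmp$insertion_len, 5L)
})

test_that("microhomology is the longest insert-suffix / flank-prefix match", {
  expect_equal(microhomology("CCTTAG", "TAGCAAT"),
               list(length = 3L, seq = "TAG"))
  expect_equal(microhomology("CCTTAG", "TCAA"), list(length = 0L, seq = ""))
  withr::local_seed(12)
  for (rep in 1:50) {
    ins <- random_dna(sample(10:40, 1))
    fl <- random_dna(sample(10:40, 1))
    m <- sample(0:6, 1)
    if (m > 0) substr(fl, 1, m) <- substr(ins, nchar(ins) - m + 1, nchar(ins))
    got <- microhomology(ins, fl)
    expect_equal(got$length, oracle_microhomology(ins, fl))
    expect_gte(got$length, m)
  }
})

test_that("planted microhomologies are recovered through the pipeline", {
  x <- make_pair(
    locus_config("m0", "A", its_units = 5, divergence = 0),
    locus_config("m3", "A", its_units = 5, microhomology_len = 3,
                 divergence = 0),
    locus_config("m5i", "A", its_units = 5, insertion_len = 17,
                 microhomology_len = 5, divergence = 0),
    seed = 62)
  cmp <- run_compare(x$loci, x$co$focal, x$co$ortholog, x$co$terc,
                     x$co$annotation)
  got <- cmp$microhomology_len[match(paste0(c("m0", "m3", "m5i"), ":2001"),
                                     cmp$locus_id)]
  expect_equal(got, c(0L, 3L, 5L))
})

test_that("swapping the roles of an identical empty pair still yields category none", {
  withr::local_seed(9)
  anc <- random_dna(3000)
  ch <- strsplit(anc, "")[[1]]
  idx <- sample(3000, 30) # ~1% divergence between the two copies
  ch[idx] <- vapply(ch[idx],
                    function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                    "")
  anc2 <- paste(ch, collapse = "")
  gf <- tibble::tibble(id = "c", seq = anc)
  go <- tibble::tibble(id = "c", seq = anc2)
  wf <- extract_window(gf, "c", 1500, 1501, flank = 500)
  wo <- extract_window(go, "c", 1500, 1501, flank = 500)
  # the ortholog span excludes the focal "core" base, as a placed flank
  # pair would
  m12 <- type_modifications(wf, paste0(substr(anc2, 1001, 1500),
                                       substr(anc2, 1502, 2001)), 500, 501)
  m21 <- type_modifications(wo, paste0(substr(anc, 1001, 1500),
                                       substr(anc, 1502, 2001)), 500, 501)
  expect_equal(m12$category, "none")
  expect_equal(m21$category, "none")
})

test_that("modification categories partition the informative loci", {
  grid <- expand.grid(d = c(0L, 5L), i = c(0L, 3L))
  cfgs <- purrr::map_dfr(seq_len(nrow(grid)), function(k) {
    locus_config(sprintf("g%d", k), "A", its_units = 4,
                 deletion_len = grid$d[k], insertion_len = grid$i[k],
                 divergence = 0)
  })
  x <- make_pair(cfgs, seed = 63)
  cmp <- run_compare(x$loci, x$co$focal, x$co$ortholog, x$co$terc,
                     x$co$annotation)
  expect_setequal(cmp$category,
                  c("none", "deletion", "insertion", "deletion_and_insertion"))
  s <- summarize_tercits(x$loci, cmp)
  expect_equal(sum(s$categories$n), s$n_informative)
})
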