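mouse_ann <- terc_annotation(397, template = c(2, 13),
                             domains = list(pseudoknot = c(0, 150),
                                            scaRNA = c(330, 397)))

test_that("map_to_terc labels the dominant domain with first-listed tie-break", {
  h <- fake_hit(0, 43, q_start = 331L, q_end = 374L)
  m <- map_to_terc(h, mouse_ann)
  expect_equal(m$domain_label, "scaRNA")
  expect_equal(c(m$terc_from, m$terc_to), c(332L, 374L))

  none <- map_to_terc(fake_hit(0, 20, q_start = 200L, q_end = 220L), mouse_ann)
  expect_equal(none$domain_label, "other")

  ann2 <- terc_annotation(400, c(2, 13),
                          domains = list(d1 = c(100, 160), d2 = c(160, 260)))
  sixty40 <- map_to_terc(fake_hit(0, 100, q_start = 124L, q_end = 224L), ann2)
  expect_equal(sixty40$domain_label, "d2") # 64 vs 36 bases of overlap
  tie <- map_to_terc(fake_hit(0, 40, q_start = 140L, q_end = 180L), ann2)
  expect_equal(tie$domain_label, "d1") # 20/20 tie -> first listed

  expect_error(map_to_terc(fake_hit(0, 20, q_start = 390L, q_end = 410L),
                           mouse_ann), "outside")
})

test_that("organization classes match the three published arrangements", {
  seqA <- paste0(random_dna(100), random_dna(50), "TCGAC",
                 strrep("TTAGGG", 10), random_dna(100))
  a <- classify_organization(
    dplyr::mutate(fake_hit(100, 150, strand = "-"), arrays = list(
      tibble::tibble(start = 155L, end = 215L, strand = "+", n_units = 10L,
                     interruptions = 0L, its_length = 60L)),
      gap_to_its = 5L, junction_bases = ""), seqA)
  expect_equal(a$organization, "A")
  expect_false(a$head_to_head)
  expect_false(a$nonstandard)

  b <- classify_organization(
    dplyr::mutate(fake_hit(118, 149, strand = "+"), arrays = list(
      tibble::tibble(start = 100L, end = 114L, strand = "+", n_units = 2L,
                     interruptions = 1L, its_length = 14L)),
      gap_to_its = 4L, junction_bases = ""), seqA)
  expect_equal(b$organization, "B")

  cc <- classify_organization(
    dplyr::mutate(fake_hit(100, 111, strand = "+"), arrays = list(
      tibble::tibble(start = c(115L, 127L), end = c(127L, 143L),
                     strand = c("-", "+"), n_units = c(2L, 2L),
                     interruptions = c(0L, 1L), its_length = c(12L, 16L))),
      gap_to_its = 4L, junction_bases = ""), seqA)
  expect_equal(cc$organization, "C")
  expect_true(cc$head_to_head)
  expect_equal(cc$its_length, 28L)
})

test_that("head-to-head arrays with an opposite-orientation fragment stay class A", {
  x <- classify_organization(
    dplyr::mutate(fake_hit(100, 140, strand = "-"), arrays = list(
      tibble::tibble(start = c(145L, 163L), end = c(163L, 181L),
                     strand = c("-", "+"), n_units = c(3L, 3L),
                     interruptions = 0L, its_length = c(18L, 18L))),
      gap_to_its = 5L, junction_bases = ""), random_dna(300))
  expect_equal(x$organization, "A")
  expect_true(x$head_to_head)
})

test_that("classification is invariant under reverse-complementing the locus", {
  withr::local_seed(21)
  co <- simulate_cohort(dplyr::bind_rows(
    locus_config("ra", "A", its_units = 6, divergence = 0),
    locus_config("rb", "B", its_units = 4, divergence = 0),
    locus_config("rcx", "C", its_units = 5, divergence = 0)
  ), seed = 99)
  fwd <- run_find(co$focal, co$terc, co$annotation)
  rev <- run_find(dplyr::mutate(co$focal, seq = revcomp(seq)),
                  co$terc, co$annotation)
  expect_equal(nrow(rev), 3L)
  fo <- fwd[order(fwd$subject_id), ]
  ro <- rev[order(rev$subject_id), ]
  expect_equal(ro$organization, fo$organization)
  expect_equal(ro$head_to_head, fo$head_to_head)
  expect_equal(ro$inframe_ext, fo$inframe_ext)
  expect_equal(ro$its_length, fo$its_length)
  expect_equal(paste(ro$terc_from, ro$terc_to), paste(fo$terc_from, fo$terc_to))
})

test_that("inframe_extension matches its published examples and the phase oracle", {
  expect_equal(inframe_extension("GTT", "AGGGTT"), 3L)
  expect_equal(inframe_extension("CCC", "TTAGGG"), 0L)
  expect_equal(inframe_extension("G", "GTTAGG"), 1L)
  withr::local_seed(6)
  # exhaustive short suffixes x hexamer-phase ITS starts
  bases <- c("A", "C", "G", "T")
  phases <- vapply(0:5, function(p) substr(strrep("TTAGGG", 3), p + 1, p + 6),
                   "")
  for (suf in c("", bases,
                apply(expand.grid(bases, bases), 1, paste, collapse = ""),
                replicate(25, random_dna(3)))) {
    for (its in phases) {
      expect_equal(inframe_extension(suf, its), oracle_inframe(suf, its),
                   info = paste(suf, its))
    }
  }
})

test_that("planted in-frame extensions are recovered across organizations", {
  withr::local_seed(33)
  cfgs <- purrr::map_dfr(c("A", "B", "C"), function(org) {
    purrr::map_dfr(0:3, function(k) {
      locus_config(paste0("if", org, k), org, its_units = 4 + k,
                   inframe_ext = k, divergence = 0)
    })
  })
  co <- simulate_cohort(cfgs, seed = 17)
  loci <- run_find(co$focal, co$terc, co$annotation)
  expect_equal(nrow(loci), nrow(cfgs))
  merged <- merge(as.data.frame(loci), as.data.frame(co$truth),
                  by.x = "subject_id", by.y = "id")
  expect_equal(merged$inframe_ext.x, merged$inframe_ext.y)
  expect_equal(merged$organization.x, merged$organization.y)
})
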