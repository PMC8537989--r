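test_that("scan_telomere_arrays finds tandem runs with strand and units", {
  a <- scan_telomere_arrays("AATTAGGGTTAGGGAA")
  expect_equal(nrow(a), 1L)
  expect_equal(a$strand, "+")
  expect_equal(a$n_units, 2L)
  expect_equal(a$its_length, 12L)
  expect_equal(a$start, 2L)

  # head-to-head: two adjacent stretches on opposite strands never merge
  b <- scan_telomere_arrays("CCCTAACCCTAATTAGGGTTAGGG")
  expect_equal(nrow(b), 2L)
  expect_equal(b$strand, c("-", "+"))
  expect_equal(b$n_units, c(2L, 2L))
  expect_equal(b$start, c(0L, 12L))
})

test_that("bridging merges interrupted arrays up to max_bridge", {
  one <- scan_telomere_arrays("TTAGGGTTTAGGG", max_bridge = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_units, 2L)
  expect_equal(one$interruptions, 1L)
  expect_equal(one$its_length, 13L)

  two <- scan_telomere_arrays("TTAGGGTTTAGGG", max_bridge = 0)
  expect_equal(nrow(two), 2L)
})

test_that("scan equals an exhaustive regex-and-merge oracle on motif-rich sequences", {
  withr::local_seed(314)
  for (rep in 1:50) {
    parts <- character(0)
    for (k in 1:sample(3:8, 1)) {
      parts <- c(parts, random_dna(sample(5:60, 1)),
                 strrep(sample(c("TTAGGG", "CCCTAA"), 1), sample(1:4, 1)),
                 random_dna(sample(0:8, 1)))
    }
    s <- paste(parts, collapse = "")
    mb <- sample(0:8, 1)
    got <- scan_telomere_arrays(s, max_bridge = mb)
    expect_equal(as.data.frame(got), as.data.frame(oracle_scan_arrays(s, mb)))
  }
})

test_that("every reported array is at least one hexamer and strands mirror under revcomp", {
  withr::local_seed(8)
  for (rep in 1:20) {
    s <- paste0(random_dna(200), strrep("TTAGGG", sample(1:5, 1)),
                random_dna(200))
    a <- scan_telomere_arrays(s)
    expect_true(all(a$its_length >= 6))
    expect_true(all(a$n_units * 6 <= a$its_length))
    expect_true(all(a$its_length <= a$n_units * 6 + a$interruptions * 6))
    m <- scan_telomere_arrays(revcomp(s))
    n <- nchar(s)
    expect_setequal(paste(a$start, a$end, a$strand),
                    paste(n - m$end, n - m$start,
                          ifelse(m$strand == "+", "-", "+")))
  }
})

test_that("attach_its pairs hits with arrays inside the adjacency window", {
  arrays <- tibble::tibble(start = 106L, end = 166L, strand = "+",
                           n_units = 10L, interruptions = 0L,
                           its_length = 60L)
  seq <- strrep("A", 300)
  cand <- attach_its(fake_hit(60, 100), arrays, seq, adjacency_window = 30)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$gap_to_its, 6L)

  far <- dplyr::mutate(arrays, start = 200L, end = 260L)
  expect_equal(nrow(attach_its(fake_hit(60, 100), far, seq, 30)), 0L)
})

test_that("a hit flanked by two arrays yields one head-to-head candidate", {
  arrays <- tibble::tibble(start = c(30L, 106L), end = c(54L, 166L),
                           strand = c("-", "+"), n_units = c(4L, 10L),
                           interruptions = 0L, its_length = c(24L, 60L))
  cand <- attach_its(fake_hit(60, 100), arrays, strrep("A", 300), 30)
  expect_equal(nrow(cand), 1L)
  expect_equal(nrow(cand$arrays[[1]]), 2L)
})

test_that("template-only hits and template arrays inside a hit are not candidates", {
  arrays <- tibble::tibble(start = 106L, end = 166L, strand = "+",
                           n_units = 10L, interruptions = 0L,
                           its_length = 60L)
  # hit query interval fully inside the template region: excluded
  tpl_hit <- fake_hit(60, 100, q_start = 46L, q_end = 56L)
  expect_equal(nrow(attach_its(tpl_hit, arrays, strrep("A", 300), 30,
                               template_interval = c(45, 56))), 0L)
  # array contained inside the hit's subject interval (pseudogene
  # template) is not flanking evidence
  inner <- tibble::tibble(start = 70L, end = 76L, strand = "-",
                          n_units = 1L, interruptions = 0L, its_length = 6L)
  expect_equal(nrow(attach_its(fake_hit(20, 300), inner, strrep("A", 400),
                               30)), 0L)
})
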