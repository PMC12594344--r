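mkblock <- function(rs, re, ds, de, strand = "+", raln = NULL,
                    daln = NULL) {
  len <- re - rs + 1L
  if (is.null(raln)) raln <- strrep("A", len)
  if (is.null(daln)) daln <- raln
  data.frame(recipient_start = rs, recipient_end = re, donor_start = ds,
             donor_end = de, strand = strand, recipient_aln = raln,
             donor_aln = daln, stringsAsFactors = FALSE)
}

test_that("XMFA blocks parse with header coordinates and strand", {
  path <- tempfile(fileext = ".xmfa")
  write_xmfa_fixture(path, list(
    list(seqs = list(
      list(id = "1", start = 101, end = 110, strand = "+",
           comment = "recipient.fa", seq = "ACGTACGTAC"),
      list(id = "2", start = 201, end = 210, strand = "+",
           comment = "donor.fa", seq = "ACGTACGTAC"))),
    list(seqs = list(
      list(id = "1", start = 300, end = 309, strand = "+",
           comment = "recipient.fa", seq = "TTTTTTTTTT"),
      list(id = "2", start = 400, end = 409, strand = "-",
           comment = "donor.fa", seq = "TTTTTTTTTT")))))
  b <- read_xmfa(path)
  expect_equal(nrow(b), 2L)
  expect_equal(b$recipient_start, c(101L, 300L))
  expect_equal(b$donor_start, c(201L, 400L))
  expect_equal(b$strand, c("+", "-"))
})

test_that("XMFA edge cases: empty file, one-genome block, bad header", {
  empty <- tempfile(fileext = ".xmfa")
  writeLines(character(0), empty)
  expect_equal(nrow(read_xmfa(empty)), 0L)
  one <- tempfile(fileext = ".xmfa")
  writeLines(c("> 2:10-19 + donor.fa", "ACGTACGTAC", "="), one)
  expect_warning(b <- read_xmfa(one), "skipped")
  expect_equal(nrow(b), 0L)
  bad <- tempfile(fileext = ".xmfa")
  writeLines(c("> nonsense header", "ACGT", "="), bad)
  expect_error(read_xmfa(bad), "malformed")
})

test_that("length filter drops blocks shorter than 110 bp, boundary inclusive", {
  b <- rbind(mkblock(1, 109, 1, 109),      # 109 bp -> dropped
             mkblock(200, 309, 200, 309),  # 110 bp -> retained
             mkblock(400, 600, 400, 600))
  f <- filter_synteny_blocks(b)
  expect_equal(f$recipient_start, c(200, 400))
})

test_that("distance filter drops blocks jumping more than 100 kb on the donor", {
  b <- rbind(mkblock(1, 1000, 1, 1000),
             mkblock(2000, 3000, 151000, 152000),   # 150 kb jump -> dropped
             mkblock(4000, 5000, 2000, 3000))       # close to block 1 -> kept
  f <- filter_synteny_blocks(b)
  expect_equal(f$recipient_start, c(1, 4000))
  # jump of exactly 100 kb is allowed ("more than 100 kb" is strict)
  b2 <- rbind(mkblock(1, 1000, 1, 1000),
              mkblock(2000, 3000, 101000, 102000))
  expect_equal(nrow(filter_synteny_blocks(b2)), 2L)
})

test_that("strand filter keeps the majority orientation", {
  b <- rbind(mkblock(1, 200, 1, 200, "+"),
             mkblock(300, 500, 300, 500, "+"),
             mkblock(600, 800, 600, 800, "-"))
  f <- filter_synteny_blocks(b)
  expect_true(all(f$strand == "+"))
  expect_equal(nrow(f), 2L)
  # all-plus input is untouched
  b3 <- b[b$strand == "+", ]
  expect_equal(nrow(filter_synteny_blocks(b3)), 2L)
})

test_that("synteny filtering is idempotent", {
  set.seed(5)
  rs <- sort(sample.int(1e6, 20))
  b <- do.call(rbind, lapply(rs, function(s) {
    len <- sample(c(50, 150, 5000), 1)
    mkblock(s, s + len - 1, s + sample(c(0, 2e5), 1),
            s + len - 1, sample(c("+", "-"), 1, prob = c(.8, .2)))
  }))
  f1 <- filter_synteny_blocks(b)
  f2 <- filter_synteny_blocks(f1)
  expect_identical(f1, f2)
})

test_that("site extraction skips gaps and records both coordinate frames", {
  # one block: 3-bp gap in the donor and 2 substitutions
  b <- mkblock(101, 112, 501, 509, "+",
               raln = "ACGTACGTACGT",
               daln = "ACTTA---ACGA")
  s <- extract_polymorphic_sites(b)
  expect_equal(nrow(s), 2L)
  expect_equal(s$recipient_pos, c(103L, 112L))
  expect_equal(s$donor_pos, c(503L, 509L))
  expect_equal(s$recipient_allele, c("G", "T"))
  expect_equal(s$donor_allele, c("T", "A"))
  # identical blocks yield nothing
  expect_equal(nrow(extract_polymorphic_sites(
    mkblock(1, 10, 1, 10))), 0L)
})

test_that("site extraction on the truth alignment recovers truth sites", {
  acc <- data.frame(genome = c("donor", "recipient"),
                    length = c(2000, 1500), count = c(2, 1))
  pair <- small_pair(8e4, divergence = 0.015, seed = 21, accessory = acc)
  got <- extract_polymorphic_sites(truth_blocks(pair))
  ts <- pair$truth_sites
  expect_equal(got$recipient_pos, ts$recipient_pos)
  expect_equal(got$donor_pos, ts$donor_pos)
  expect_equal(got$recipient_allele, ts$recipient_allele)
  expect_equal(got$donor_allele, ts$donor_allele)
})

test_that("homology runs split at substitutions and shrink with k", {
  b <- mkblock(1, 1000, 1, 1000, raln = strrep("A", 1000))
  h <- homology_opportunity_density(b, k = 20, bin = 1e5,
                                    genome_length = 1000)
  expect_equal(h$count_k20[1], 1L)
  # single substitution at position 500 splits the run in two
  daln <- paste0(strrep("A", 499), "C", strrep("A", 500))
  b2 <- mkblock(1, 1000, 1, 1000, raln = strrep("A", 1000), daln = daln)
  h2 <- homology_opportunity_density(b2, k = 20, bin = 1e5,
                                     genome_length = 1000)
  expect_equal(h2$count_k20[1], 2L)
  expect_error(homology_opportunity_density(b, k = 0,
                                            genome_length = 1000), "k")
})

test_that("higher identity thresholds never gain opportunities", {
  pair <- small_pair(2e5, divergence = 0.01, seed = 5)
  h <- homology_opportunity_density(pair)
  expect_true(all(h$count_k27 <= h$count_k20))
  expect_true(all(h$count_k20 > 0))
  # direct enumeration oracle on one bin: gaps between consecutive sites
  gaps <- diff(c(0L, pair$truth_sites$recipient_pos,
                 nchar(pair$recipient_seq) + 1L)) - 1L
  expect_equal(sum(h$count_k20), sum(gaps >= 20))
  expect_equal(sum(h$count_k27), sum(gaps >= 27))
})
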