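test_that("a clone with no extra fragments has exactly the marker tract", {
  pair <- small_pair(5e4, seed = 4)
  rec <- simulate_recombinant(pair, 2.5e4,
                              fragment_dist("fixed", length = 1e4),
                              extra_count = 0L, seed = 1)
  expect_equal(nrow(rec$fragments), 1L)
  expect_true(rec$fragments$contains_marker)
  expect_equal(rec$fragments$end - rec$fragments$start, 1e4)
  expect_true(rec$fragments$start <= 2.5e4 &&
                2.5e4 < rec$fragments$end)
})

test_that("recombinant carries donor alleles inside tracts only", {
  pair <- small_pair(1e5, seed = 42)
  rec <- simulate_recombinant(
    pair, 5e4, fragment_dist("fixed", length = 2e4),
    extra_count = 2L,
    extra_dist = fragment_dist("log_uniform", low = 3e3, high = 8e3),
    placement_window = 4e4, seed = 5)
  ts <- pair$truth_sites
  inside <- sites_inside(ts, rec$fragments)
  got <- substring(rec$sequence, ts$recipient_pos, ts$recipient_pos)
  expect_true(all(got[inside] == ts$donor_allele[inside]))
  expect_true(all(got[!inside] == ts$recipient_allele[!inside]))
  # substitution-only model conserves length
  expect_equal(nchar(rec$sequence), nchar(pair$recipient_seq))
  # exactly one merged fragment contains the marker
  expect_equal(sum(rec$fragments$contains_marker), 1L)
  expect_true(all(rec$fragments$start < rec$fragments$end))
})

test_that("marker inside an accessory segment is rejected", {
  acc <- data.frame(genome = "recipient", length = 5000, count = 1)
  pair <- small_pair(3e4, seed = 9, accessory = acc)
  acc_iv <- hfrmap:::.accessory_intervals(pair$recipient_insertions)
  bad <- acc_iv$start[1] + 10L
  expect_error(
    simulate_recombinant(pair, bad, fragment_dist("fixed", length = 1e3),
                         extra_count = 0L),
    "accessory")
})

test_that("no fragment covers a counter-selected position", {
  pair <- small_pair(1e5, seed = 12)
  for (s in 1:5) {
    rec <- simulate_recombinant(
      pair, 5e4, fragment_dist("log_uniform", low = 1e4, high = 6e4),
      extra_count = list(family = "poisson", lambda = 2),
      extra_dist = fragment_dist("log_uniform", low = 3e3, high = 2e4),
      forbidden = 7e4, seed = s)
    expect_false(any(rec$fragments$start <= 7e4 &
                       7e4 < rec$fragments$end))
    expect_equal(sum(rec$fragments$contains_marker), 1L)
  }
})

test_that("simulated reads are exact substrings when error-free", {
  pair <- small_pair(3e4, seed = 2)
  rr <- simulate_reads(pair$recipient_seq, depth = 3, seed = 5)
  expect_equal(nrow(rr), round(3 * 3e4 / 150))
  expect_true(all(substring(pair$recipient_seq, rr$true_pos,
                            rr$true_pos + 149) == rr$seq))
})

test_that("read count follows the coverage formula", {
  seqc <- strrep("ACGT", 25000)
  rr <- simulate_reads(seqc, depth = 10, read_length = 150, seed = 1)
  expect_equal(nrow(rr), 6667)  # round(10 * 1e5 / 150)
  expect_error(simulate_reads("", depth = 1), "empty")
  expect_error(simulate_reads("ACGT", depth = 1, read_length = 10),
               "read_length")
})

test_that("substitution errors appear at the configured rate", {
  pair <- small_pair(5e4, seed = 6)
  rr <- simulate_reads(pair$recipient_seq, depth = 5, error_rate = 0.01,
                       seed = 7)
  n_bases <- nrow(rr) * 150
  mism <- sum(mapply(function(s, p) {
    sum(strsplit(s, "")[[1]] !=
          strsplit(substring(pair$recipient_seq, p, p + 149), "")[[1]])
  }, rr$seq, rr$true_pos))
  se <- sqrt(n_bases * 0.01 * 0.99)
  expect_lt(abs(mism - n_bases * 0.01), 3 * se)
})

test_that("pool read counts follow the clone weights", {
  pair <- small_pair(2e4, seed = 3)
  mk <- function(id, seed) simulate_recombinant(
    pair, 1e4, fragment_dist("fixed", length = 5e3), extra_count = 0L,
    clone_id = id, seed = seed)
  c1 <- mk("c1", 1); c2 <- mk("c2", 2)
  # degenerate pool: single clone takes every read
  p1 <- build_pool(list(c1), total_depth = 5, seed = 9)
  expect_equal(unique(p1$reads$clone_id), "c1")
  expect_equal(p1$manifest$n_reads, nrow(p1$reads))
  # zero weight excludes a clone entirely
  p0 <- build_pool(list(c1, c2), weights = c(1, 0), total_depth = 5,
                   seed = 9)
  expect_false("c2" %in% p0$reads$clone_id)
  # equal weights balance within 3 multinomial standard errors
  pq <- build_pool(list(c1, c2), weights = c(1, 1), total_depth = 60,
                   seed = 10)
  n <- sum(pq$manifest$n_reads)
  se <- sqrt(n * 0.5 * 0.5)
  expect_lt(abs(pq$manifest$n_reads[1] - n / 2), 3 * se)
  expect_error(build_pool(list(c1), weights = 0, total_depth = 1),
               "weights")
})

test_that("clone simulation is a pure function of its seed", {
  pair <- small_pair(3e4, seed = 1)
  args <- list(pair, 1.5e4, fragment_dist("fixed", length = 8e3),
               extra_count = 1L,
               extra_dist = fragment_dist("fixed", length = 2e3),
               seed = 77)
  r1 <- do.call(simulate_recombinant, args)
  r2 <- do.call(simulate_recombinant, args)
  expect_identical(r1$sequence, r2$sequence)
  expect_identical(r1$fragments, r2$fragments)
})
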