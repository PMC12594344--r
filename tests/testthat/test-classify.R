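test_that("error-free reads are labeled by their region of origin", {
  pair <- small_pair(1e5, seed = 42)
  fx <- small_clone(pair, depth = 8, error_rate = 0, seed = 7)
  cls <- classify_builtin(fx$reads, pair)
  lab <- cls$labels
  fr <- fx$rec$fragments
  # every read gets exactly one category; counts sum to total reads
  expect_equal(sum(table(lab$category)), nrow(fx$reads))
  fully_in <- rep(FALSE, nrow(lab))
  outside <- rep(TRUE, nrow(lab))
  for (i in seq_len(nrow(fr))) {
    fully_in <- fully_in | (lab$recipient_pos >= fr$start[i] &
                              lab$recipient_pos + 150 <= fr$end[i])
    outside <- outside & (lab$recipient_pos + 150 <= fr$start[i] |
                            lab$recipient_pos >= fr$end[i])
  }
  expect_true(all(lab$category[fully_in] %in%
                    c("DONOR_BETTER", "TIE")))
  expect_true(all(lab$category[outside] %in%
                    c("RECIPIENT_BETTER", "TIE")))
  # TIE reads cover no site (margin NA) or are balanced
  ties <- lab$category == "TIE"
  expect_true(all(is.na(lab$score_margin[ties]) |
                    lab$score_margin[ties] == 0))
  # placements agree with the simulator's recorded positions
  expect_equal(lab$recipient_pos, fx$reads$true_pos)
})

test_that("an empty site list makes every placed read uninformative", {
  pair <- small_pair(2e4, divergence = 0, seed = 3)
  rr <- simulate_reads(pair$recipient_seq, depth = 2, seed = 4)
  cls <- classify_builtin(rr, pair)
  expect_true(all(cls$labels$category == "TIE"))
})

test_that("accessory reads get single-genome categories", {
  acc <- data.frame(genome = c("donor", "recipient"),
                    length = c(5000, 5000), count = c(1, 1))
  pair <- small_pair(5e4, seed = 15, accessory = acc)
  # reads drawn from the raw donor genome: accessory interior ones
  rr_d <- simulate_reads(pair$donor_seq, depth = 5, seed = 6)
  cls_d <- classify_builtin(rr_d, pair)
  dacc <- hfrmap:::.accessory_intervals(pair$donor_insertions)
  in_acc <- rr_d$true_pos >= dacc$start[1] &
    rr_d$true_pos + 150 <= dacc$end[1]
  expect_true(any(in_acc))
  expect_true(all(cls_d$labels$category[in_acc] == "DONOR_ONLY"))
  rr_r <- simulate_reads(pair$recipient_seq, depth = 5, seed = 7)
  cls_r <- classify_builtin(rr_r, pair)
  racc <- hfrmap:::.accessory_intervals(pair$recipient_insertions)
  in_racc <- rr_r$true_pos >= racc$start[1] &
    rr_r$true_pos + 150 <= racc$end[1]
  expect_true(all(cls_r$labels$category[in_racc] == "RECIPIENT_ONLY"))
})

test_that("swapping the genomes swaps the labels and frequencies", {
  pair <- small_pair(6e4, seed = 23)
  fx <- small_clone(pair, marker = 3e4, depth = 6, error_rate = 0,
                    seed = 11)
  swapped <- pair
  swapped$donor_seq <- pair$recipient_seq
  swapped$recipient_seq <- pair$donor_seq
  swapped$donor_insertions <- pair$recipient_insertions
  swapped$recipient_insertions <- pair$donor_insertions
  ts <- pair$truth_sites
  swapped$truth_sites <- data.frame(
    core_pos = ts$core_pos, recipient_pos = ts$donor_pos,
    donor_pos = ts$recipient_pos, recipient_allele = ts$donor_allele,
    donor_allele = ts$recipient_allele, stringsAsFactors = FALSE)
  a <- classify_builtin(fx$reads, pair)
  b <- classify_builtin(fx$reads, swapped)
  swap <- c(DONOR_BETTER = "RECIPIENT_BETTER",
            RECIPIENT_BETTER = "DONOR_BETTER", TIE = "TIE",
            DONOR_ONLY = "RECIPIENT_ONLY",
            RECIPIENT_ONLY = "DONOR_ONLY", UNMAPPED = "UNMAPPED")
  expect_equal(unname(swap[a$labels$category]), b$labels$category)
  fa <- site_frequencies(a, pair$truth_sites)
  fb <- site_frequencies(b, swapped$truth_sites)
  cov <- fa$covered & fb$covered
  expect_equal(fa$donor_frequency[cov], 1 - fb$donor_frequency[cov])
})

test_that("site frequencies are 1 inside donor tracts and 0 outside", {
  pair <- small_pair(1e5, seed = 42)
  fx <- small_clone(pair, depth = 10, error_rate = 0, seed = 7)
  cls <- classify_builtin(fx$reads, pair)
  fr <- site_frequencies(cls, pair$truth_sites)
  inside <- sites_inside(pair$truth_sites, fx$rec$fragments)
  cov <- fr$covered
  expect_true(all(fr$donor_frequency[inside & cov] == 1))
  expect_true(all(fr$donor_frequency[!inside & cov] == 0))
  # counts conserve observations
  expect_equal(sum(fr$donor_count) + sum(fr$recipient_count),
               sum(cls$observations$is_donor | cls$observations$is_recipient))
})

test_that("a balanced two-clone pool gives half-frequencies at private sites", {
  pair <- small_pair(5e4, seed = 31)
  c1 <- simulate_recombinant(pair, 2.5e4,
                             fragment_dist("fixed", length = 2e4),
                             extra_count = 0L, clone_id = "c1", seed = 1)
  c2 <- simulate_recombinant(pair, 2.5e4,
                             fragment_dist("fixed", length = 500),
                             extra_count = 0L, clone_id = "c2", seed = 2)
  pool <- build_pool(list(c1, c2), weights = c(1, 1), total_depth = 60,
                     seed = 3)
  cls <- classify_builtin(pool$reads, pair)
  fr <- site_frequencies(cls, pair$truth_sites)
  ts <- pair$truth_sites
  only1 <- sites_inside(ts, c1$fragments) & !sites_inside(ts, c2$fragments)
  sel <- only1 & fr$covered & (fr$donor_count + fr$recipient_count) >= 20
  expect_true(sum(sel) > 50)
  p <- fr$donor_frequency[sel]
  ntot <- fr$donor_count[sel] + fr$recipient_count[sel]
  within <- abs(p - 0.5) <= 3 * sqrt(0.25 / ntot)
  expect_gt(mean(within), 0.95)
})

test_that("SAM score comparison reproduces the category definitions", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:donor|chr\tLN:10000",
    "@SQ\tSN:recipient|chr\tLN:10000",
    paste("r1", 0, "donor|chr", 100, 60, "10M", "*", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", "AS:i:20", sep = "\t"),
    paste("r1", 256, "recipient|chr", 100, 60, "10M", "*", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", "AS:i:10", sep = "\t"),
    paste("r2", 0, "recipient|chr", 500, 60, "10M", "*", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", "AS:i:20", sep = "\t"),
    paste("r2", 256, "donor|chr", 600, 60, "10M", "*", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", "AS:i:20", sep = "\t"),
    paste("r3", 0, "donor|chr", 900, 60, "10M", "*", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", "AS:i:20", sep = "\t"),
    paste("r4", 0, "recipient|chr", 700, 60, "10M", "*", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", "AS:i:15", sep = "\t"),
    paste("r4", 256, "donor|chr", 800, 60, "10M", "*", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", "AS:i:5", sep = "\t")), sam)
  lab <- classify_from_sam(sam)
  got <- setNames(lab$category, lab$read_id)
  expect_equal(got[["r1"]], "DONOR_BETTER")
  expect_equal(got[["r2"]], "TIE")
  expect_equal(got[["r3"]], "DONOR_ONLY")
  expect_equal(got[["r4"]], "RECIPIENT_BETTER")
  expect_equal(lab$score_margin[lab$read_id == "r1"], 10)
  expect_equal(lab$recipient_pos[lab$read_id == "r4"], 700)
})

test_that("SAM files without alignment scores are refused by name", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:donor|chr\tLN:10000",
    "@SQ\tSN:recipient|chr\tLN:10000",
    paste("r1", 0, "donor|chr", 100, 60, "10M", "*", 0, 0,
          "ACGTACGTAC", "IIIIIIIIII", sep = "\t")), sam)
  expect_error(classify_from_sam(sam), "AS")
})
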