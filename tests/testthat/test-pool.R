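mklab <- function(pos, cat) {
  data.frame(read_id = sprintf("r%d", seq_along(pos)),
             recipient_pos = pos, category = cat,
             stringsAsFactors = FALSE)
}

test_that("binned profiles count informative reads and tile the genome", {
  lab <- mklab(c(100, 200, 1500, 1600, 2500, 50),
               c("DONOR_BETTER", "RECIPIENT_BETTER", "DONOR_BETTER",
                 "DONOR_BETTER", "RECIPIENT_BETTER", "TIE"))
  pr <- bin_pool(lab, genome_length = 3000, bin_size = 1000)
  expect_equal(nrow(pr), 3L)
  expect_equal(pr$donor_count, c(1L, 2L, 0L))
  expect_equal(pr$recipient_count, c(1L, 0L, 1L))
  # equal counts -> log-ratio 0; empty bins flagged with 0 log-ratio
  expect_equal(pr$log_ratio[1], 0)
  expect_false(pr$no_data[1])
  lab0 <- mklab(c(100), "TIE")
  pr0 <- bin_pool(lab0, 3000, 1000)
  expect_true(all(pr0$no_data))
  expect_true(all(pr0$log_ratio == 0))
  expect_true(all(is.na(pr0$donor_fraction)))
  # conservation: totals equal the number of informative labels
  expect_equal(sum(pr$donor_count) + sum(pr$recipient_count), 5L)
  expect_error(bin_pool(lab, 3000, bin_size = 0), "bin_size")
})

test_that("peak localization picks the argmax bin and flags ties", {
  lab <- mklab(c(rep(1500, 10), rep(2500, 4), rep(3500, 2)),
               rep("DONOR_BETTER", 16))
  lab <- rbind(lab, mklab(rep(c(1500, 2500, 3500), c(1, 4, 8)),
                          rep("RECIPIENT_BETTER", 13)))
  pr <- bin_pool(lab, 4000, 1000)
  call <- locate_selected_locus(pr)
  expect_equal(call$peak_bin_start, 1001L)
  expect_false(call$tie)
  expect_true(call$interval[1] <= 1001 && call$interval[2] >= 2001)
  # flat informative profile -> tie flagged, leftmost reported
  flat <- mklab(c(500, 1500, 2500), rep("DONOR_BETTER", 3))
  cf <- locate_selected_locus(bin_pool(flat, 3000, 1000))
  expect_true(cf$tie)
  expect_equal(cf$peak_bin_start, 1L)
  # all-empty profile is an error
  expect_error(locate_selected_locus(
    bin_pool(mklab(100, "TIE"), 1000, 1000)), "informative")
})

test_that("peak localization is equivariant under coordinate shift", {
  set.seed(8)
  pos <- sample.int(50000, 400)
  cat <- ifelse(abs(pos - 20000) < 3000, "DONOR_BETTER",
                sample(c("DONOR_BETTER", "RECIPIENT_BETTER"), 400,
                       replace = TRUE, prob = c(.2, .8)))
  lab <- mklab(pos, cat)
  shift <- 10000L
  lab2 <- transform(lab, recipient_pos = recipient_pos + shift)
  c1 <- locate_selected_locus(bin_pool(lab, 50000, 1000))
  c2 <- locate_selected_locus(bin_pool(lab2, 60000, 1000))
  expect_equal(c2$peak_position - c1$peak_position, shift)
})

test_that("decay distance grows with fragment length", {
  pair <- small_pair(2e5, seed = 14)
  mkpool <- function(L, seed) {
    clones <- lapply(1:25, function(i) simulate_recombinant(
      pair, 1e5, fragment_dist("fixed", length = L), extra_count = 0L,
      clone_id = paste0("c", i), seed = seed + i))
    build_pool(clones, total_depth = 40, seed = seed)
  }
  prof <- function(pool) {
    cls <- classify_builtin(pool$reads, pair)
    bin_pool(cls$labels, 2e5)
  }
  d_short <- decay_profile(prof(mkpool(2e4, 1)), 1e5)
  d_long <- decay_profile(prof(mkpool(8e4, 100)), 1e5)
  expect_lt(d_short$half_decay_right, d_long$half_decay_right)
  expect_lt(d_short$half_decay_left, d_long$half_decay_left)
  # donor fraction reaches ~0 beyond the fixed fragment length
  tab <- d_short$table
  far <- !is.na(tab$donor_fraction) & abs(tab$distance) > 2.2e4
  expect_lt(max(tab$donor_fraction[far]), 0.05)
  # symmetric simulation: left and right half-decay within sampling error
  expect_lt(abs(d_long$half_decay_left - d_long$half_decay_right), 2e4)
})

test_that("a counter-selected site carves a dip at its position", {
  pair <- small_pair(2e5, seed = 33)
  forb <- 1.3e5
  clones <- lapply(1:30, function(i) simulate_recombinant(
    pair, 1e5, fragment_dist("log_uniform", low = 2e4, high = 1e5),
    extra_count = list(family = "poisson", lambda = 2),
    extra_dist = fragment_dist("log_uniform", low = 5e3, high = 4e4),
    forbidden = forb, clone_id = paste0("c", i), seed = 500 + i))
  pool <- build_pool(clones, total_depth = 50, error_rate = 1e-3,
                     seed = 6)
  cls <- classify_builtin(pool$reads, pair)
  pr <- bin_pool(cls$labels, 2e5)
  dip <- locate_counterselected_site(pr, halfwidth = 5e4)
  expect_lte(abs(dip$dip_position - forb), 2000)
})

test_that("insertion density fold-changes follow their definitions", {
  glen <- 4e6
  bin <- 250000
  dom <- data.frame(name = c("Ter", "Ori"),
                    start = c(1500001, 3500001),
                    end = c(2500001, 3900001))
  # perfectly uniform: one site per 10 kb, constant counts
  tab_u <- data.frame(position = seq(5000, glen, by = 10000), count = 5)
  idn <- insertion_density(tab_u, dom, glen, bin)
  expect_true(all(abs(idn$bins$log2fc_density) < 1e-9))
  expect_true(all(abs(idn$bins$log2fc_coverage) < 1e-9))
  # doubling site density outside Ter gives +1 there on the density metric
  ter_lo <- 1500000; ter_hi <- 2500000
  extra <- seq(10000, glen, by = 10000)
  extra <- extra[extra <= ter_lo | extra > ter_hi]
  tab_2x <- rbind(tab_u, data.frame(position = extra, count = 5))
  idn2 <- insertion_density(tab_2x, dom, glen, bin)
  out <- !idn2$bins$in_ter
  expect_true(all(abs(idn2$bins$log2fc_density[out] - 1) < 0.1))
  expect_true(all(abs(idn2$bins$log2fc_density[!out]) < 0.1))
  # validation
  expect_error(insertion_density(tab_u,
                                 data.frame(name = "Ori", start = 1,
                                            end = 100), glen), "Ter")
  expect_error(insertion_density(data.frame(position = 10, count = 0),
                                 dom, glen), "counts")
})

test_that("coverage bias amplifies density bias in the two metrics", {
  glen <- 4e6
  dom <- data.frame(name = c("Ter"), start = c(1500001),
                    end = c(2500001))
  set.seed(2)
  pos <- seq(2000, glen, by = 4000)
  in_ter <- pos > 1500000 & pos <= 2500000
  # deplete sites inside Ter and give the remaining ones lower counts
  keep <- !in_ter | (runif(length(pos)) < 0.5)
  pos <- pos[keep]
  in_ter <- in_ter[keep]
  counts <- ifelse(in_ter, 4, 12)
  idn <- insertion_density(data.frame(position = pos, count = counts),
                           dom, glen)
  out <- !idn$bins$in_ter
  expect_gt(mean(idn$bins$log2fc_coverage[out]),
            mean(idn$bins$log2fc_density[out]))
  expect_gt(idn$correlation, 0.5)
})
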