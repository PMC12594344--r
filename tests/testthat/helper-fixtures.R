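# Shared fixture builders. Unit tests use small genomes (50-200 kb) so the
# default suite stays fast; the acceptance tests build the full-size
# fixtures themselves.

small_pair <- function(len = 1e5, divergence = 0.01, seed = 42,
                       accessory = NULL) {
  generate_genome_pair(genome_pair_config(len, divergence,
                                          accessory_segments = accessory,
                                          seed = seed))
}

# One clone with a marker fragment and two extra fragments, plus reads.
small_clone <- function(pair, marker = 5e4, depth = 10, error_rate = 0,
                        seed = 7) {
  rec <- simulate_recombinant(
    pair, marker,
    marker_dist = fragment_dist("fixed", length = 2e4),
    extra_count = 2L,
    extra_dist = fragment_dist("log_uniform", low = 3e3, high = 8e3),
    placement_window = 4e4,
    clone_id = "fix", seed = seed)
  reads <- simulate_reads(rec$sequence, depth = depth,
                          error_rate = error_rate, seed = seed + 1L)
  list(rec = rec, reads = reads)
}

# Sites covered by a truth fragment set (merged, recipient coordinates).
sites_inside <- function(sites, fragments) {
  inside <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(fragments))) {
    inside <- inside | (sites$recipient_pos >= fragments$start[i] &
                          sites$recipient_pos < fragments$end[i])
  }
  inside
}

# Gap between the truth sites flanking a boundary coordinate: the
# resolution limit of site-based tract detection at that point.
local_site_gap <- function(site_pos, boundary) {
  i <- findInterval(boundary - 1e-9, site_pos)
  lo <- if (i >= 1) site_pos[i] else 1
  hi <- if (i < length(site_pos)) site_pos[i + 1] else max(site_pos)
  max(hi - lo, 1)
}

write_xmfa_fixture <- function(path, blocks) {
  lines <- character(0)
  for (b in blocks) {
    for (s in b$seqs) {
      lines <- c(lines, sprintf("> %s:%d-%d %s %s", s$id, s$start, s$end,
                                s$strand, s$comment), s$seq)
    }
    lines <- c(lines, "=")
  }
  writeLines(lines, path)
  path
}
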