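#' Read a two-genome XMFA core alignment
#'
#' Parses the XMFA produced by whole-genome core aligners: alignment blocks
#' separated by `=` lines, each sequence introduced by a header of the form
#' `> seqid:start-end strand [comment]` with 1-based inclusive coordinates.
#' Sequence id 1 is taken as the recipient (the alignment reference),
#' id 2 as the donor.
#'
#' @param path XMFA file.
#' @return A `data.frame` of synteny blocks ordered by recipient start:
#'   columns `recipient_start`, `recipient_end`, `donor_start`,
#'   `donor_end` (1-based inclusive), `strand` (donor orientation relative
#'   to the recipient), `recipient_aln`, `donor_aln` (aligned sequences,
#'   gaps as `-`). Blocks missing either genome are skipped with a
#'   warning.
#' @export
read_xmfa <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- list()
  seq_open <- NULL
  flush_seq <- function() {
    if (!is.null(seq_open)) {
      cur[[seq_open$id]] <<- c(seq_open,
                               list(seq = paste(seq_buf, collapse = "")))
    }
    seq_open <<- NULL
    seq_buf <<- character(0)
  }
  seq_buf <- character(0)
  flush_block <- function() {
    flush_seq()
    if (length(cur) > 0L) blocks[[length(blocks) + 1L]] <<- cur
    cur <<- list()
  }
  for (ln in lines) {
    if (grepl("^=", ln)) {
      flush_block()
    } else if (grepl("^>", ln)) {
      flush_seq()
      m <- regmatches(ln, regexec(
        "^>\\s*([^:\\s]+):(\\d+)-(\\d+)\\s+([+-])", ln))[[1]]
      if (length(m) == 0L)
        stopf("malformed XMFA header: %s", ln)
      seq_open <- list(id = m[2], start = as.integer(m[3]),
                       end = as.integer(m[4]), strand = m[5])
    } else if (nzchar(trimws(ln))) {
      seq_buf <- c(seq_buf, trimws(ln))
    }
  }
  flush_block()

  keep <- vapply(blocks, function(b) all(c("1", "2") %in% names(b)),
                 logical(1))
  if (any(!keep))
    warning(sum(!keep), " block(s) missing one genome were skipped")
  blocks <- blocks[keep]
  if (length(blocks) == 0L) {
    return(data.frame(recipient_start = integer(0),
                      recipient_end = integer(0),
                      donor_start = integer(0), donor_end = integer(0),
                      strand = character(0), recipient_aln = character(0),
                      donor_aln = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(blocks, function(b) {
    # relative orientation of the donor with respect to the recipient
    rel <- if (b[["1"]]$strand == b[["2"]]$strand) "+" else "-"
    data.frame(recipient_start = b[["1"]]$start,
               recipient_end = b[["1"]]$end,
               donor_start = b[["2"]]$start, donor_end = b[["2"]]$end,
               strand = rel,
               recipient_aln = toupper(b[["1"]]$seq),
               donor_aln = toupper(b[["2"]]$seq),
               stringsAsFactors = FALSE)
  }))
  df <- df[order(df$recipient_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Filter synteny blocks before site extraction
#'
#' Removes alignment blocks that tend to reflect spurious homology or
#' synteny breaks rather than genuine core-genome colinearity:
#' \itemize{
#'   \item blocks whose recipient span is shorter than `min_length`
#'     (default 110 bp; spurious homologies in accessory genes),
#'   \item blocks on the minority donor orientation (translocations /
#'     inversions),
#'   \item blocks whose donor coordinates jump more than `max_jump`
#'     (default 100 kb) from the previous retained block, scanning in
#'     recipient order (long-range rearrangements).
#' }
#' Filters are applied in the order given by `order`; the result is
#' idempotent.
#'
#' @param blocks Block `data.frame` from [read_xmfa()] (or
#'   [truth_blocks()]).
#' @param min_length Minimum recipient-span length retained (bp).
#' @param max_jump Maximum allowed donor-coordinate gap between
#'   consecutive retained blocks (bp).
#' @param order Character vector permuting
#'   `c("length", "strand", "distance")`.
#' @return The retained blocks, same columns, recipient order.
#' @export
filter_synteny_blocks <- function(blocks, min_length = 110L,
                                  max_jump = 1e5,
                                  order = c("length", "strand",
                                            "distance")) {
  stopifnot(all(order %in% c("length", "strand", "distance")))
  b <- blocks[order(blocks$recipient_start), , drop = FALSE]
  for (step in order) {
    if (nrow(b) == 0L) break
    b <- switch(step,
      length = b[(b$recipient_end - b$recipient_start + 1L) >= min_length, ,
                 drop = FALSE],
      strand = {
        tab <- table(b$strand)
        majority <- names(tab)[which.max(tab)]
        b[b$strand == majority, , drop = FALSE]
      },
      distance = {
        keep <- logical(nrow(b))
        prev_end <- NA_real_
        for (i in seq_len(nrow(b))) {
          jump <- if (is.na(prev_end)) 0 else
            abs(b$donor_start[i] - prev_end)
          if (jump <= max_jump) {
            keep[i] <- TRUE
            prev_end <- b$donor_end[i]
          }
        }
        b[keep, , drop = FALSE]
      })
  }
  rownames(b) <- NULL
  b
}

#' Extract polymorphic sites from filtered synteny blocks
#'
#' One record per aligned column where the two genomes carry different
#' unambiguous bases. Gap columns and ambiguity codes are skipped. Donor
#' positions and alleles honour block orientation (minus-strand donor
#' alleles are reported in donor-genome coordinates and complemented).
#'
#' @param blocks Block `data.frame` (usually after
#'   [filter_synteny_blocks()]).
#' @return `data.frame` with `recipient_pos`, `donor_pos`,
#'   `recipient_allele`, `donor_allele`, sorted by `recipient_pos`,
#'   duplicates at the same recipient position removed (first kept).
#' @export
extract_polymorphic_sites <- function(blocks) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- vector("list", nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    rc <- strsplit(blocks$recipient_aln[i], "")[[1]]
    dc <- strsplit(blocks$donor_aln[i], "")[[1]]
    if (length(rc) != length(dc))
      stopf("block %d: aligned sequences differ in length", i)
    rpos <- blocks$recipient_start[i] - 1L + cumsum(rc != "-")
    if (blocks$strand[i] == "+") {
      dpos <- blocks$donor_start[i] - 1L + cumsum(dc != "-")
    } else {
      dpos <- blocks$donor_end[i] + 1L - cumsum(dc != "-")
    }
    is_site <- rc %in% BASES & dc %in% BASES & rc != dc
    if (!any(is_site)) next
    d_allele <- dc[is_site]
    if (blocks$strand[i] == "-") d_allele <- unname(comp[d_allele])
    out[[i]] <- data.frame(recipient_pos = rpos[is_site],
                           donor_pos = dpos[is_site],
                           recipient_allele = rc[is_site],
                           donor_allele = d_allele,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(recipient_pos = integer(0), donor_pos = integer(0),
                      recipient_allele = character(0),
                      donor_allele = character(0),
                      stringsAsFactors = FALSE))
  }
  sites <- do.call(rbind, out)
  sites <- sites[order(sites$recipient_pos), , drop = FALSE]
  sites <- sites[!duplicated(sites$recipient_pos), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Synteny blocks from a synthetic pair's known alignment
#'
#' For generated genome pairs the core alignment is known exactly: cores
#' are colinear and accessory insertions are recorded. This builds the
#' corresponding block table (one block per contiguous core segment
#' between insertion points in either genome), which feeds the same
#' downstream functions as [read_xmfa()] output.
#'
#' @param pair A `genome_pair`.
#' @return Block `data.frame` as from [read_xmfa()].
#' @export
truth_blocks <- function(pair) {
  G <- pair$core_length
  cuts <- sort(unique(c(0L, G,
                        pair$donor_insertions$after,
                        pair$recipient_insertions$after)))
  cuts <- cuts[cuts >= 0L & cuts <= G]
  segs <- data.frame(core_start = cuts[-length(cuts)] + 1L,
                     core_end = cuts[-1])
  segs <- segs[segs$core_end >= segs$core_start, , drop = FALSE]
  rs <- core_to_recipient(pair, segs$core_start)
  re <- core_to_recipient(pair, segs$core_end)
  ds <- core_to_donor(pair, segs$core_start)
  de <- core_to_donor(pair, segs$core_end)
  data.frame(recipient_start = rs, recipient_end = re,
             donor_start = ds, donor_end = de,
             strand = "+",
             recipient_aln = substring(pair$recipient_seq, rs, re),
             donor_aln = substring(pair$donor_seq, ds, de),
             stringsAsFactors = FALSE)
}

#' Density of recombination-initiation opportunities
#'
#' Counts, per genomic bin, the maximal runs of strictly identical aligned
#' columns of length at least `k` bases. Runs of perfect identity of
#' roughly 20 bp (permissive bound) to 27 bp (strict bound) are the
#' substrate RecA needs to initiate strand invasion, so their density maps
#' where homologous recombination can start. A run is assigned to the bin
#' containing its midpoint (recipient coordinates); gaps, ambiguity codes
#' and block boundaries break runs.
#'
#' @param x A `genome_pair` or a block `data.frame`.
#' @param k Integer vector of run-length thresholds (default `c(20, 27)`).
#' @param bin Bin width in bases (default 100 kb).
#' @param genome_length Recipient genome length (required when `x` is a
#'   block table; inferred for a pair).
#' @return `data.frame` with `bin_start` (1-based) and, per threshold,
#'   `count_k<k>` and `per_kb_k<k>` columns.
#' @export
homology_opportunity_density <- function(x, k = c(20L, 27L), bin = 1e5,
                                         genome_length = NULL) {
  if (any(k <= 0)) stopf("k must be positive")
  if (inherits(x, "genome_pair")) {
    genome_length <- nchar(x$recipient_seq)
    blocks <- truth_blocks(x)
  } else {
    blocks <- x
    if (is.null(genome_length))
      stopf("'genome_length' required with a block table")
  }
  n_bins <- ceiling(genome_length / bin)
  bin_start <- as.integer((seq_len(n_bins) - 1L) * bin + 1L)
  runs_mid <- integer(0)
  runs_len <- integer(0)
  for (i in seq_len(nrow(blocks))) {
    rc <- strsplit(blocks$recipient_aln[i], "")[[1]]
    dc <- strsplit(blocks$donor_aln[i], "")[[1]]
    rpos <- blocks$recipient_start[i] - 1L + cumsum(rc != "-")
    eq <- rc == dc & rc %in% BASES
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- r$values
    if (!any(sel)) next
    s <- starts[sel]; e <- ends[sel]
    mid <- (s + e) %/% 2L
    runs_mid <- c(runs_mid, rpos[mid])
    runs_len <- c(runs_len, e - s + 1L)
  }
  out <- data.frame(bin_start = bin_start)
  for (kk in k) {
    sel <- runs_len >= kk
    counts <- tabulate(((runs_mid[sel] - 1L) %/% bin) + 1L, nbins = n_bins)
    out[[sprintf("count_k%d", kk)]] <- counts
    width_kb <- pmin(bin_start + bin - 1L, genome_length) -
      bin_start + 1L
    out[[sprintf("per_kb_k%d", kk)]] <- counts / (width_kb / 1000)
  }
  out
}
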