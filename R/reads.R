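#' Simulate shotgun sequencing reads
#'
#' Single-end reads of fixed length with uniform start positions and
#' i.i.d. substitution errors. The read count is
#' `round(depth * nchar(sequence) / read_length)`. The true origin position
#' is recorded in each read name (`<prefix>_<i>|pos=<start>`) for
#' validation only — no analysis step reads it.
#'
#' @param sequence Template sequence (character scalar).
#' @param depth Fold coverage (> 0).
#' @param read_length Read length in bases (default 150).
#' @param error_rate Per-base substitution probability.
#' @param seed RNG seed.
#' @param id_prefix Prefix for read names.
#' @param out_fastq Optional path: reads written as FASTQ (Phred+33,
#'   constant quality).
#' @return `data.frame` with columns `id`, `seq`, `true_pos`.
#' @export
simulate_reads <- function(sequence, depth, read_length = 150L,
                           error_rate = 0, seed = NULL,
                           id_prefix = "read", out_fastq = NULL) {
  n <- nchar(sequence)
  if (n == 0L) stopf("empty sequence")
  if (read_length > n) stopf("read_length exceeds sequence length")
  if (depth <= 0) stopf("depth must be positive")
  n_reads <- round(depth * n / read_length)
  out <- with_seed(seed, {
    starts <- sample.int(n - read_length + 1L, n_reads, replace = TRUE)
    reads <- substring(sequence, starts, starts + read_length - 1L)
    if (error_rate > 0) {
      total <- n_reads * read_length
      n_err <- stats::rbinom(1L, total, error_rate)
      if (n_err > 0L) {
        flat <- sample.int(total, n_err)          # flat index over all bases
        ridx <- (flat - 1L) %/% read_length + 1L  # which read
        off <- (flat - 1L) %% read_length + 1L    # which base
        shift <- sample.int(3L, n_err, replace = TRUE)  # cyclic base shift
        o <- order(ridx)
        ridx <- ridx[o]; off <- off[o]; shift <- shift[o]
        for (grp in split(seq_len(n_err), ridx)) {
          i <- ridx[grp[1]]
          r <- charToRaw(reads[i])
          cur <- match(strsplit(rawToChar(r[off[grp]]), "")[[1]], BASES)
          new <- BASES[((cur - 1L + shift[grp]) %% 4L) + 1L]
          r[off[grp]] <- charToRaw(paste(new, collapse = ""))
          reads[i] <- rawToChar(r)
        }
      }
    }
    data.frame(
      id = sprintf("%s_%06d|pos=%d", id_prefix, seq_len(n_reads), starts),
      seq = reads, true_pos = starts,
      row.names = NULL, stringsAsFactors = FALSE)
  })
  if (!is.null(out_fastq)) write_fastq(out$seq, out$id, out_fastq)
  out
}

#' Build a sequencing pool from several recombinant clones
#'
#' Per-clone read counts are multinomial with probabilities proportional to
#' `weights`, emulating the relative abundance of recombinants in a pooled
#' library.
#'
#' @param clones List of `recombinant` objects (from
#'   [simulate_recombinant()]).
#' @param weights Nonnegative clone weights, not all zero (default equal).
#' @param total_depth Aggregate fold coverage of the pool.
#' @param read_length,error_rate,seed As in [simulate_reads()].
#' @param out_fastq Optional FASTQ output path.
#' @param out_manifest Optional JSON manifest path (per-clone read counts
#'   and weights).
#' @return A list of class `read_pool`: `reads` (`data.frame` `id`, `seq`,
#'   `true_pos`, `clone_id`) and `manifest` (`data.frame` `clone_id`,
#'   `weight`, `n_reads`).
#' @export
build_pool <- function(clones, weights = NULL, total_depth,
                       read_length = 150L, error_rate = 0, seed = NULL,
                       out_fastq = NULL, out_manifest = NULL) {
  if (length(clones) < 1L) stopf("need at least one clone")
  if (is.null(weights)) weights <- rep(1, length(clones))
  if (length(weights) != length(clones))
    stopf("one weight per clone required")
  if (any(weights < 0) || sum(weights) == 0)
    stopf("weights must be nonnegative and not all zero")
  glen <- nchar(clones[[1]]$sequence)
  n_total <- round(total_depth * glen / read_length)
  res <- with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1L, n_total,
                                         weights / sum(weights)))
    parts <- vector("list", length(clones))
    for (i in seq_along(clones)) {
      if (counts[i] == 0L) next
      sub_seed <- sample.int(.Machine$integer.max, 1L)
      rr <- simulate_reads(clones[[i]]$sequence,
                           depth = counts[i] * read_length / glen,
                           read_length = read_length,
                           error_rate = error_rate, seed = sub_seed,
                           id_prefix = clones[[i]]$clone_id)
      rr$clone_id <- clones[[i]]$clone_id
      parts[[i]] <- rr
    }
    reads <- do.call(rbind, parts)
    rownames(reads) <- NULL
    list(reads = reads,
         manifest = data.frame(
           clone_id = vapply(clones, `[[`, character(1), "clone_id"),
           weight = weights, n_reads = counts,
           stringsAsFactors = FALSE))
  })
  class(res) <- "read_pool"
  if (!is.null(out_fastq)) write_fastq(res$reads$seq, res$reads$id, out_fastq)
  if (!is.null(out_manifest)) {
    jsonlite::write_json(res$manifest, out_manifest, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
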