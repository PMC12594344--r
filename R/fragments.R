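#' Concordance between the two tract-detection methods
#'
#' Compares the donor territories called by the HMM and by the
#' changepoint method for the same clone: per-base Jaccard index,
#' reciprocally overlapping fragment pairs, and fragments unique to each
#' method.
#'
#' @param frags_hmm,frags_freq Fragment `data.frame`s (only rows with
#'   `origin == "donor"` are used).
#' @param reciprocal Minimum reciprocal overlap fraction for two
#'   fragments to count as matched (default 0.5).
#' @return A list of class `method_concordance`: `jaccard`, `matched`
#'   (`data.frame` of index pairs and overlap widths), `only_hmm`,
#'   `only_freq` (fragment rows unique to one method).
#' @export
compare_methods <- function(frags_hmm, frags_freq, reciprocal = 0.5) {
  don <- function(f) f[f$origin == "donor", , drop = FALSE]
  a <- don(frags_hmm); b <- don(frags_freq)
  ir <- function(f) {
    if (nrow(f) == 0L) return(IRanges::IRanges())
    IRanges::reduce(IRanges::IRanges(f$start, f$end - 1L))
  }
  ia <- ir(a); ib <- ir(b)
  inter <- sum(IRanges::width(IRanges::intersect(ia, ib)))
  uni <- sum(IRanges::width(IRanges::union(ia, ib)))
  jac <- if (uni == 0) 1 else inter / uni

  matched <- data.frame(hmm = integer(0), freq = integer(0),
                        overlap = integer(0))
  if (nrow(a) > 0L && nrow(b) > 0L) {
    ra <- IRanges::IRanges(a$start, a$end - 1L)
    rb <- IRanges::IRanges(b$start, b$end - 1L)
    hits <- IRanges::findOverlaps(ra, rb)
    if (length(hits) > 0L) {
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      ov <- IRanges::width(IRanges::pintersect(ra[qi], rb[si]))
      good <- ov >= reciprocal * IRanges::width(ra[qi]) &
        ov >= reciprocal * IRanges::width(rb[si])
      matched <- data.frame(hmm = qi[good], freq = si[good],
                            overlap = ov[good])
    }
  }
  structure(list(
    jaccard = jac,
    matched = matched,
    only_hmm = a[setdiff(seq_len(nrow(a)), matched$hmm), , drop = FALSE],
    only_freq = b[setdiff(seq_len(nrow(b)), matched$freq), , drop = FALSE]),
    class = "method_concordance")
}

#' @export
print.method_concordance <- function(x, ...) {
  cat(sprintf(
    "method concordance: Jaccard %.4f, %d matched, %d HMM-only, %d freq-only\n",
    x$jaccard, nrow(x$matched), nrow(x$only_hmm), nrow(x$only_freq)))
  invisible(x)
}

#' Summary statistics of recombined fragments across clones
#'
#' Length and count summaries of the donor-derived fragments of a set of
#' recombinant clones, split by whether the fragment carries the selected
#' marker, plus a two-sided rank-sum (Wilcoxon) comparison of
#' marker-containing versus other fragment lengths — selection inflates
#' the marker-covering fragment relative to passenger fragments.
#'
#' @param clones Named list of fragment `data.frame`s (one per clone;
#'   only `origin == "donor"` rows are used).
#' @param marker Optional marker coordinate; when the fragment tables
#'   lack a `contains_marker` column it is recomputed from this.
#' @return A list of class `fragment_stats`: `fragments` (pooled table
#'   with `clone_id`), `per_clone` (`clone_id`, `n_fragments`,
#'   `total_length`), `summary` (medians/means overall and by marker
#'   status, `wilcox_stat`, `wilcox_p`).
#' @export
fragment_stats <- function(clones, marker = NULL) {
  if (length(clones) < 1L) stopf("need at least one clone")
  if (is.null(names(clones)))
    names(clones) <- sprintf("clone_%02d", seq_along(clones))
  rows <- lapply(names(clones), function(id) {
    f <- clones[[id]]
    f <- f[f$origin == "donor", , drop = FALSE]
    if (!("contains_marker" %in% names(f)) && !is.null(marker))
      f$contains_marker <- f$start <= marker & marker < f$end
    if (nrow(f) == 0L) return(NULL)
    f$clone_id <- id
    f$length <- f$end - f$start
    f[, c("clone_id", "start", "end", "length", "origin",
          "contains_marker")]
  })
  frag <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  per_clone <- data.frame(
    clone_id = names(clones),
    n_fragments = vapply(names(clones), function(id)
      sum(frag$clone_id == id), integer(1)),
    total_length = vapply(names(clones), function(id)
      sum(frag$length[frag$clone_id == id]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  mk <- frag$length[frag$contains_marker]
  ot <- frag$length[!frag$contains_marker]
  wt <- if (length(mk) > 0L && length(ot) > 0L)
    stats::wilcox.test(mk, ot, alternative = "two.sided", exact = NULL)
  else NULL
  summary <- data.frame(
    n_fragments = nrow(frag),
    median_length = stats::median(frag$length),
    mean_length = mean(frag$length),
    median_marker_length = if (length(mk)) stats::median(mk) else NA_real_,
    median_other_length = if (length(ot)) stats::median(ot) else NA_real_,
    mean_fragments_per_clone = mean(per_clone$n_fragments),
    mean_total_length = mean(per_clone$total_length),
    wilcox_stat = if (is.null(wt)) NA_real_ else unname(wt$statistic),
    wilcox_p = if (is.null(wt)) NA_real_ else wt$p.value)
  structure(list(fragments = frag, per_clone = per_clone,
                 summary = summary), class = "fragment_stats")
}

#' @export
print.fragment_stats <- function(x, ...) {
  cat(sprintf(
    "fragment_stats: %d donor fragments over %d clones; median %.0f bp, %.2f fragments/clone\n",
    x$summary$n_fragments, nrow(x$per_clone), x$summary$median_length,
    x$summary$mean_fragments_per_clone))
  invisible(x)
}

#' Robustness of tract detection to sequencing coverage
#'
#' Re-runs both segmentation methods on random subsets of a clone's reads
#' and reports how many donor fragments survive at each coverage level.
#' Because read classification is deterministic per read, reads are
#' classified once and label subsets are drawn without replacement.
#'
#' @param reads Read `data.frame` for one clone.
#' @param pair `genome_pair`.
#' @param sites Polymorphic-site table (default `pair$truth_sites`).
#' @param fractions Subsampling fractions in (0, 1].
#' @param seed RNG seed for the subsampling.
#' @param hmm [hmm_params()].
#' @param cp [changepoint_params()].
#' @param marker Optional marker coordinate.
#' @param index Optional prebuilt classifier index.
#' @return `data.frame`: `fraction`, `n_reads`, `mean_coverage`,
#'   `n_fragments_hmm`, `n_fragments_cp`.
#' @export
downsample_robustness <- function(reads, pair, sites = NULL,
                                  fractions = c(1, 0.5, 0.4, 0.25,
                                                0.175, 0.1),
                                  seed = NULL, hmm = hmm_params(),
                                  cp = changepoint_params(),
                                  marker = NULL, index = NULL) {
  if (any(fractions <= 0 | fractions > 1))
    stopf("fractions must lie in (0, 1]")
  if (is.null(sites)) sites <- pair$truth_sites
  cls <- classify_builtin(reads, pair, sites, index = index)
  glen <- nchar(pair$recipient_seq)
  read_len <- nchar(reads$seq[1])
  n <- nrow(reads)
  with_seed(seed, {
    res <- lapply(fractions, function(f) {
      keep_ids <- if (f == 1) reads$id else
        sample(reads$id, round(f * n))
      lab <- cls$labels[cls$labels$read_id %in% keep_ids, , drop = FALSE]
      obs <- cls$observations[
        cls$observations$read_id %in% keep_ids, , drop = FALSE]
      sub <- structure(list(labels = lab, observations = obs),
                       class = "read_classification")
      fr_h <- hmm_segment(binary_series(sub), hmm, marker = marker)
      fr_c <- changepoint_segment(site_frequencies(sub, sites), cp,
                                  marker = marker)
      data.frame(fraction = f,
                 n_reads = length(keep_ids),
                 mean_coverage = length(keep_ids) * read_len / glen,
                 n_fragments_hmm = sum(fr_h$origin == "donor"),
                 n_fragments_cp = sum(fr_c$origin == "donor"))
    })
    do.call(rbind, res)
  })
}
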