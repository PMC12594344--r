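#' Simulate a recombinant clone from a conjugation cross
#'
#' A recombinant carries the recipient genome with one or more donor-derived
#' fragments substituted in. Selection guarantees one fragment covering the
#' selected marker; additional fragments — pieces of the incoming donor DNA
#' cut and recombined separately — land in the neighbourhood of the marker
#' fragment (or genome-wide when `genome_wide = TRUE`, emulating the
#' occasional distant integration).
#'
#' The marker-covering fragment has length `L` drawn from `marker_dist` and
#' left overhang uniform on `[0, L)`, i.e. the marker position is uniform
#' within the fragment — the law of an interval conditioned on covering a
#' fixed point when positions are uniform. Fragments are clipped at the
#' genome ends (no wrap-around). Extra fragments are redrawn until they are
#' at least 1 kb away from already-placed fragments, so that distinct
#' recombined regions stay distinct; if no gap can be found they are merged.
#'
#' @param pair A `genome_pair`.
#' @param marker_position Recipient-genome coordinate of the selected
#'   marker (must fall in the core genome).
#' @param marker_dist [fragment_dist()] for the marker-covering fragment.
#' @param extra_count Either a single nonnegative integer (fixed count) or
#'   `list(family = "poisson", lambda = ...)`; number of extra fragments.
#' @param extra_dist [fragment_dist()] for extra fragment lengths.
#' @param placement_window Half-width (bases) of the window around the
#'   marker fragment in which extra fragments are placed (default 500 kb).
#' @param genome_wide Place extra fragments uniformly over the whole
#'   genome instead of in the window.
#' @param forbidden Optional counter-selected locus that no fragment may
#'   overlap: either a single coordinate or a length-2 vector
#'   `c(start, end)` (half-open interval, e.g. a resistance cassette
#'   retained in the recipient). Fragments overlapping it are redrawn.
#' @param clone_id Identifier stored with the truth.
#' @param seed RNG seed.
#' @param out_bed Optional path: truth fragments written as BED.
#' @return A list of class `recombinant`: `sequence` (recipient frame,
#'   same length as the recipient genome), `fragments` (`data.frame`
#'   `start`, `end` half-open, `contains_marker`), `marker_position`,
#'   `clone_id`.
#' @export
simulate_recombinant <- function(pair, marker_position, marker_dist,
                                 extra_count = list(family = "poisson",
                                                    lambda = 1.2),
                                 extra_dist = NULL,
                                 placement_window = 5e5,
                                 genome_wide = FALSE,
                                 forbidden = NULL,
                                 clone_id = "clone",
                                 seed = NULL,
                                 out_bed = NULL) {
  stopifnot(inherits(pair, "genome_pair"),
            inherits(marker_dist, "fragment_dist"))
  glen <- nchar(pair$recipient_seq)
  if (marker_position < 1 || marker_position > glen)
    stopf("marker_position outside the genome")
  if (is.na(recipient_to_core(pair, marker_position)))
    stopf("marker_position falls in an accessory region")
  if (!is.null(forbidden)) {
    # a point is a degenerate one-base interval
    if (length(forbidden) == 1L) forbidden <- c(forbidden, forbidden + 1L)
    if (forbidden[1] <= marker_position && marker_position < forbidden[2])
      stopf("'forbidden' cannot cover the marker position")
  }
  hits_forbidden <- function(s, e) {
    !is.null(forbidden) && s < forbidden[2] && forbidden[1] < e
  }

  res <- with_seed(seed, {
    draw_marker_fragment <- function() {
      for (i in 1:1000) {
        L <- draw_lengths(marker_dist, 1L)
        U <- floor(stats::runif(1, 0, L))
        s <- marker_position - U
        e <- s + L                      # half-open [s, e)
        s <- max(1, s); e <- min(glen + 1, e)
        if (!hits_forbidden(s, e)) return(c(s, e))
      }
      stopf("could not draw a marker fragment avoiding 'forbidden'")
    }
    mf <- draw_marker_fragment()

    n_extra <- if (is.list(extra_count)) {
      stopifnot(identical(extra_count$family, "poisson"))
      stats::rpois(1L, extra_count$lambda)
    } else {
      as.integer(extra_count)
    }
    if (n_extra > 0L && is.null(extra_dist))
      stopf("'extra_dist' required when extra fragments are requested")

    starts <- mf[1]; ends <- mf[2]; flags <- TRUE
    if (n_extra > 0L) {
      win_lo <- if (genome_wide) 1 else max(1, mf[1] - placement_window)
      win_hi <- if (genome_wide) glen + 1 else
        min(glen + 1, mf[2] + placement_window)
      for (i in seq_len(n_extra)) {
        placed <- FALSE
        for (try in 1:100) {
          L <- draw_lengths(extra_dist, 1L)
          s <- floor(stats::runif(1, win_lo, max(win_lo, win_hi - L) + 1))
          e <- min(glen + 1, s + L)
          if (hits_forbidden(s, e)) next
          # keep distinct regions >= 1 kb apart where possible
          if (all(e + 1000 <= starts | s >= ends + 1000) || try == 100) {
            starts <- c(starts, s); ends <- c(ends, e)
            flags <- c(flags, FALSE)
            placed <- TRUE
            break
          }
        }
        if (!placed) next
      }
    }
    frags <- merge_intervals(starts, ends, flags)
    frags <- frags[order(frags$start), , drop = FALSE]
    rownames(frags) <- NULL

    # substitute donor alleles at truth sites inside fragments
    ts <- pair$truth_sites
    inside <- rep(FALSE, nrow(ts))
    for (i in seq_len(nrow(frags))) {
      inside <- inside | (ts$recipient_pos >= frags$start[i] &
                            ts$recipient_pos < frags$end[i])
    }
    seqr <- substitute_bases(pair$recipient_seq,
                             ts$recipient_pos[inside],
                             ts$donor_allele[inside])
    list(sequence = seqr, fragments = frags,
         marker_position = marker_position, clone_id = clone_id)
  })
  class(res) <- "recombinant"
  if (!is.null(out_bed)) {
    bed <- res$fragments
    bed$origin <- ifelse(bed$contains_marker, "donor_marker", "donor")
    write_fragments_bed(bed, out_bed)
  }
  res
}

#' @export
print.recombinant <- function(x, ...) {
  cat(sprintf("recombinant '%s': %d donor fragment(s), marker at %d\n",
              x$clone_id, nrow(x$fragments), x$marker_position))
  invisible(x)
}
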