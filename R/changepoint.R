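#' Parameters for penalized changepoint segmentation
#'
#' @param penalty Nonnegative cost added per changepoint (default 3,
#'   permissive enough to pick up small fragments on near-binary
#'   frequency data).
#' @param min_segment_sites Minimum sites per segment (default 2).
#' @return Object of class `changepoint_params`.
#' @export
changepoint_params <- function(penalty = 3, min_segment_sites = 2L) {
  if (!is_number(penalty) || penalty < 0) stopf("penalty must be >= 0")
  if (min_segment_sites < 1L) stopf("min_segment_sites must be >= 1")
  structure(list(penalty = penalty,
                 min_segment_sites = as.integer(min_segment_sites)),
            class = "changepoint_params")
}

#' Optimal piecewise-constant-mean changepoints (PELT)
#'
#' Minimizes `sum of within-segment squared errors + penalty * (number of
#' changepoints)` exactly, using pruned exact linear time dynamic
#' programming. Ties are broken towards the earliest candidate start.
#'
#' @param x Numeric series.
#' @param penalty Per-changepoint cost.
#' @param min_seg Minimum segment length.
#' @return Sorted integer vector of changepoint indices: a value `c`
#'   means a new segment starts at `c + 1`.
#' @export
pelt_changepoints <- function(x, penalty, min_seg = 2L) {
  n <- length(x)
  if (n < 2L * min_seg) return(integer(0))
  S1 <- c(0, cumsum(x))
  S2 <- c(0, cumsum(x * x))
  Fv <- rep(Inf, n + 1L)
  Fv[1L] <- -penalty
  prev <- rep(NA_integer_, n + 1L)
  cand <- 0L
  for (t in seq.int(min_seg, n)) {
    ok <- cand[t - cand >= min_seg]
    # cost of segment x[(s+1)..t] for every candidate start s, vectorised
    s1 <- S1[t + 1L] - S1[ok + 1L]
    segc <- (S2[t + 1L] - S2[ok + 1L]) - s1 * s1 / (t - ok)
    vals <- Fv[ok + 1L] + segc + penalty
    b <- which.min(vals)
    Fv[t + 1L] <- vals[b]
    prev[t + 1L] <- ok[b]
    keep <- ok[vals - penalty <= Fv[t + 1L]]
    # candidates too recent to start a minimum-length segment stay eligible
    cand <- c(keep, cand[t - cand < min_seg], t)
  }
  cps <- integer(0)
  t <- n
  while (!is.na(prev[t + 1L]) && prev[t + 1L] > 0L) {
    cps <- c(prev[t + 1L], cps)
    t <- prev[t + 1L]
  }
  cps
}

#' Segment donor-allele frequencies into donor and recipient tracts
#'
#' Fits a piecewise-constant mean to the per-site donor-allele frequency
#' series by exact penalized least squares; segments with mean frequency
#' above 0.5 are donor-derived. Sites without coverage are dropped first;
#' adjacent same-origin segments are merged. On clone data the
#' frequencies sit near 0 and 1, so the result is insensitive to the
#' Gaussian idealization behind the squared-error cost.
#'
#' @param freqs `data.frame` from [site_frequencies()] (needs
#'   `recipient_pos`, `donor_frequency`; rows with `NA` frequency are
#'   dropped).
#' @param params [changepoint_params()].
#' @param marker Optional marker coordinate to flag `contains_marker`.
#' @return `data.frame` of fragments: `start`, `end` (half-open,
#'   boundaries at site coordinates), `origin`, `n_obs`,
#'   `contains_marker`, `mean_freq`.
#' @export
changepoint_segment <- function(freqs, params = changepoint_params(),
                                marker = NULL) {
  usable <- freqs[!is.na(freqs$donor_frequency), , drop = FALSE]
  usable <- usable[order(usable$recipient_pos), , drop = FALSE]
  empty <- data.frame(start = integer(0), end = integer(0),
                      origin = character(0), n_obs = integer(0),
                      contains_marker = logical(0),
                      mean_freq = numeric(0))
  if (nrow(usable) == 0L) return(empty)
  x <- usable$donor_frequency
  pos <- usable$recipient_pos
  n <- length(x)
  cps <- if (n < 2L) integer(0) else
    pelt_changepoints(x, params$penalty, params$min_segment_sites)
  bounds <- c(0L, cps, n)
  seg <- data.frame(
    from = bounds[-length(bounds)] + 1L,
    to = bounds[-1L])
  seg$mean_freq <- vapply(seq_len(nrow(seg)), function(i)
    mean(x[seg$from[i]:seg$to[i]]), numeric(1))
  seg$origin <- ifelse(seg$mean_freq > 0.5, "donor", "recipient")

  # merge adjacent same-origin segments
  grp <- cumsum(c(TRUE, seg$origin[-1L] != seg$origin[-nrow(seg)]))
  out <- do.call(rbind, lapply(split(seq_len(nrow(seg)), grp), function(ii) {
    from <- seg$from[ii[1L]]; to <- seg$to[ii[length(ii)]]
    data.frame(start = pos[from], end = pos[to] + 1L,
               origin = seg$origin[ii[1L]],
               n_obs = to - from + 1L,
               mean_freq = mean(x[from:to]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$contains_marker <- if (is.null(marker)) FALSE else
    (out$start <= marker & marker < out$end)
  out[, c("start", "end", "origin", "n_obs", "contains_marker",
          "mean_freq")]
}
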