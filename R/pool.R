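#' Binned donor/recipient profile of a sequenced recombinant pool
#'
#' Tiles the recipient genome into fixed-width bins and counts the
#' informative reads (donor-better / recipient-better) per bin, giving
#' the donor fraction and the pseudocounted log10 donor-to-recipient
#' ratio along the genome. In a pool under selection, donor-specific
#' reads pile up around the selected locus, so the profile peaks there.
#'
#' @param labels Read labels (`data.frame` with `recipient_pos`,
#'   `category`), e.g. `classify_builtin(...)$labels`.
#' @param genome_length Recipient genome length (bases).
#' @param bin_size Bin width (default 1000).
#' @param pseudocount Added to both counts in the log-ratio (default 1);
#'   keeps empty bins finite.
#' @return `data.frame` of class `pool_profile`: `bin_start` (1-based),
#'   `donor_count`, `recipient_count`, `donor_fraction` (NA on empty
#'   bins), `log_ratio`, `no_data`. Attributes: `bin_size`,
#'   `genome_length`, `pseudocount`.
#' @export
bin_pool <- function(labels, genome_length, bin_size = 1000L,
                     pseudocount = 1) {
  if (bin_size <= 0) stopf("bin_size must be positive")
  n_bins <- as.integer(ceiling(genome_length / bin_size))
  informative <- labels[
    labels$category %in% c("DONOR_BETTER", "RECIPIENT_BETTER") &
      !is.na(labels$recipient_pos), , drop = FALSE]
  bidx <- pmin(n_bins,
               (pmax(1L, informative$recipient_pos) - 1L) %/%
                 bin_size + 1L)
  dct <- tabulate(bidx[informative$category == "DONOR_BETTER"], n_bins)
  rct <- tabulate(bidx[informative$category == "RECIPIENT_BETTER"], n_bins)
  tot <- dct + rct
  out <- data.frame(
    bin_start = as.integer((seq_len(n_bins) - 1L) * bin_size + 1L),
    donor_count = dct, recipient_count = rct,
    donor_fraction = ifelse(tot > 0, dct / tot, NA_real_),
    log_ratio = log10((dct + pseudocount) / (rct + pseudocount)),
    no_data = tot == 0L)
  attr(out, "bin_size") <- as.integer(bin_size)
  attr(out, "genome_length") <- as.integer(genome_length)
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("pool_profile", class(out))
  out
}

#' Localize the selected locus from a pool profile
#'
#' The selected locus is estimated as the centre of the bin maximizing
#' the log10 donor/recipient ratio; the reported interval is the
#' contiguous run of bins whose log-ratio stays within `delta` of the
#' peak value.
#'
#' @param profile A [bin_pool()] profile.
#' @param delta Drop from the peak defining the interval (default
#'   `log10(2)`, a two-fold ratio drop).
#' @param refine `"none"` (default) reports the peak at the bin centre;
#'   `"quadratic"` fits a parabola through the peak bin and its two
#'   neighbours and reports its vertex (clamped to one bin width).
#' @return A list of class `locus_call`: `peak_position` (bin centre),
#'   `peak_bin_start`, `peak_value`, `interval` (`c(start, end)`,
#'   half-open), `tie` (TRUE when several bins share the maximum;
#'   leftmost reported).
#' @export
locate_selected_locus <- function(profile, delta = log10(2),
                                  refine = c("none", "quadratic")) {
  refine <- match.arg(refine)
  usable <- !profile$no_data
  if (!any(usable)) stopf("profile has no informative bin")
  lr <- profile$log_ratio
  mx <- max(lr[usable])
  peaks <- which(usable & lr == mx)
  peak <- peaks[1L]
  bin_size <- attr(profile, "bin_size")
  # contiguous run around the peak within delta of the maximum
  lo <- peak
  while (lo > 1L && !profile$no_data[lo - 1L] && lr[lo - 1L] >= mx - delta)
    lo <- lo - 1L
  hi <- peak
  while (hi < nrow(profile) && !profile$no_data[hi + 1L] &&
         lr[hi + 1L] >= mx - delta)
    hi <- hi + 1L
  peak_position <- profile$bin_start[peak] + bin_size / 2 - 0.5
  if (refine == "quadratic" && peak > 1L && peak < nrow(profile) &&
      !profile$no_data[peak - 1L] && !profile$no_data[peak + 1L]) {
    y <- lr[(peak - 1L):(peak + 1L)]
    denom <- y[1L] - 2 * y[2L] + y[3L]
    if (denom < 0) {
      shift <- 0.5 * (y[1L] - y[3L]) / denom * bin_size
      peak_position <- peak_position +
        max(-bin_size / 2, min(bin_size / 2, shift))
    }
  }
  structure(list(
    peak_position = peak_position,
    peak_bin_start = profile$bin_start[peak],
    peak_value = mx,
    interval = c(profile$bin_start[lo],
                 profile$bin_start[hi] + bin_size),
    tie = length(peaks) > 1L), class = "locus_call")
}

#' @export
print.locus_call <- function(x, ...) {
  cat(sprintf(
    "locus call: peak at %.0f (log10 ratio %.2f), interval [%d, %d)%s\n",
    x$peak_position, x$peak_value, x$interval[1], x$interval[2],
    if (x$tie) " [tie: leftmost reported]" else ""))
  invisible(x)
}

#' Localize a counter-selected site as a profile dip
#'
#' A marker retained in the recipient under counter-selection (donor
#' fragments never replace it) produces a sharp local minimum of the
#' log-ratio. The dip is searched within a window around `center`
#' (default: the profile peak, where donor signal is dense enough for a
#' minimum to be meaningful).
#'
#' @param profile A [bin_pool()] profile.
#' @param center Window centre (default: peak position).
#' @param halfwidth Window half-width in bases (default 100 kb).
#' @return List: `dip_position` (bin centre), `dip_bin_start`,
#'   `dip_value`.
#' @export
locate_counterselected_site <- function(profile, center = NULL,
                                        halfwidth = 1e5) {
  if (is.null(center)) center <- locate_selected_locus(profile)$peak_position
  bin_size <- attr(profile, "bin_size")
  mid <- profile$bin_start + bin_size / 2 - 0.5
  inwin <- abs(mid - center) <= halfwidth & !profile$no_data
  if (!any(inwin)) stopf("no informative bin in the window")
  idx <- which(inwin)[which.min(profile$log_ratio[inwin])]
  list(dip_position = mid[idx],
       dip_bin_start = profile$bin_start[idx],
       dip_value = profile$log_ratio[idx])
}

#' Donor-presence decay around the selected locus
#'
#' Re-indexes the pool profile by signed distance to the marker and
#' reports the distance (left and right) at which the donor fraction
#' first falls below half of its value at the marker — longer recombined
#' tracts give a slower decay.
#'
#' @param profile A [bin_pool()] profile.
#' @param marker Marker coordinate.
#' @return A list of class `decay_profile`: `table` (`distance`,
#'   `donor_fraction`, `log_ratio`), `peak_fraction`,
#'   `half_decay_left`, `half_decay_right` (bases; NA when the fraction
#'   never falls below half within the profile).
#' @export
decay_profile <- function(profile, marker) {
  glen <- attr(profile, "genome_length")
  if (marker < 1 || marker > glen) stopf("marker outside the genome")
  bin_size <- attr(profile, "bin_size")
  mid <- profile$bin_start + bin_size / 2 - 0.5
  tab <- data.frame(distance = mid - marker,
                    donor_fraction = profile$donor_fraction,
                    log_ratio = profile$log_ratio)
  tab <- tab[order(tab$distance), , drop = FALSE]
  at_marker <- which.min(abs(tab$distance))
  peak_frac <- tab$donor_fraction[at_marker]
  half <- peak_frac / 2
  right <- tab[tab$distance >= 0, , drop = FALSE]
  left <- tab[tab$distance <= 0, , drop = FALSE]
  first_below <- function(fr, d) {
    i <- which(!is.na(fr) & fr < half)
    if (length(i) == 0L) NA_real_ else abs(d[i[1L]])
  }
  structure(list(
    table = tab,
    peak_fraction = peak_frac,
    half_decay_right = first_below(right$donor_fraction, right$distance),
    half_decay_left = first_below(rev(left$donor_fraction),
                                  rev(left$distance))),
    class = "decay_profile")
}

#' Transposon insertion density along the genome
#'
#' Summarizes a transposon insertion-site table in fixed bins by two
#' metrics — the count of distinct insertion sites (density) and the
#' summed read counts over those sites (coverage) — each expressed as a
#' log2 fold-change relative to the mean per-bin value inside the Ter
#' macrodomain. Coverage amplifies replication-associated copy-number
#' bias on top of insertion bias, so the coverage fold-changes typically
#' exceed the density ones; their correlation across bins is reported.
#'
#' @param table `data.frame` with `position` and `count` (reads per
#'   insertion site, >= 1).
#' @param domains Named-interval `data.frame` (`name`, `start`, `end`
#'   half-open), e.g. from [read_domains_bed()]; must contain `Ter`.
#' @param genome_length Genome length (bases).
#' @param bin Bin width (default 250 kb).
#' @return A list of class `insertion_density`: `bins` (`bin_start`,
#'   `site_count`, `coverage`, `log2fc_density`, `log2fc_coverage`,
#'   `in_ter`), `correlation` (Pearson, across bins of the two log2
#'   fold-changes), `n_sites`.
#' @export
insertion_density <- function(table, domains, genome_length,
                              bin = 250000L) {
  if (!("Ter" %in% domains$name)) stopf("'Ter' domain required")
  if (any(table$count < 1)) stopf("insertion counts must be >= 1")
  if (any(table$position < 1 | table$position > genome_length))
    stopf("insertion positions outside the genome")
  n_bins <- as.integer(ceiling(genome_length / bin))
  bidx <- (table$position - 1L) %/% bin + 1L
  site_count <- tabulate(bidx, n_bins)
  coverage <- rep(0, n_bins)
  cv <- rowsum(table$count, bidx)
  coverage[as.integer(rownames(cv))] <- cv[, 1]
  bin_start <- as.integer((seq_len(n_bins) - 1L) * bin + 1L)
  bin_mid <- bin_start + bin / 2
  ter <- domains[domains$name == "Ter", , drop = FALSE]
  in_ter <- rep(FALSE, n_bins)
  for (i in seq_len(nrow(ter)))
    in_ter <- in_ter | (bin_mid >= ter$start[i] & bin_mid < ter$end[i])
  if (!any(in_ter)) stopf("no bin falls inside Ter")
  ref_density <- mean(site_count[in_ter])
  ref_coverage <- mean(coverage[in_ter])
  if (ref_density == 0 || ref_coverage == 0)
    stopf("Ter bins carry no insertions; fold-changes undefined")
  bins <- data.frame(
    bin_start = bin_start,
    site_count = site_count,
    coverage = coverage,
    log2fc_density = log2(site_count / ref_density),
    log2fc_coverage = log2(coverage / ref_coverage),
    in_ter = in_ter)
  finite <- is.finite(bins$log2fc_density) & is.finite(bins$log2fc_coverage)
  varies <- sum(finite) > 2 &&
    stats::sd(bins$log2fc_density[finite]) > 0 &&
    stats::sd(bins$log2fc_coverage[finite]) > 0
  structure(list(
    bins = bins,
    correlation = if (varies)
      stats::cor(bins$log2fc_density[finite], bins$log2fc_coverage[finite])
    else NA_real_,
    n_sites = nrow(table)), class = "insertion_density")
}
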