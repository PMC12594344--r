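#' Exact-seed index for the built-in competitive classifier
#'
#' Hashes every k-mer of the donor and the recipient genome so reads can
#' be placed by exact seed lookup. Building the index once and passing it
#' to repeated [classify_builtin()] calls avoids rebuilding per clone.
#'
#' @param pair A `genome_pair`.
#' @param k Seed length (default 31; long enough that random collisions
#'   are negligible at Mb genome scale).
#' @return An object of class `classifier_index`.
#' @export
build_classifier_index <- function(pair, k = 31L) {
  nr <- nchar(pair$recipient_seq)
  nd <- nchar(pair$donor_seq)
  structure(list(
    k = as.integer(k),
    recipient_kmers = substring(pair$recipient_seq, 1:(nr - k + 1L),
                                k:nr),
    donor_kmers = substring(pair$donor_seq, 1:(nd - k + 1L), k:nd)),
    class = "classifier_index")
}

# which half-open intervals [s, e) lie entirely inside accessory blocks
.inside_accessory <- function(start, end_excl, acc) {
  if (nrow(acc) == 0L) return(rep(FALSE, length(start)))
  idx <- findInterval(start, acc$start)
  ok <- idx >= 1L
  ii <- pmax(idx, 1L)
  ok & start >= acc$start[ii] & end_excl <= acc$end[ii]
}

#' Competitively classify reads without an external aligner
#'
#' Places each read on the recipient genome by exact k-mer seed lookup
#' (falling back to the donor genome, with projection through the core
#' coordinate map) and assigns the competitive-mapping category by a
#' majority vote over the alleles observed at covered polymorphic sites:
#' \describe{
#'   \item{DONOR_BETTER / RECIPIENT_BETTER}{majority of covered sites
#'     carries that genome's allele; `score_margin` = donor votes minus
#'     recipient votes}
#'   \item{TIE}{no covered site, or an even vote — uninformative}
#'   \item{DONOR_ONLY / RECIPIENT_ONLY}{read falls entirely in an
#'     accessory (strain-specific) segment}
#'   \item{UNMAPPED}{no clean seed in either genome}
#' }
#' On error-free reads the categories agree with score-based competitive
#' mapping of a SAM alignment ([classify_from_sam()]): a read carrying a
#' donor allele mismatches the recipient reference there and vice versa,
#' so the vote margin and the alignment-score margin have the same sign.
#'
#' @param reads `data.frame` with `id` and `seq` (as from
#'   [simulate_reads()] or [read_fastq()]).
#' @param pair A `genome_pair`.
#' @param sites Polymorphic-site table (`recipient_pos`,
#'   `recipient_allele`, `donor_allele`); default `pair$truth_sites`.
#' @param index Optional prebuilt [build_classifier_index()].
#' @return A list of class `read_classification`:
#'   \describe{
#'     \item{labels}{`data.frame`: `read_id`, `recipient_pos` (leftmost,
#'       NA when not placeable on the recipient frame), `category`,
#'       `score_margin`, `first_support`, `last_support` (first/last
#'       covered site supporting the assigned category)}
#'     \item{observations}{`data.frame` of per-read allele observations at
#'       covered sites: `read_id`, `site_pos`, `base`, `is_donor`,
#'       `is_recipient`}
#'   }
#' @export
classify_builtin <- function(reads, pair, sites = NULL, index = NULL) {
  if (is.null(sites)) sites <- pair$truth_sites
  if (is.null(index)) index <- build_classifier_index(pair)
  k <- index$k
  n <- nrow(reads)
  rl <- nchar(reads$seq)
  max_rl <- if (n > 0L) max(rl) else 0L
  offsets <- unique(c(seq(1L, max(1L, max_rl - k + 1L), by = k),
                      max(1L, max_rl - k + 1L)))

  pos <- rep(NA_integer_, n)      # recipient-frame leftmost position
  via_donor <- rep(FALSE, n)
  donor_pos <- rep(NA_integer_, n)

  for (off in offsets) {
    todo <- which(is.na(pos) & is.na(donor_pos) & rl >= off + k - 1L)
    if (length(todo) == 0L) next
    seeds <- substring(reads$seq[todo], off, off + k - 1L)
    hit <- match(seeds, index$recipient_kmers)
    ok <- !is.na(hit)
    pos[todo[ok]] <- hit[ok] - off + 1L
    rest <- todo[!ok]
    if (length(rest) > 0L) {
      hit_d <- match(seeds[!ok], index$donor_kmers)
      okd <- !is.na(hit_d)
      donor_pos[rest[okd]] <- hit_d[okd] - off + 1L
    }
  }
  # project donor-frame placements onto the recipient through the core map
  dp <- which(!is.na(donor_pos) & is.na(pos))
  if (length(dp) > 0L) {
    core <- donor_to_core(pair, donor_pos[dp])
    ok <- !is.na(core)
    pos[dp[ok]] <- core_to_recipient(pair, core[ok])
    via_donor[dp] <- TRUE
  }

  category <- rep("UNMAPPED", n)
  margin <- rep(NA_real_, n)
  first_support <- rep(NA_integer_, n)
  last_support <- rep(NA_integer_, n)

  placed <- which(!is.na(pos))
  obs <- data.frame(read_id = character(0), site_pos = integer(0),
                    base = character(0), is_donor = logical(0),
                    is_recipient = logical(0), stringsAsFactors = FALSE)
  if (length(placed) > 0L && nrow(sites) > 0L) {
    sp <- sites$recipient_pos
    p <- pos[placed]
    lo <- findInterval(p - 1L, sp) + 1L           # first site >= p
    hi <- findInterval(p + rl[placed] - 1L, sp)   # last site <= read end
    cnt <- pmax(0L, hi - lo + 1L)
    has <- cnt > 0L
    if (any(has)) {
      ridx <- rep(placed[has], cnt[has])
      sidx <- sequence(cnt[has]) + rep(lo[has] - 1L, cnt[has])
      off <- sp[sidx] - pos[ridx] + 1L
      base <- substring(reads$seq[ridx], off, off)
      isd <- base == sites$donor_allele[sidx]
      isr <- base == sites$recipient_allele[sidx]
      obs <- data.frame(read_id = reads$id[ridx], site_pos = sp[sidx],
                        base = base, is_donor = isd, is_recipient = isr,
                        stringsAsFactors = FALSE)
      dv <- rowsum(as.integer(isd), ridx)
      rv <- rowsum(as.integer(isr), ridx)
      ids <- as.integer(rownames(dv))
      margin[ids] <- dv[, 1] - rv[, 1]
      # first/last supporting site for the winning class
      win_d <- margin[ridx] > 0 & isd
      win_r <- margin[ridx] < 0 & isr
      sup <- win_d | win_r
      if (any(sup)) {
        agg_min <- tapply(sp[sidx][sup], ridx[sup], min)
        agg_max <- tapply(sp[sidx][sup], ridx[sup], max)
        ii <- as.integer(names(agg_min))
        first_support[ii] <- as.integer(agg_min)
        last_support[ii] <- as.integer(agg_max)
      }
    }
  }
  category[placed] <- "TIE"
  category[!is.na(margin) & margin > 0] <- "DONOR_BETTER"
  category[!is.na(margin) & margin < 0] <- "RECIPIENT_BETTER"

  # accessory-only reads: strain-specific sequence
  racc <- .accessory_intervals(pair$recipient_insertions)
  dacc <- .accessory_intervals(pair$donor_insertions)
  rp <- which(!is.na(pos) & !via_donor)
  inr <- .inside_accessory(pos[rp], pos[rp] + rl[rp], racc)
  category[rp[inr]] <- "RECIPIENT_ONLY"
  dp2 <- which(!is.na(donor_pos))
  ind <- .inside_accessory(donor_pos[dp2], donor_pos[dp2] + rl[dp2], dacc)
  category[dp2[ind]] <- "DONOR_ONLY"

  structure(list(
    labels = data.frame(read_id = reads$id, recipient_pos = pos,
                        category = category, score_margin = margin,
                        first_support = first_support,
                        last_support = last_support,
                        stringsAsFactors = FALSE),
    observations = obs), class = "read_classification")
}

#' @export
print.read_classification <- function(x, ...) {
  cat("read_classification:", nrow(x$labels), "reads\n")
  print(table(x$labels$category))
  invisible(x)
}

#' Classify competitively mapped reads from a SAM/BAM file
#'
#' Consumes an alignment of reads mapped simultaneously against the donor
#' and the recipient genome (references named `donor|*` / `recipient|*`,
#' prefixes configurable) and compares, per read, the best alignment score
#' (`AS` tag) on each genome: a higher donor score yields `DONOR_BETTER`,
#' equal scores `TIE` (uninformative), a single-genome alignment
#' `DONOR_ONLY` / `RECIPIENT_ONLY`.
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @param donor_prefix,recipient_prefix Reference-name prefixes
#'   identifying the two genomes.
#' @param min_mapq Reads whose best alignment is below this mapping
#'   quality on both genomes are `UNMAPPED` (default 0).
#' @param pair Optional `genome_pair`: used to project the position of
#'   donor-better reads lacking a recipient-side alignment onto the
#'   recipient frame.
#' @return `data.frame`: `read_id`, `recipient_pos`, `category`,
#'   `score_margin` (donor minus recipient score).
#' @export
classify_from_sam <- function(path, donor_prefix = "donor",
                              recipient_prefix = "recipient",
                              min_mapq = 0, pair = NULL) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "mapq", "flag"), tag = "AS")
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  as_score <- b$tag$AS
  if (is.null(as_score) || all(is.na(as_score)))
    stopf("alignment scores missing: no 'AS' tag in %s", basename(path))
  rn <- as.character(b$rname)
  mapped <- !bitwAnd(b$flag, 4L)
  df <- data.frame(qname = b$qname, rname = rn, pos = b$pos,
                   mapq = b$mapq, score = as_score,
                   stringsAsFactors = FALSE)[mapped, , drop = FALSE]
  df$genome <- ifelse(startsWith(df$rname, donor_prefix), "donor",
               ifelse(startsWith(df$rname, recipient_prefix), "recipient",
                      NA_character_))
  if (anyNA(df$genome))
    stopf("reference names must start with '%s' or '%s'",
          donor_prefix, recipient_prefix)

  qnames <- unique(b$qname)
  best <- function(g) {
    sub <- df[df$genome == g, , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(data.frame(qname = character(0), pos = integer(0),
                        mapq = integer(0), score = numeric(0)))
    }
    sub <- sub[order(sub$qname, -sub$score), , drop = FALSE]
    sub[!duplicated(sub$qname), c("qname", "pos", "mapq", "score")]
  }
  bd <- best("donor"); br <- best("recipient")
  id <- match(qnames, bd$qname); ir <- match(qnames, br$qname)
  sd <- bd$score[id]; sr <- br$score[ir]
  mq <- pmax(bd$mapq[id], br$mapq[ir], na.rm = TRUE)

  category <- rep("UNMAPPED", length(qnames))
  margin <- rep(NA_real_, length(qnames))
  rpos <- br$pos[ir]
  both <- !is.na(sd) & !is.na(sr)
  margin[both] <- sd[both] - sr[both]
  category[both & margin > 0] <- "DONOR_BETTER"
  category[both & margin < 0] <- "RECIPIENT_BETTER"
  category[both & margin == 0] <- "TIE"
  category[!is.na(sd) & is.na(sr)] <- "DONOR_ONLY"
  category[is.na(sd) & !is.na(sr)] <- "RECIPIENT_ONLY"
  low <- !is.na(mq) & mq < min_mapq & category != "UNMAPPED"
  category[low] <- "UNMAPPED"

  # donor-better reads without a recipient alignment: project if possible
  need <- which(category == "DONOR_BETTER" & is.na(rpos))
  if (length(need) > 0L && !is.null(pair)) {
    core <- donor_to_core(pair, bd$pos[id[need]])
    ok <- !is.na(core)
    rpos[need[ok]] <- core_to_recipient(pair, core[ok])
  }
  data.frame(read_id = qnames, recipient_pos = rpos,
             category = category, score_margin = margin,
             stringsAsFactors = FALSE)
}

#' Donor-allele frequencies at polymorphic sites
#'
#' Tallies, per site, the reads carrying the donor versus the recipient
#' allele. Bases matching neither allele (sequencing errors) are excluded
#' from both counts. Sites with no covering read keep `NA` frequency and
#' are flagged.
#'
#' @param classification A `read_classification` from
#'   [classify_builtin()].
#' @param sites Site table (`recipient_pos`, `recipient_allele`,
#'   `donor_allele`).
#' @return `data.frame`: `recipient_pos`, `donor_count`,
#'   `recipient_count`, `donor_frequency`, `covered`.
#' @export
site_frequencies <- function(classification, sites) {
  obs <- classification$observations
  dc <- rep(0L, nrow(sites)); rc <- rep(0L, nrow(sites))
  if (nrow(obs) > 0L) {
    idx <- match(obs$site_pos, sites$recipient_pos)
    dtab <- rowsum(as.integer(obs$is_donor), idx)
    rtab <- rowsum(as.integer(obs$is_recipient), idx)
    ii <- as.integer(rownames(dtab))
    dc[ii] <- dtab[, 1]; rc[ii] <- rtab[, 1]
  }
  tot <- dc + rc
  data.frame(recipient_pos = sites$recipient_pos,
             donor_count = dc, recipient_count = rc,
             donor_frequency = ifelse(tot > 0, dc / tot, NA_real_),
             covered = tot > 0)
}

#' Ordered binary label series for segmentation
#'
#' Extracts the informative reads (donor-better / recipient-better) as an
#' ordered 0/1 series: the observation unit the tract-segmentation HMM
#' consumes. The observation coordinate is the read's first supporting
#' polymorphic site by default (`position = "support"`), which pins
#' detected boundaries to site coordinates; `"read"` uses the leftmost
#' read position. Reads at identical coordinates are kept as separate
#' observations, ordered by read id.
#'
#' @param classification A `read_classification`.
#' @param position `"support"` or `"read"`.
#' @return `data.frame` of class `binary_series`: `position`, `label`
#'   (1 = donor-better), `first_support`, `last_support`, `read_id`.
#' @export
binary_series <- function(classification,
                          position = c("support", "read")) {
  position <- match.arg(position)
  lab <- classification$labels
  keep <- lab$category %in% c("DONOR_BETTER", "RECIPIENT_BETTER")
  lab <- lab[keep, , drop = FALSE]
  posv <- if (position == "support") lab$first_support else
    lab$recipient_pos
  out <- data.frame(position = posv,
                    label = as.integer(lab$category == "DONOR_BETTER"),
                    first_support = lab$first_support,
                    last_support = lab$last_support,
                    read_id = lab$read_id,
                    stringsAsFactors = FALSE)
  out <- out[order(out$position, out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("binary_series", class(out))
  out
}
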