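#' Configuration for a synthetic donor/recipient genome pair
#'
#' Emulates a pair of conspecific bacterial strains: a shared core genome
#' that accumulated point substitutions at a fixed per-site rate, plus
#' optional strain-specific (accessory) segments inserted into either
#' genome.
#'
#' @param genome_length Core genome length in bases (> 0).
#' @param divergence Per-site substitution probability between the two
#'   cores, in `[0, 1)`. Typical intra-species values are 0.005-0.02.
#' @param accessory_segments Optional `data.frame` with columns `genome`
#'   (`"donor"` or `"recipient"`), `length` (bases, > 0) and `count`
#'   (integer >= 1): random strain-specific segments to insert.
#' @param seed Integer RNG seed.
#' @return An object of class `genome_pair_config`.
#' @export
genome_pair_config <- function(genome_length, divergence = 0.01,
                               accessory_segments = NULL, seed = 1L) {
  if (!is_number(genome_length) || genome_length <= 0)
    stopf("'genome_length' must be a positive number")
  if (!is_number(divergence) || divergence < 0 || divergence >= 1)
    stopf("'divergence' must be in [0, 1)")
  if (!is.null(accessory_segments)) {
    stopifnot(is.data.frame(accessory_segments),
              all(c("genome", "length", "count") %in%
                    names(accessory_segments)))
    if (any(accessory_segments$length <= 0))
      stopf("accessory segment lengths must be positive")
    if (any(accessory_segments$count < 1))
      stopf("accessory segment counts must be >= 1")
    if (!all(accessory_segments$genome %in% c("donor", "recipient")))
      stopf("accessory 'genome' must be 'donor' or 'recipient'")
  }
  structure(list(genome_length = as.integer(genome_length),
                 divergence = divergence,
                 accessory_segments = accessory_segments,
                 seed = as.integer(seed)),
            class = "genome_pair_config")
}

# Insertion table -> cumulative offset lookup.
# Insertions sit after core position `after` (0 = before the genome).
.core_to_full <- function(core_pos, insertions) {
  if (nrow(insertions) == 0L) return(as.integer(core_pos))
  cum <- cumsum(insertions$length)
  k <- findInterval(core_pos - 0.5, insertions$after)
  as.integer(core_pos + c(0L, cum)[k + 1L])
}

.full_to_core <- function(full_pos, insertions, core_length) {
  out <- as.integer(full_pos)
  if (nrow(insertions) > 0L) {
    cum <- cumsum(insertions$length)
    # accessory block i occupies full positions after_full[i]+1 .. +length[i]
    after_full <- insertions$after + c(0L, cum[-length(cum)])
    k <- findInterval(full_pos, after_full + 1L)  # blocks starting <= pos
    kk <- pmax(k, 1L)
    inside <- k >= 1L &
      full_pos <= after_full[kk] + insertions$length[kk]
    out <- as.integer(full_pos - c(0L, cum)[k + 1L])
    out[inside] <- NA_integer_
  }
  out[!is.na(out) & (out < 1L | out > core_length)] <- NA_integer_
  out
}

# Accessory block intervals in full coordinates, half-open [start, end)
.accessory_intervals <- function(insertions) {
  if (nrow(insertions) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  cum <- cumsum(insertions$length)
  after_full <- insertions$after + c(0L, cum[-length(cum)])
  data.frame(start = after_full + 1L,
             end = after_full + 1L + insertions$length)
}

#' Generate a synthetic donor/recipient genome pair
#'
#' Builds a random ancestor core genome; the recipient carries the ancestor
#' core, the donor differs at Bernoulli(`divergence`) core positions
#' (substitutions only, alternative base uniform among the other three).
#' Accessory segments are inserted at uniform positions and never contain
#' polymorphic sites. The full truth (coordinate map, site table) is
#' carried on the returned object for downstream validation.
#'
#' @param config A [genome_pair_config()].
#' @param out_dir Optional directory: when given, both genomes are written
#'   as FASTA and the truth sites as TSV.
#' @return An object of class `genome_pair` with elements
#'   `donor_seq`, `recipient_seq` (character), `core_length`,
#'   `truth_sites` (`data.frame`: `core_pos`, `recipient_pos`, `donor_pos`,
#'   `recipient_allele`, `donor_allele`), `donor_insertions`,
#'   `recipient_insertions`, and the originating `config`.
#' @examples
#' pair <- generate_genome_pair(genome_pair_config(10000, 0.01, seed = 42))
#' nrow(pair$truth_sites)
#' @export
generate_genome_pair <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "genome_pair_config"))
  G <- config$genome_length
  pair <- with_seed(config$seed, {
    core <- random_dna(G)
    n_sub <- stats::rbinom(1L, G, config$divergence)
    sub_pos <- sort(sample.int(G, n_sub))
    ref_allele <- seq_chars(core, sub_pos)
    # uniform among the three alternatives
    alt_allele <- vapply(ref_allele,
                         function(b) sample(setdiff(BASES, b), 1L),
                         character(1), USE.NAMES = FALSE)
    donor_core <- substitute_bases(core, sub_pos, alt_allele)

    ins <- list(donor = data.frame(after = integer(0), length = integer(0)),
                recipient = data.frame(after = integer(0),
                                       length = integer(0)))
    acc_seq <- list(donor = character(0), recipient = character(0))
    acc <- config$accessory_segments
    if (!is.null(acc)) {
      for (i in seq_len(nrow(acc))) {
        g <- acc$genome[i]
        for (j in seq_len(acc$count[i])) {
          ins[[g]] <- rbind(ins[[g]],
                            data.frame(after = sample.int(G + 1L, 1L) - 1L,
                                       length = as.integer(acc$length[i])))
        }
      }
      for (g in c("donor", "recipient")) {
        if (nrow(ins[[g]]) > 0L) {
          o <- order(ins[[g]]$after)
          ins[[g]] <- ins[[g]][o, , drop = FALSE]
          rownames(ins[[g]]) <- NULL
          acc_seq[[g]] <- vapply(ins[[g]]$length, random_dna, character(1))
        }
      }
    }

    assemble <- function(core_seq, instab, pieces) {
      if (nrow(instab) == 0L) return(core_seq)
      parts <- character(0)
      prev <- 0L
      for (i in seq_len(nrow(instab))) {
        parts <- c(parts, substr(core_seq, prev + 1L, instab$after[i]),
                   pieces[i])
        prev <- instab$after[i]
      }
      paste(c(parts, substr(core_seq, prev + 1L, nchar(core_seq))),
            collapse = "")
    }

    donor_seq <- assemble(donor_core, ins$donor, acc_seq$donor)
    recipient_seq <- assemble(core, ins$recipient, acc_seq$recipient)

    truth_sites <- data.frame(
      core_pos = sub_pos,
      recipient_pos = .core_to_full(sub_pos, ins$recipient),
      donor_pos = .core_to_full(sub_pos, ins$donor),
      recipient_allele = ref_allele,
      donor_allele = alt_allele,
      stringsAsFactors = FALSE
    )
    rownames(truth_sites) <- NULL

    structure(list(donor_seq = donor_seq, recipient_seq = recipient_seq,
                   core_length = G, truth_sites = truth_sites,
                   donor_insertions = ins$donor,
                   recipient_insertions = ins$recipient,
                   config = config),
              class = "genome_pair")
  })
  if (!is.null(out_dir)) write_genome_pair(pair, out_dir)
  pair
}

#' @export
print.genome_pair <- function(x, ...) {
  cat(sprintf(
    "genome_pair: core %d bp, divergence %.4g, %d polymorphic sites\n",
    x$core_length, x$config$divergence, nrow(x$truth_sites)))
  cat(sprintf("  donor %d bp (%d accessory), recipient %d bp (%d accessory)\n",
              nchar(x$donor_seq), nrow(x$donor_insertions),
              nchar(x$recipient_seq), nrow(x$recipient_insertions)))
  invisible(x)
}

#' Map recipient full-genome coordinates to core coordinates
#' (NA inside recipient accessory segments)
#' @param pair A `genome_pair`.
#' @param pos Integer positions.
#' @return Integer core positions (NA where accessory).
#' @export
recipient_to_core <- function(pair, pos) {
  .full_to_core(pos, pair$recipient_insertions, pair$core_length)
}

#' Map donor full-genome coordinates to core coordinates
#' @inheritParams recipient_to_core
#' @export
donor_to_core <- function(pair, pos) {
  .full_to_core(pos, pair$donor_insertions, pair$core_length)
}

#' Map core coordinates to recipient full-genome coordinates
#' @inheritParams recipient_to_core
#' @export
core_to_recipient <- function(pair, pos) {
  .core_to_full(pos, pair$recipient_insertions)
}

#' Map core coordinates to donor full-genome coordinates
#' @inheritParams recipient_to_core
#' @export
core_to_donor <- function(pair, pos) {
  .core_to_full(pos, pair$donor_insertions)
}
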