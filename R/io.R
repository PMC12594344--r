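# File-format plumbing. Sequence formats go through Biostrings, BED through
# rtracklayer/GenomicRanges; plain tables are TSV.

#' Write a genome pair to disk
#'
#' Emits `donor.fasta`, `recipient.fasta` and `truth_sites.tsv`
#' (columns: recipient_pos, donor_pos, recipient_allele, donor_allele;
#' positions 1-based).
#'
#' @param pair A `genome_pair`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- Biostrings::DNAStringSet(pair$donor_seq)
  names(d) <- "donor"
  r <- Biostrings::DNAStringSet(pair$recipient_seq)
  names(r) <- "recipient"
  Biostrings::writeXStringSet(d, file.path(dir, "donor.fasta"))
  Biostrings::writeXStringSet(r, file.path(dir, "recipient.fasta"))
  utils::write.table(
    pair$truth_sites[, c("recipient_pos", "donor_pos",
                         "recipient_allele", "donor_allele")],
    file.path(dir, "truth_sites.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write reads as FASTQ (Phred+33, constant quality)
#'
#' @param reads Character vector of read sequences.
#' @param ids Read names.
#' @param path Output file.
#' @param quality_char Constant per-base quality character (default `"I"`,
#'   Q40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, ids, path, quality_char = "I") {
  dna <- Biostrings::DNAStringSet(reads)
  names(dna) <- ids
  qual <- Biostrings::BStringSet(vapply(
    nchar(reads), function(n) strrep(quality_char, n), character(1)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file.
#' @return `data.frame` with columns `id` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = names(x), seq = as.character(x),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Fragment data.frame (1-based half-open [start, end)) -> GRanges (1-based
# closed) -> BED (0-based half-open, handled by rtracklayer).
.fragments_to_granges <- function(fragments, seqname = "recipient") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = fragments$start,
                              end = fragments$end - 1L))
  if (!is.null(fragments$origin)) gr$name <- fragments$origin
  if (!is.null(fragments$n_obs)) gr$score <- fragments$n_obs
  gr
}

#' Write fragments as BED
#'
#' Fragments are held internally as 1-based half-open `[start, end)`
#' intervals on the recipient genome; BED output follows the BED convention
#' (0-based half-open), so the interval `[start, end)` appears as
#' `start-1`, `end-1` in columns 2-3.
#'
#' @param fragments `data.frame` with `start`, `end` and optionally
#'   `origin`, `n_obs`.
#' @param path Output BED file.
#' @param seqname Chromosome name to use.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path, seqname = "recipient") {
  if (nrow(fragments) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  rtracklayer::export(.fragments_to_granges(fragments, seqname), path,
                      format = "BED")
  invisible(path)
}

#' Read a fragments BED file
#'
#' @param path BED file written by [write_fragments_bed()] (or any BED).
#' @return `data.frame` with `start`, `end` (1-based half-open), `origin`,
#'   `n_obs`.
#' @export
read_fragments_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      origin = character(0), n_obs = numeric(0)))
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr) + 1L,
    origin = if (!is.null(gr$name)) gr$name else NA_character_,
    n_obs = if (!is.null(gr$score)) gr$score else NA_real_,
    stringsAsFactors = FALSE)
}

#' Read a named-interval BED file (e.g. macrodomain annotations)
#'
#' @param path BED file with at least chrom/start/end/name.
#' @return `data.frame` with `name`, `start`, `end` (1-based half-open).
#' @export
read_domains_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(name = gr$name,
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr) + 1L,
             stringsAsFactors = FALSE)
}

#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
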