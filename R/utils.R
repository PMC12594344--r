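# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so simulation helpers are
#' pure functions of (arguments, seed).
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' @noRd
random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Substitute single bases in a long string by position (1-based).
#' Works on the raw byte representation: O(n) and fast for Mb-scale genomes.
#' @noRd
substitute_bases <- function(seq, positions, bases) {
  if (length(positions) == 0L) return(seq)
  r <- charToRaw(seq)
  r[positions] <- charToRaw(paste(bases, collapse = ""))
  rawToChar(r)
}

#' @noRd
seq_chars <- function(seq, positions) {
  if (length(positions) == 0L) return(character(0))
  substring(seq, positions, positions)
}

#' Vectorised single-character extraction from many strings.
#' @noRd
char_at <- function(strings, offsets) {
  substring(strings, offsets, offsets)
}

#' Check a scalar is a single finite number
#' @noRd
is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Merge half-open intervals [start, end), keeping a logical flag by any()
#' @noRd
merge_intervals <- function(start, end, flag = NULL, min_gap = 0L) {
  if (length(start) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      contains_marker = logical(0)))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  if (is.null(flag)) flag <- rep(FALSE, length(start)) else flag <- flag[o]
  ms <- start[1]; me <- end[1]; mf <- flag[1]
  out_s <- integer(0); out_e <- integer(0); out_f <- logical(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + min_gap) {
      me <- max(me, end[i]); mf <- mf || flag[i]
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me); out_f <- c(out_f, mf)
      ms <- start[i]; me <- end[i]; mf <- flag[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me); out_f <- c(out_f, mf)
  data.frame(start = out_s, end = out_e, contains_marker = out_f)
}
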