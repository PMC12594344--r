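#' Parameters of the two-state ancestry HMM
#'
#' The tract-detection HMM has hidden states donor-derived /
#' recipient-derived and Bernoulli emissions on the per-read binary labels
#' (1 = read matched the donor better). `e_d` and `e_r` absorb sequencing
#' errors, boundary-straddling reads and classification noise; `t` is the
#' per-observation probability of switching state, i.e. the prior rate of
#' recombination breakpoints per informative read.
#'
#' @param e_d P(label 1 | donor state), in (0,1).
#' @param e_r P(label 1 | recipient state), in (0,1); must be < `e_d`.
#' @param t Per-observation state-switch probability, in (0,1).
#' @param pi_d Initial probability of the donor state.
#' @return Object of class `hmm_params`.
#' @export
hmm_params <- function(e_d = 0.95, e_r = 0.05, t = 1e-3, pi_d = 0.5) {
  vals <- c(e_d = e_d, e_r = e_r, t = t, pi_d = pi_d)
  if (any(vals <= 0 | vals >= 1))
    stopf("all HMM parameters must lie strictly in (0, 1)")
  if (e_d <= e_r) stopf("e_d must exceed e_r")
  structure(as.list(vals), class = "hmm_params")
}

# log emission matrix: rows = obs, cols = c(donor, recipient)
.hmm_log_emission <- function(labels, params) {
  cbind(donor = ifelse(labels == 1L, log(params$e_d), log1p(-params$e_d)),
        recipient = ifelse(labels == 1L, log(params$e_r),
                           log1p(-params$e_r)))
}

# per-step switch probabilities (length n-1)
.hmm_switch_probs <- function(positions, params, distance_scale) {
  n <- length(positions)
  if (n <= 1L) return(numeric(0))
  if (is.null(distance_scale)) return(rep(params$t, n - 1L))
  gap <- pmax(0, diff(positions))
  # switch probability saturating at 1/2 with genomic distance
  0.5 * (1 - exp(-gap / distance_scale)) + params$t * exp(-gap / distance_scale)
}

#' Viterbi decoding of the two-state ancestry HMM
#'
#' @param labels Integer 0/1 vector.
#' @param params [hmm_params()].
#' @param positions Optional coordinates (needed for
#'   `distance_scale`).
#' @param distance_scale Optional length scale (bases): switch
#'   probability grows with the genomic gap between consecutive
#'   observations instead of being homogeneous per observation.
#' @return Integer vector of decoded states (1 = donor, 0 = recipient).
#' @export
hmm_viterbi <- function(labels, params = hmm_params(), positions = NULL,
                        distance_scale = NULL) {
  n <- length(labels)
  if (n == 0L) return(integer(0))
  le <- .hmm_log_emission(labels, params)
  tp <- .hmm_switch_probs(if (is.null(positions)) seq_len(n) else positions,
                          params, distance_scale)
  led <- le[, 1L]; ler <- le[, 2L]
  lt_stay <- log1p(-tp); lt_switch <- log(tp)
  psi_d <- integer(n); psi_r <- integer(n)
  dd <- log(params$pi_d) + led[1L]
  dr <- log1p(-params$pi_d) + ler[1L]
  for (i in seq_len(n)[-1]) {
    a <- dd + lt_stay[i - 1L]; b <- dr + lt_switch[i - 1L]
    if (a >= b) { psi_d[i] <- 1L; nd <- a } else { psi_d[i] <- 2L; nd <- b }
    a <- dd + lt_switch[i - 1L]; b <- dr + lt_stay[i - 1L]
    if (a >= b) { psi_r[i] <- 1L; nr <- a } else { psi_r[i] <- 2L; nr <- b }
    dd <- nd + led[i]; dr <- nr + ler[i]
  }
  states <- integer(n)
  states[n] <- if (dd >= dr) 1L else 2L
  for (i in rev(seq_len(n - 1L))) {
    states[i] <- if (states[i + 1L] == 1L) psi_d[i + 1L] else psi_r[i + 1L]
  }
  as.integer(states == 1L)
}

#' Posterior donor-state probabilities (forward-backward)
#'
#' @inheritParams hmm_viterbi
#' @return Numeric vector: P(donor state | all labels) per observation.
#' @export
hmm_posterior <- function(labels, params = hmm_params(), positions = NULL,
                          distance_scale = NULL) {
  n <- length(labels)
  if (n == 0L) return(numeric(0))
  le <- .hmm_log_emission(labels, params)
  tp <- .hmm_switch_probs(if (is.null(positions)) seq_len(n) else positions,
                          params, distance_scale)
  # scaled forward-backward, two scalar chains
  ed <- exp(le[, 1L]); er <- exp(le[, 2L])
  fad <- numeric(n); far <- numeric(n)
  a1 <- params$pi_d * ed[1L]; a2 <- (1 - params$pi_d) * er[1L]
  s <- a1 + a2; fad[1L] <- a1 / s; far[1L] <- a2 / s
  for (i in seq_len(n)[-1]) {
    stay <- 1 - tp[i - 1L]; sw <- tp[i - 1L]
    a1 <- (fad[i - 1L] * stay + far[i - 1L] * sw) * ed[i]
    a2 <- (fad[i - 1L] * sw + far[i - 1L] * stay) * er[i]
    s <- a1 + a2; fad[i] <- a1 / s; far[i] <- a2 / s
  }
  bbd <- numeric(n); bbr <- numeric(n)
  bbd[n] <- 1; bbr[n] <- 1
  for (i in rev(seq_len(n - 1L))) {
    stay <- 1 - tp[i]; sw <- tp[i]
    x1 <- ed[i + 1L] * bbd[i + 1L]; x2 <- er[i + 1L] * bbr[i + 1L]
    b1 <- stay * x1 + sw * x2
    b2 <- sw * x1 + stay * x2
    s <- b1 + b2; bbd[i] <- b1 / s; bbr[i] <- b2 / s
  }
  pd <- fad * bbd
  pd / (pd + far * bbr)
}

#' Baum-Welch refinement of the emission and switch parameters
#'
#' Optional expectation-maximization update of `e_d`, `e_r` and `t`
#' (initial probability kept fixed). Off by default in the pipeline for
#' reproducibility; useful when the defaults are far from the data.
#'
#' @inheritParams hmm_viterbi
#' @param n_iter Number of EM iterations.
#' @return Updated `hmm_params`.
#' @export
hmm_em <- function(labels, params = hmm_params(), n_iter = 10L) {
  n <- length(labels)
  if (n < 2L) return(params)
  for (iter in seq_len(n_iter)) {
    le <- .hmm_log_emission(labels, params)
    tp <- rep(params$t, n - 1L)
    fa <- matrix(0, n, 2L); sc <- numeric(n)
    a <- c(params$pi_d, 1 - params$pi_d) * exp(le[1, ])
    sc[1] <- sum(a); fa[1, ] <- a / sc[1]
    for (i in 2:n) {
      Tm <- matrix(c(1 - tp[i - 1], tp[i - 1], tp[i - 1], 1 - tp[i - 1]),
                   2L, 2L)
      a <- as.vector(fa[i - 1L, ] %*% Tm) * exp(le[i, ])
      sc[i] <- sum(a); fa[i, ] <- a / sc[i]
    }
    bb <- matrix(0, n, 2L); bb[n, ] <- 1
    xi_switch <- 0; xi_total <- 0
    for (i in (n - 1L):1L) {
      Tm <- matrix(c(1 - tp[i], tp[i], tp[i], 1 - tp[i]), 2L, 2L)
      b <- as.vector(Tm %*% (exp(le[i + 1L, ]) * bb[i + 1L, ]))
      bb[i, ] <- b / sum(b)
    }
    post <- fa * bb; post <- post / rowSums(post)
    # expected transitions
    for (i in seq_len(n - 1L)) {
      Tm <- matrix(c(1 - tp[i], tp[i], tp[i], 1 - tp[i]), 2L, 2L)
      joint <- outer(fa[i, ], exp(le[i + 1L, ]) * bb[i + 1L, ]) * Tm
      joint <- joint / sum(joint)
      xi_switch <- xi_switch + joint[1, 2] + joint[2, 1]
      xi_total <- xi_total + 1
    }
    clamp <- function(x) min(max(x, 1e-6), 1 - 1e-6)
    e_d <- clamp(sum(post[, 1] * labels) / sum(post[, 1]))
    e_r <- clamp(sum(post[, 2] * labels) / sum(post[, 2]))
    if (e_d <= e_r) break  # refuse label-swapping updates
    params <- hmm_params(e_d = e_d, e_r = e_r,
                         t = clamp(xi_switch / xi_total),
                         pi_d = params$pi_d)
  }
  params
}

#' Segment a clone into donor and recipient tracts with the HMM
#'
#' Viterbi-decodes the ordered binary label series and converts maximal
#' runs of each state into fragments. Fragment boundaries are reported at
#' supporting-site coordinates when the series carries them
#' (`first_support` / `last_support`, see [binary_series()]): the start is
#' the first donor-allele-bearing site of the run and the end is one past
#' the last, which bounds the boundary error by the local inter-site
#' spacing. A clone whose posterior state probabilities stay intermediate
#' (max posterior < 0.8 over more than 20% of observations) is flagged
#' `unresolved` — the sequenced colony still segregated donor and
#' recipient genotypes.
#'
#' @param series A [binary_series()] (or any `data.frame` with `position`
#'   and `label`).
#' @param params [hmm_params()].
#' @param marker Optional marker coordinate to flag `contains_marker`.
#' @param em Run [hmm_em()] first (default `FALSE`).
#' @param distance_scale Optional distance scaling for transitions.
#' @return `data.frame` of fragments: `start`, `end` (half-open),
#'   `origin`, `n_obs`, `contains_marker`; attribute `unresolved`
#'   (logical), attribute `posterior` (donor posterior per observation).
#' @export
hmm_segment <- function(series, params = hmm_params(), marker = NULL,
                        em = FALSE, distance_scale = NULL) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      origin = character(0), n_obs = integer(0),
                      contains_marker = logical(0))
  if (nrow(series) == 0L) {
    attr(empty, "unresolved") <- FALSE
    return(empty)
  }
  if (em) params <- hmm_em(series$label, params)
  states <- hmm_viterbi(series$label, params, series$position,
                        distance_scale)
  post <- hmm_posterior(series$label, params, series$position,
                        distance_scale)
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  frags <- lapply(seq_along(r$values), function(j) {
    idx <- starts[j]:ends[j]
    origin <- if (r$values[j] == 1L) "donor" else "recipient"
    lab_match <- series$label[idx] == r$values[j]
    fs <- series$first_support[idx]
    ls <- series$last_support[idx]
    if (!is.null(fs) && any(lab_match & !is.na(fs))) {
      s <- min(fs[lab_match], na.rm = TRUE)
      e <- max(ls[lab_match], na.rm = TRUE) + 1L
    } else {
      s <- series$position[starts[j]]
      e <- series$position[ends[j]] + 1L
    }
    data.frame(start = s, end = e, origin = origin,
               n_obs = length(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, frags)
  out$contains_marker <- if (is.null(marker)) FALSE else
    (out$start <= marker & marker < out$end)
  attr(out, "posterior") <- post
  attr(out, "unresolved") <- mean(pmax(post, 1 - post) < 0.8) > 0.2
  out
}
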