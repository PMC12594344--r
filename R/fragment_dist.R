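#' Fragment-length distributions
#'
#' Recombined fragments observed in conjugation crosses span roughly three
#' orders of magnitude, from about a kilobase up to a megabase. Several
#' parametric families are provided to model the length `L` of a donor
#' fragment; the log-uniform family is the workhorse because it spreads mass
#' evenly across length scales.
#'
#' Families:
#' \describe{
#'   \item{fixed}{every draw equals `length`}
#'   \item{log_uniform}{`log(L)` uniform on `[log(low), log(high)]`}
#'   \item{log_normal}{`log(L)` normal with `meanlog`, `sdlog` (draws are
#'     truncated to `[min, max]` when given)}
#'   \item{empirical}{draws from an explicit `lengths` vector with optional
#'     `weights`}
#' }
#'
#' @param family One of `"fixed"`, `"log_uniform"`, `"log_normal"`,
#'   `"empirical"`.
#' @param ... Family parameters (see Details).
#' @return An object of class `fragment_dist`.
#' @examples
#' d <- fragment_dist("log_uniform", low = 1e4, high = 1e6)
#' draw_lengths(d, 5)
#' @export
fragment_dist <- function(family = c("fixed", "log_uniform", "log_normal",
                                     "empirical"), ...) {
  family <- match.arg(family)
  p <- list(...)
  switch(family,
    fixed = {
      if (!is_number(p$length) || p$length <= 0)
        stopf("'length' must be a single positive number")
    },
    log_uniform = {
      if (!is_number(p$low) || !is_number(p$high) ||
          p$low <= 0 || p$high < p$low)
        stopf("need 0 < low <= high")
    },
    log_normal = {
      if (!is_number(p$meanlog) || !is_number(p$sdlog) || p$sdlog < 0)
        stopf("need numeric meanlog and sdlog >= 0")
    },
    empirical = {
      if (is.null(p$lengths) || any(p$lengths <= 0))
        stopf("'lengths' must all be positive")
      if (is.null(p$weights)) p$weights <- rep(1, length(p$lengths))
      if (length(p$weights) != length(p$lengths) || any(p$weights < 0) ||
          sum(p$weights) == 0)
        stopf("'weights' must be nonnegative, same length, not all zero")
    }
  )
  structure(list(family = family, params = p), class = "fragment_dist")
}

#' Draw fragment lengths
#'
#' @param dist A [fragment_dist()].
#' @param n Number of draws.
#' @return Numeric vector of `n` positive lengths (bases, rounded to
#'   integers, minimum 1).
#' @export
draw_lengths <- function(dist, n) {
  stopifnot(inherits(dist, "fragment_dist"))
  p <- dist$params
  x <- switch(dist$family,
    fixed = rep(p$length, n),
    log_uniform = exp(stats::runif(n, log(p$low), log(p$high))),
    log_normal = {
      y <- stats::rlnorm(n, p$meanlog, p$sdlog)
      if (!is.null(p$min)) y <- pmax(y, p$min)
      if (!is.null(p$max)) y <- pmin(y, p$max)
      y
    },
    empirical = sample(p$lengths, n, replace = TRUE,
                       prob = p$weights / sum(p$weights))
  )
  pmax(1, round(x))
}

#' Harmonic mean of fragment lengths
#'
#' Computes `mu = 1 / E(1/L)`, the quantity that controls the expected size
#' of the donor region shared by all selected recombinants. For a
#' [fragment_dist()], closed forms are used for the fixed, log-uniform and
#' empirical families; other families are evaluated by Monte-Carlo with the
#' standard error reported as an attribute.
#'
#' @param x Numeric vector of positive lengths, or a [fragment_dist()].
#' @param n_mc Monte-Carlo sample size for families without a closed form.
#' @param seed RNG seed for the Monte-Carlo path.
#' @return The harmonic mean (bases).
#' @examples
#' harmonic_mean(c(50, 200))  # 80
#' @export
harmonic_mean <- function(x, n_mc = 1e5, seed = NULL) {
  if (inherits(x, "fragment_dist")) {
    p <- x$params
    return(switch(x$family,
      fixed = p$length,
      log_uniform = {
        # E(1/L) for log-uniform on [a,b]: (1/a - 1/b) / log(b/a)
        a <- p$low; b <- p$high
        if (a == b) a else log(b / a) / (1 / a - 1 / b)
      },
      empirical = {
        w <- p$weights / sum(p$weights)
        1 / sum(w / p$lengths)
      },
      {
        draws <- with_seed(seed, draw_lengths(x, n_mc))
        inv <- 1 / draws
        out <- 1 / mean(inv)
        attr(out, "mc_se") <- stats::sd(inv) / sqrt(n_mc) * out^2
        out
      }
    ))
  }
  if (any(x <= 0)) stopf("all lengths must be positive")
  1 / mean(1 / x)
}
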