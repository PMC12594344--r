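# Independent reference implementations used to validate the fast paths.
# These deliberately use brute force / naive dynamic programming and share
# no code with the package internals.

# Best state path by exhaustive enumeration of all 2^n paths.
oracle_viterbi <- function(labels, pr) {
  n <- length(labels)
  best <- NULL
  bestll <- -Inf
  for (m in 0:(2^n - 1)) {
    st <- as.integer(intToBits(m))[1:n]  # 1 = donor
    ll <- log(ifelse(st[1] == 1, pr$pi_d, 1 - pr$pi_d)) +
      sum(log(ifelse(st == 1,
                     ifelse(labels == 1, pr$e_d, 1 - pr$e_d),
                     ifelse(labels == 1, pr$e_r, 1 - pr$e_r)))) +
      (if (n > 1) sum(log(ifelse(diff(st) != 0, pr$t, 1 - pr$t))) else 0)
    if (ll > bestll) {
      bestll <- ll
      best <- st
    }
  }
  best
}

# Posterior donor probabilities by summing over all paths.
oracle_posterior <- function(labels, pr) {
  n <- length(labels)
  tot <- rep(0, n)
  Z <- 0
  for (m in 0:(2^n - 1)) {
    st <- as.integer(intToBits(m))[1:n]
    ll <- log(ifelse(st[1] == 1, pr$pi_d, 1 - pr$pi_d)) +
      sum(log(ifelse(st == 1,
                     ifelse(labels == 1, pr$e_d, 1 - pr$e_d),
                     ifelse(labels == 1, pr$e_r, 1 - pr$e_r)))) +
      (if (n > 1) sum(log(ifelse(diff(st) != 0, pr$t, 1 - pr$t))) else 0)
    w <- exp(ll)
    Z <- Z + w
    tot <- tot + w * st
  }
  tot / Z
}

# Exact optimal partitioning by a naive O(n^2) dynamic program with
# segment costs computed directly on slices (no cumulative-sum trick).
oracle_changepoints <- function(x, penalty, min_seg = 2L) {
  n <- length(x)
  if (n < 2L * min_seg) return(integer(0))
  Fv <- rep(Inf, n + 1)
  Fv[1] <- -penalty
  prev <- rep(NA_integer_, n + 1)
  cost <- function(i, j) {
    s <- x[(i + 1):j]
    sum((s - mean(s))^2)
  }
  for (t in min_seg:n) {
    for (s in c(0L, seq_len(t - min_seg))) {
      if (t - s < min_seg) next
      if (s > 0L && !is.finite(Fv[s + 1])) next
      v <- Fv[s + 1] + cost(s, t) + penalty
      if (v < Fv[t + 1]) {
        Fv[t + 1] <- v
        prev[t + 1] <- s
      }
    }
  }
  cps <- integer(0)
  t <- n
  while (!is.na(prev[t + 1]) && prev[t + 1] > 0) {
    cps <- c(prev[t + 1], cps)
    t <- prev[t + 1]
  }
  as.integer(cps)
}

# Exact two-sided rank-sum p-value by enumerating all group assignments.
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pooled), n)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n)])
  stats <- apply(idx, 2, function(i) sum(r[i]))
  mu <- n * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}
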