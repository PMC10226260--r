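# Independent brute-force oracles. These re-derive the statistics from
# first principles with deliberately different code paths (scalar loops,
# uniroot instead of Newton, explicit risk-table accounting) so they can
# arbitrate the vectorized implementations.

# -- moderated two-group t-test, gene-by-gene loop -------------------------
oracle_moderated_t <- function(dep, group, context = unique(group)[1L]) {
  a <- which(group == context)
  b <- which(group != context)
  n1 <- length(a); n2 <- length(b)
  d <- n1 + n2 - 2
  m <- nrow(dep)
  delta <- s2 <- numeric(m)
  for (g in seq_len(m)) {
    xa <- dep[g, a]; xb <- dep[g, b]
    delta[g] <- mean(xa) - mean(xb)
    s2[g] <- (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) / d
  }
  # prior by moments of log s^2; trigamma inverse via uniroot
  e <- log(s2[s2 > 0]) - digamma(d / 2) + log(d / 2)
  ev <- var(e) - trigamma(d / 2)
  if (is.finite(ev) && ev > 0) {
    half_d0 <- uniroot(function(y) trigamma(y) - ev,
                       lower = 1e-8, upper = 1e8, tol = 1e-12)$root
    d0 <- 2 * half_d0
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    s2p <- (d0 * s02 + d * s2) / (d0 + d)
    dft <- d0 + d
  } else {
    d0 <- Inf
    s02 <- mean(s2[s2 > 0])
    s2p <- rep(s02, m)
    dft <- Inf
  }
  tval <- delta / sqrt(s2p * (1 / n1 + 1 / n2))
  p <- if (is.finite(dft)) 2 * pt(-abs(tval), dft) else 2 * pnorm(-abs(tval))
  list(t = tval, p = p, d0 = d0, s02 = s02)
}

# -- log-rank statistic from the risk table --------------------------------
oracle_logrank_stat <- function(time, event, in_group1) {
  tev <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tt in tev) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_group1)
    dd <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & in_group1)
    O <- O + d1
    E <- E + dd * n1 / n
    if (n > 1) V <- V + dd * (n1 / n) * (1 - n1 / n) * (n - dd) / (n - 1)
  }
  if (V == 0) return(0)
  (O - E)^2 / V
}

oracle_logrank_permutation_p <- function(time, event, in_group1, n_perm, seed) {
  obs <- oracle_logrank_stat(time, event, in_group1)
  set.seed(seed)
  n1 <- sum(in_group1)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    perm <- logical(length(time))
    perm[sample.int(length(time), n1)] <- TRUE
    if (oracle_logrank_stat(time, event, perm) >= obs - 1e-12) hits <- hits + 1L
  }
  list(observed = obs, p = hits / n_perm)
}

# -- BH step-up by the direct min-over-j definition ------------------------
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    j <- i:m
    adj[ord[i]] <- min(1, min(p[ord[j]] * m / j))
  }
  adj
}

# -- exact hypergeometric upper tail by combinatorial sum ------------------
oracle_hyper_upper <- function(N, K, n, k) {
  ks <- k:min(n, K)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}
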