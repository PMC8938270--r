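# Independent brute-force oracles. These re-derive the model from first
# principles (no calls into the package's decoding/phasing machinery) and
# are only feasible at tiny problem sizes.

# P(observed call | true dosage): dropout splits het truth to each
# homozygote, a miscall moves to either wrong call uniformly, no-call is
# state-independent
oracle_call_prob <- function(call, g, ado, err, miss) {
  if (is.na(call)) return(miss)
  after <- numeric(3)
  if (g == 1) {
    after[c(1, 3)] <- ado / 2
    after[2] <- 1 - ado
  } else {
    after[g + 1] <- 1
  }
  p <- 0
  for (x in 0:2) {
    p <- p + after[x + 1] * (if (x == call) 1 - err else err / 2)
  }
  (1 - miss) * p
}

oracle_haldane <- function(d_cm) (1 - exp(-2 * d_cm / 100)) / 2

# exhaustive enumeration over all 4^n joint transmitted-haplotype paths.
# state s in 1..4 maps to (m, p) with m = ((s-1) %% 2) + 1 (mother's
# haplotype) and p = ((s-1) %/% 2) + 1 (father's), matching the package's
# reported marginals. em: 4 x n emission probabilities; r: length n-1
# per-parent switch probabilities.
oracle_hmm <- function(em, r) {
  n <- ncol(em)
  states <- as.matrix(expand.grid(rep(list(1:4), n)))
  sm <- ((states - 1) %% 2) + 1
  sp <- ((states - 1) %/% 2) + 1
  logp <- rep(log(0.25), nrow(states))
  for (t in 1:n) logp <- logp + log(em[cbind(states[, t], t)])
  if (n > 1) {
    for (t in 2:n) {
      logp <- logp +
        log(ifelse(sm[, t] != sm[, t - 1], r[t - 1], 1 - r[t - 1])) +
        log(ifelse(sp[, t] != sp[, t - 1], r[t - 1], 1 - r[t - 1]))
    }
  }
  M <- max(logp)
  w <- exp(logp - M)
  post <- matrix(0, 4, n)
  for (t in 1:n) for (s in 1:4) post[s, t] <- sum(w[states[, t] == s])
  post <- sweep(post, 2, colSums(post), "/")
  list(loglik = M + log(sum(w)), viterbi_loglik = max(logp), posterior = post)
}

# full-chromosome log-likelihood of one parent-phase configuration,
# enumerating this parent's 2^k transmitted-haplotype paths; the other
# parent's allele marginalized independently per site (the single-pass
# phasing model). x: allele on haplotype 1 per het site; calls: embryos x k
# matrix; p_oth1: P(other parent transmits the alt allele) per site.
oracle_phase_loglik <- function(x, calls, p_oth1, d_cm, ado, err, miss) {
  k <- length(x)
  r <- oracle_haldane(d_cm)
  paths <- as.matrix(expand.grid(rep(list(1:2), k)))
  trans_lp <- if (k > 1) {
    lp <- 0
    for (t in 2:k) {
      lp <- lp + log(ifelse(paths[, t] != paths[, t - 1], r[t - 1], 1 - r[t - 1]))
    }
    lp
  } else 0
  ll <- 0
  for (e in seq_len(nrow(calls))) {
    em_path <- matrix(0, nrow(paths), k)
    for (t in 1:k) {
      p0 <- (1 - p_oth1[t]) * oracle_call_prob(calls[e, t], x[t], ado, err, miss) +
        p_oth1[t] * oracle_call_prob(calls[e, t], x[t] + 1, ado, err, miss)
      p1 <- (1 - p_oth1[t]) * oracle_call_prob(calls[e, t], 1 - x[t], ado, err, miss) +
        p_oth1[t] * oracle_call_prob(calls[e, t], 2 - x[t], ado, err, miss)
      em_path[, t] <- ifelse(paths[, t] == 1, p0, p1)
    }
    pe <- sum(exp(log(0.5) + trans_lp + rowSums(log(em_path))))
    ll <- ll + log(pe)
  }
  ll
}

# maximum-likelihood phase over all 2^(k-1) configurations (x[1] fixed 1)
oracle_best_phase <- function(calls, p_oth1, d_cm, ado, err, miss) {
  k <- length(p_oth1)
  configs <- as.matrix(expand.grid(rep(list(0:1), k - 1)))
  lls <- apply(configs, 1, function(rest) {
    oracle_phase_loglik(c(1L, rest), calls, p_oth1, d_cm, ado, err, miss)
  })
  list(best_ll = max(lls),
       configs = cbind(1L, configs),
       lls = lls)
}
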