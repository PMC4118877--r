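# Independent pure-R oracles: collapsed joint probabilities computed from
# scratch (naive loops over the latent state), exhaustive enumeration of
# tiny posteriors, and exact conditionals by renormalization. These never
# touch the package's compiled code paths.

oracle_atam_logjoint <- function(obj, a = obj$a, ts = obj$tstate) {
  A <- obj$A; Z <- obj$Z; W <- obj$W
  sgm <- obj$sigma; gam <- obj$gamma; lam <- obj$lambda; bet <- obj$beta
  ptr <- obj$flat$doc_ptr
  word <- obj$flat$word + 1L
  asp <- obj$flat$aspect + 1L
  act <- which(!is.na(a))
  n_ail <- tabulate(a[act], A)
  ll <- lgamma(A * sgm) - lgamma(A * sgm + length(act)) +
    sum(lgamma(sgm + n_ail) - lgamma(sgm))
  n_tw <- matrix(0L, Z, W)
  n_bg <- matrix(0L, 3L, W)
  n_aaw <- array(0L, c(A, 3L, W))
  nbg <- 0L; nnon <- 0L
  for (d in act) {
    idx <- if (ptr[d] < ptr[d + 1]) (ptr[d] + 1L):ptr[d + 1] else integer(0)
    std <- ts[idx]; wd <- word[idx]; jd <- asp[idx]
    nA <- sum(std == 2L); ntop <- sum(std > 2L)
    nbg <- nbg + sum(std == 1L); nnon <- nnon + nA + ntop
    ll <- ll + lgamma(2 * gam) - lgamma(2 * gam + nA + ntop) +
      lgamma(gam + nA) + lgamma(gam + ntop) - 2 * lgamma(gam)
    ai <- obj$alpha[a[d], ]
    ndz <- tabulate(std[std > 2L] - 2L, Z)
    ll <- ll + lgamma(sum(ai)) - lgamma(sum(ai) + ntop) +
      sum(lgamma(ai + ndz) - lgamma(ai))
    for (q in seq_along(idx)) {
      if (std[q] == 1L) n_bg[jd[q], wd[q]] <- n_bg[jd[q], wd[q]] + 1L
      else if (std[q] == 2L)
        n_aaw[a[d], jd[q], wd[q]] <- n_aaw[a[d], jd[q], wd[q]] + 1L
      else n_tw[std[q] - 2L, wd[q]] <- n_tw[std[q] - 2L, wd[q]] + 1L
    }
  }
  if (nnon > 0L) ll <- ll + nnon * log(lam)
  if (nbg > 0L) ll <- ll + nbg * log(1 - lam)
  for (k in seq_len(Z))
    ll <- ll + lgamma(W * bet) - lgamma(W * bet + sum(n_tw[k, ])) +
      sum(lgamma(bet + n_tw[k, ]) - lgamma(bet))
  for (j in 1:3)
    ll <- ll + lgamma(W * bet) - lgamma(W * bet + sum(n_bg[j, ])) +
      sum(lgamma(bet + n_bg[j, ]) - lgamma(bet))
  for (i in seq_len(A)) for (j in 1:3) {
    sm <- obj$s[i] * obj$m[i, ]
    ll <- ll + lgamma(obj$s[i]) - lgamma(obj$s[i] + sum(n_aaw[i, j, ])) +
      sum(lgamma(sm + n_aaw[i, j, ]) - lgamma(sm))
  }
  ll
}

oracle_lda_logjoint <- function(obj, ts = obj$tstate) {
  Z <- obj$Z; W <- obj$W
  lam <- obj$lambda; bet <- obj$beta; al <- obj$alpha
  ptr <- obj$flat$doc_ptr
  word <- obj$flat$word + 1L
  D <- length(ptr) - 1L
  n_tw <- matrix(0L, Z, W)
  n_bg <- integer(W)
  nbg <- 0L; nnon <- 0L
  ll <- 0
  for (d in seq_len(D)) {
    idx <- if (ptr[d] < ptr[d + 1]) (ptr[d] + 1L):ptr[d + 1] else integer(0)
    if (!length(idx) || anyNA(ts[idx])) next
    std <- ts[idx]; wd <- word[idx]
    ntop <- sum(std > 1L)
    nbg <- nbg + sum(std == 1L); nnon <- nnon + ntop
    ndz <- tabulate(std[std > 1L] - 1L, Z)
    ll <- ll + lgamma(sum(al)) - lgamma(sum(al) + ntop) +
      sum(lgamma(al + ndz) - lgamma(al))
    for (q in seq_along(idx)) {
      if (std[q] == 1L) n_bg[wd[q]] <- n_bg[wd[q]] + 1L
      else n_tw[std[q] - 1L, wd[q]] <- n_tw[std[q] - 1L, wd[q]] + 1L
    }
  }
  if (nnon > 0L) ll <- ll + nnon * log(lam)
  if (nbg > 0L) ll <- ll + nbg * log(1 - lam)
  for (k in seq_len(Z))
    ll <- ll + lgamma(W * bet) - lgamma(W * bet + sum(n_tw[k, ])) +
      sum(lgamma(bet + n_tw[k, ]) - lgamma(bet))
  ll + lgamma(W * bet) - lgamma(W * bet + sum(n_bg)) +
    sum(lgamma(bet + n_bg) - lgamma(bet))
}

decode_config <- function(ix, D, N, A, S) {
  ts <- integer(N)
  if (N > 0) for (t in N:1) {
    ts[t] <- ix %% S + 1L
    ix <- ix %/% S
  }
  a <- integer(D)
  if (D > 0) for (d in D:1) {
    a[d] <- ix %% A + 1L
    ix <- ix %/% A
  }
  list(a = a, ts = ts)
}

# Exact posterior over all full latent configurations of a tiny ATAM state,
# indexed exactly as posterior_config_counts() indexes its tally.
oracle_atam_posterior <- function(obj) {
  D <- length(obj$a)
  N <- length(obj$tstate)
  S <- obj$Z + 2L
  total <- obj$A^D * S^N
  lj <- numeric(total)
  for (ix in 0:(total - 1L)) {
    cfg <- decode_config(ix, D, N, obj$A, S)
    lj[ix + 1L] <- oracle_atam_logjoint(obj, a = cfg$a, ts = cfg$ts)
  }
  p <- exp(lj - max(lj))
  p / sum(p)
}

oracle_lda_posterior <- function(obj) {
  N <- length(obj$tstate)
  S <- obj$Z + 1L
  total <- S^N
  lj <- numeric(total)
  for (ix in 0:(total - 1L)) {
    cfg <- decode_config(ix, 0L, N, 1L, S)
    lj[ix + 1L] <- oracle_lda_logjoint(obj, ts = cfg$ts)
  }
  p <- exp(lj - max(lj))
  p / sum(p)
}

# Exact conditional of a_d by renormalizing the enumerated joint over the
# candidate ailments with everything else fixed.
oracle_ailment_conditional <- function(obj, d) {
  lj <- vapply(seq_len(obj$A), function(i) {
    a <- obj$a
    a[d] <- i
    oracle_atam_logjoint(obj, a = a)
  }, 0)
  p <- exp(lj - max(lj))
  p / sum(p)
}

oracle_token_conditional <- function(obj, d, n) {
  t <- obj$flat$doc_ptr[d] + n
  lj <- vapply(seq_len(obj$Z + 2L), function(s) {
    ts <- obj$tstate
    ts[t] <- s
    oracle_atam_logjoint(obj, ts = ts)
  }, 0)
  p <- exp(lj - max(lj))
  p / sum(p)
}

oracle_lda_token_conditional <- function(obj, d, n) {
  t <- obj$flat$doc_ptr[d] + n
  lj <- vapply(seq_len(obj$Z + 1L), function(s) {
    ts <- obj$tstate
    ts[t] <- s
    oracle_lda_logjoint(obj, ts = ts)
  }, 0)
  p <- exp(lj - max(lj))
  p / sum(p)
}

# Textbook Pearson correlation, written out in full.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - sum(x) / n) * (y - sum(y) / n)) /
    sqrt(sum((x - sum(x) / n)^2) * sum((y - sum(y) / n)^2))
}
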