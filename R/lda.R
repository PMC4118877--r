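# LDA with a shared background word distribution: the comparison baseline.
# Token-state encoding (R side): 1 = background, 1+k = topic k.

lda_hypers_list <- function(obj) {
  list(Z = obj$Z, W = obj$W, lambda = obj$lambda, beta = obj$beta,
       alpha = obj$alpha)
}

#' Initialize an LDA-with-background sampler state
#'
#' @param corpus an \code{atam_corpus}.
#' @param control an [atam_control()] list; \code{Z}, \code{lambda},
#'   \code{beta} and the optimization settings apply.
#' @param alpha initial symmetric topic Dirichlet value (default 0.5).
#' @param seed optional integer seed.
#' @return an object of class \code{lda_bg}.
#' @export
lda_init <- function(corpus, control = atam_control(), alpha = 0.5,
                     seed = NULL) {
  stopifnot(inherits(corpus, "atam_corpus"))
  if (!is.null(seed)) set.seed(seed)
  D <- n_docs(corpus)
  if (D == 0L) stop("cannot initialize on an empty corpus")
  flat <- flatten_corpus(corpus)
  Z <- control$Z
  tstate <- sample.int(Z + 1L, length(flat$word), replace = TRUE)
  obj <- structure(list(
    flat = flat, vocab = corpus$vocab, vocab_hash = vocab_hash(corpus$vocab),
    meta = corpus$meta,
    Z = Z, W = n_vocab(corpus),
    lambda = control$lambda, beta = control$beta,
    alpha = rep(alpha, Z),
    tstate = tstate, stats = NULL,
    loglik = numeric(0), ll_iter = integer(0), sweeps_done = 0L,
    control = control, call = NULL),
    class = "lda_bg")
  obj$stats <- cpp_lda_recount(obj$flat, ts0(obj$tstate),
                               lda_hypers_list(obj))
  obj
}

#' @export
set_state.lda_bg <- function(object, tstate = NULL, alpha = NULL, ...) {
  if (!is.null(tstate)) {
    stopifnot(length(tstate) == length(object$tstate),
              all(is.na(tstate) | (tstate >= 1 & tstate <= object$Z + 1L)))
    object$tstate <- as.integer(tstate)
  }
  if (!is.null(alpha)) {
    stopifnot(length(alpha) == object$Z, all(alpha > 0))
    object$alpha <- as.numeric(alpha)
  }
  object$stats <- cpp_lda_recount(object$flat, ts0(object$tstate),
                                  lda_hypers_list(object))
  object
}

#' Full conditional over a token's state under LDA-with-background
#'
#' With probability \eqn{\lambda} a token is a topic word under standard
#' LDA, otherwise it comes from the shared background distribution; the
#' collapsed conditional mirrors that mixture. \eqn{\lambda = 1} reduces to
#' standard LDA (the background entry is zero).
#'
#' @param object an \code{lda_bg} state.
#' @param d document index (1-based).
#' @param n token position within the document (1-based).
#' @return a normalized probability vector of length \code{Z + 1}, ordered
#'   background, topic 1..Z.
#' @export
lda_token_conditional <- function(object, d, n) {
  stopifnot(inherits(object, "lda_bg"))
  t0 <- object$flat$doc_ptr[as.integer(d)] + as.integer(n) - 1L
  cpp_lda_token_conditional(object$flat, ts0(object$tstate),
                            lda_hypers_list(object), object$stats,
                            as.integer(d) - 1L, t0)
}

#' @export
gibbs_sweep.lda_bg <- function(object, nsweeps = 1L, ...) {
  if (nsweeps < 1L) return(object)
  docs <- seq_len(length(object$flat$doc_ptr) - 1L) - 1L
  res <- cpp_lda_run(object$flat, ts0(object$tstate),
                     lda_hypers_list(object), object$stats, docs,
                     as.integer(nsweeps), object$control$ll_every,
                     0L, integer(0), FALSE)
  object$tstate <- from0(res$tstate)
  object$stats <- res$stats
  if (length(res$loglik)) {
    le <- object$control$ll_every
    object$loglik <- c(object$loglik, res$loglik)
    object$ll_iter <- c(object$ll_iter,
                        object$sweeps_done + seq_len(length(res$loglik)) * le)
  }
  object$sweeps_done <- object$sweeps_done + as.integer(nsweeps)
  object
}

#' @export
posterior_config_counts.lda_bg <- function(object, nsweeps, burnin = 0L, ...) {
  nT <- sum(!is.na(object$tstate))
  size <- (object$Z + 1)^nT
  if (size > 5e6) stop("configuration space too large to tally")
  docs <- seq_len(length(object$flat$doc_ptr) - 1L) - 1L
  res <- cpp_lda_run(object$flat, ts0(object$tstate),
                     lda_hypers_list(object), object$stats, docs,
                     as.integer(nsweeps), 0L, as.integer(burnin),
                     integer(size), TRUE)
  object$tstate <- from0(res$tstate)
  object$stats <- res$stats
  object$sweeps_done <- object$sweeps_done + as.integer(nsweeps)
  list(counts = res$tally, object = object)
}

#' @export
joint_log_likelihood.lda_bg <- function(object, ...) {
  ll <- cpp_lda_joint_ll(object$flat, ts0(object$tstate),
                         lda_hypers_list(object))
  if (!is.finite(ll)) stop("joint log likelihood is not finite")
  ll
}

#' @export
audit_state.lda_bg <- function(object, ...) {
  D <- length(object$flat$doc_ptr) - 1L
  Z <- object$Z; W <- object$W
  fresh <- list(n_doc_topic = matrix(0L, D, Z),
                n_doc_top = integer(D),
                n_topic_word = matrix(0L, Z, W),
                n_bg_word = integer(W))
  ptr <- object$flat$doc_ptr
  word <- object$flat$word + 1L
  for (d in seq_len(D)) {
    if (ptr[d] >= ptr[d + 1]) next
    for (t in (ptr[d] + 1L):ptr[d + 1]) {
      s <- object$tstate[t]
      if (is.na(s)) next
      v <- word[t]
      if (s == 1L) {
        fresh$n_bg_word[v] <- fresh$n_bg_word[v] + 1L
      } else {
        k <- s - 1L
        fresh$n_topic_word[k, v] <- fresh$n_topic_word[k, v] + 1L
        fresh$n_doc_topic[d, k] <- fresh$n_doc_topic[d, k] + 1L
        fresh$n_doc_top[d] <- fresh$n_doc_top[d] + 1L
      }
    }
  }
  for (nm in names(fresh)) {
    if (!isTRUE(all.equal(as.vector(as.integer(object$stats[[nm]])),
                          as.vector(as.integer(fresh[[nm]])))))
      stop("audit failed: table '", nm, "' is inconsistent with the latent state")
  }
  invisible(TRUE)
}

#' @export
estimate_parameters.lda_bg <- function(object, ...) {
  st <- object$stats
  W <- object$W
  theta <- (st$n_doc_topic +
              matrix(object$alpha, nrow(st$n_doc_topic), object$Z,
                     byrow = TRUE)) /
    (st$n_doc_top + sum(object$alpha))
  phi_T <- (st$n_topic_word + object$beta) /
    (rowSums(st$n_topic_word) + W * object$beta)
  phi_B <- (st$n_bg_word + object$beta) / (sum(st$n_bg_word) + W * object$beta)
  list(theta = theta, phi_T = phi_T, phi_B = phi_B)
}

#' Fit LDA with a background distribution
#'
#' The baseline topic model: standard LDA plus a shared background word
#' distribution absorbing common non-topical words. Fitting mirrors
#' [atam()]: collapsed Gibbs sweeps with the symmetric topic Dirichlet
#' optimized by the fixed-mean precision update at the same cadence.
#'
#' @param corpus an \code{atam_corpus}.
#' @param control an [atam_control()] list (or settings via \code{...}).
#' @param alpha initial symmetric topic Dirichlet value.
#' @param seed integer seed.
#' @param ... forwarded to [atam_control()] when \code{control} is missing.
#' @return an object of class \code{lda_bg}.
#' @export
lda_bg <- function(corpus, control, alpha = 0.5, seed = NULL, ...) {
  if (missing(control)) control <- atam_control(...)
  else if (length(list(...))) stop("pass settings either via control or ...")
  if (!is.null(seed)) set.seed(seed)
  object <- lda_init(corpus, control, alpha = alpha)
  object$call <- match.call()
  total <- control$iterations
  while (object$sweeps_done < total) {
    stop_at <- total
    if (control$hyper_every > 0L)
      stop_at <- min(stop_at, (object$sweeps_done %/% control$hyper_every + 1L) *
                       control$hyper_every)
    object <- gibbs_sweep(object, stop_at - object$sweeps_done)
    if (control$hyper_every > 0L && control$optimize_alpha &&
        object$sweeps_done %% control$hyper_every == 0L) {
      for (p in seq_len(control$hyper_passes)) {
        s_new <- update_precision(object$stats$n_doc_topic,
                                  rep(1 / object$Z, object$Z),
                                  sum(object$alpha),
                                  floor = control$alpha_floor * object$Z)
        object$alpha <- rep(s_new / object$Z, object$Z)
      }
    }
  }
  object
}
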