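# Core ATAM state handling: initialization, conditionals, sweeps, audit,
# parameter estimation, joint likelihood.
#
# Latent-state encoding (R side, 1-based):
#   a[d] in 1..A (NA while a document is not yet active);
#   tstate[t] in 1..Z+2 with 1 = background, 2 = ailment, 2+k = topic k.

priors_list <- function(obj) {
  list(A = obj$A, Z = obj$Z, W = obj$W, Y = obj$Y,
       lambda = obj$lambda, gamma = obj$gamma, sigma = obj$sigma,
       beta = obj$beta, alpha = obj$alpha, m = obj$m, s = obj$s)
}

a0 <- function(a) {
  a <- as.integer(a) - 1L
  a[is.na(a)] <- -1L
  a
}

ts0 <- function(ts) {
  ts <- as.integer(ts) - 1L
  ts[is.na(ts)] <- -1L
  ts
}

active_docs0 <- function(obj) which(!is.na(obj$a)) - 1L

from0 <- function(x) {
  x <- as.integer(x)
  x[x < 0L] <- NA_integer_
  x + 1L
}

#' Initialize an ATAM sampler state
#'
#' Draws every document ailment uniformly and every token's composite
#' background/ailment/topic state uniformly, and builds the matching count
#' tables. Usually called through [atam()]; exposed for stepwise use.
#'
#' @param corpus an \code{atam_corpus} with at least one document.
#' @param priors optional \code{ailment_priors}; ailments without an
#'   informative prior get a uniform mean with precision
#'   \code{control$s_init}.
#' @param control an [atam_control()] list.
#' @param seed optional integer seed (sets the R RNG).
#' @param active optional integer vector of documents to activate (default
#'   all); the rest can be brought in later with [extend_data()].
#' @return an object of class \code{atam} holding the latent state, count
#'   tables, hyperparameters and corpus metadata.
#' @export
atam_init <- function(corpus, priors = NULL, control = atam_control(),
                      seed = NULL, active = NULL) {
  stopifnot(inherits(corpus, "atam_corpus"))
  if (!is.null(seed)) set.seed(seed)
  D <- n_docs(corpus)
  if (D == 0L) stop("cannot initialize on an empty corpus")
  W <- n_vocab(corpus)
  A <- control$A
  Z <- control$Z
  pr <- complete_priors(priors, A, W, control$s_init)
  flat <- flatten_corpus(corpus)
  if (is.null(active)) active <- seq_len(D)
  a <- rep(NA_integer_, D)
  a[active] <- sample.int(A, length(active), replace = TRUE)
  tstate <- rep(NA_integer_, length(flat$word))
  for (d in active) {
    idx <- if (flat$doc_ptr[d] < flat$doc_ptr[d + 1])
      (flat$doc_ptr[d] + 1L):flat$doc_ptr[d + 1] else integer(0)
    tstate[idx] <- sample.int(Z + 2L, length(idx), replace = TRUE)
  }
  obj <- structure(list(
    flat = flat, vocab = corpus$vocab, vocab_hash = vocab_hash(corpus$vocab),
    meta = corpus$meta,
    A = A, Z = Z, W = W, Y = 3L,
    lambda = control$lambda, gamma = control$gamma, sigma = control$sigma,
    beta = control$beta,
    alpha = matrix(1, A, Z), m = pr$m, s = pr$s, ailments = pr$ailments,
    a = a, tstate = tstate, stats = NULL,
    loglik = numeric(0), ll_iter = integer(0),
    sweeps_done = 0L, increments_done = 1L, doc_order = seq_len(D),
    hyper_trace = NULL, control = control, call = NULL),
    class = "atam")
  obj$stats <- cpp_atam_recount(obj$flat, a0(obj$a), ts0(obj$tstate),
                                priors_list(obj))
  obj
}

#' Set a sampler state explicitly
#'
#' Replaces the latent assignments (and optionally the topic
#' hyperparameters) and rebuilds the count tables to match. Mainly useful
#' for constructing exact states in analyses and checks.
#'
#' @param object an \code{atam} or \code{lda_bg} state.
#' @param ... passed to methods: \code{a} (document ailments, ATAM only),
#'   \code{tstate} (composite token states), \code{alpha}.
#' @return the updated object with consistent tables.
#' @export
set_state <- function(object, ...) UseMethod("set_state")

#' @export
set_state.atam <- function(object, a = NULL, tstate = NULL, alpha = NULL,
                           s = NULL, ...) {
  if (!is.null(a)) {
    stopifnot(length(a) == length(object$a),
              all(is.na(a) | (a >= 1 & a <= object$A)))
    object$a <- as.integer(a)
  }
  if (!is.null(tstate)) {
    stopifnot(length(tstate) == length(object$tstate),
              all(is.na(tstate) | (tstate >= 1 & tstate <= object$Z + 2L)))
    object$tstate <- as.integer(tstate)
  }
  if (!is.null(alpha)) {
    stopifnot(all(dim(alpha) == dim(object$alpha)), all(alpha > 0))
    object$alpha <- alpha
  }
  if (!is.null(s)) {
    stopifnot(length(s) == object$A, all(s > 0))
    object$s <- as.numeric(s)
  }
  object$stats <- cpp_atam_recount(object$flat, a0(object$a),
                                   ts0(object$tstate), priors_list(object))
  object
}

#' Full conditional over a document's ailment
#'
#' The collapsed conditional \eqn{p(a_d = i \mid \cdot)} with document
#' \eqn{d}'s own contributions removed: proportional to the ailment
#' prevalence factor, the grouped Dirichlet-multinomial predictive of the
#' document's ailment-state tokens under \eqn{\beta_i = s_i m_i} (by aspect),
#' and the Dirichlet-multinomial predictive of the document's topic counts
#' under \eqn{\alpha_i}. All products are accumulated in log space.
#'
#' @param object an \code{atam} state.
#' @param d document index (1-based, must be active).
#' @return a normalized probability vector of length \code{A}.
#' @export
ailment_conditional <- function(object, d) {
  stopifnot(inherits(object, "atam"))
  cpp_ailment_conditional(object$flat, a0(object$a), ts0(object$tstate),
                          priors_list(object), object$stats,
                          as.integer(d) - 1L)
}

#' Full conditional over a token's composite state
#'
#' The collapsed conditional over \code{Z + 2} outcomes (background, ailment,
#' each topic) for token \code{n} of document \code{d}, with the token's own
#' contribution removed. With \code{mask_ailment = TRUE} the ailment/topic
#' split is forced to topics (\eqn{\pi_d = 0}): the ailment entry is zero and
#' the Beta factor drops out, which reduces the vector to the
#' LDA-with-background conditional on identical counts.
#'
#' @param object an \code{atam} state.
#' @param d document index (1-based).
#' @param n token position within the document (1-based).
#' @param mask_ailment force \eqn{\pi_d = 0}.
#' @return a normalized probability vector of length \code{Z + 2}, ordered
#'   background, ailment, topic 1..Z.
#' @export
token_conditional <- function(object, d, n, mask_ailment = FALSE) {
  stopifnot(inherits(object, "atam"))
  t0 <- object$flat$doc_ptr[as.integer(d)] + as.integer(n) - 1L
  cpp_token_conditional(object$flat, a0(object$a), ts0(object$tstate),
                        priors_list(object), object$stats,
                        as.integer(d) - 1L, t0, isTRUE(mask_ailment))
}

#' Run collapsed Gibbs sweeps
#'
#' Each sweep resamples every active document's ailment from
#' [ailment_conditional()] and then every token's composite state from
#' [token_conditional()], maintaining the count tables incrementally.
#'
#' @param object an \code{atam} or \code{lda_bg} state.
#' @param nsweeps number of full sweeps.
#' @param ... passed to methods.
#' @return the updated object; joint log likelihood values are appended to
#'   \code{object$loglik} at the cadence \code{control$ll_every}.
#' @export
gibbs_sweep <- function(object, nsweeps = 1L, ...) UseMethod("gibbs_sweep")

#' @export
gibbs_sweep.atam <- function(object, nsweeps = 1L, ...) {
  if (nsweeps < 1L) return(object)
  res <- cpp_atam_run(object$flat, a0(object$a), ts0(object$tstate),
                      priors_list(object), object$stats, active_docs0(object),
                      as.integer(nsweeps), object$control$ll_every,
                      0L, integer(0), FALSE)
  absorb_run(object, res, nsweeps)
}

absorb_run <- function(object, res, nsweeps) {
  object$a <- from0(res$a)
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

#' Tally full latent configurations over many sweeps
#'
#' For tiny instances only: runs the sampler and counts, after a burn-in,
#' how often each complete latent configuration (all document ailments and
#' all token states) is visited. Configurations are indexed in mixed radix,
#' document ailments first (base \code{A}, document order), then token
#' states (base \code{Z + 2}, corpus order). Used to compare the chain's
#' empirical distribution against the exactly enumerated posterior.
#'
#' @param object an \code{atam} or \code{lda_bg} state.
#' @param nsweeps total sweeps to run.
#' @param burnin sweeps discarded before tallying.
#' @param ... passed to methods.
#' @return list with \code{counts} (integer vector over all configurations)
#'   and the updated \code{object}.
#' @export
posterior_config_counts <- function(object, nsweeps, burnin = 0L, ...)
  UseMethod("posterior_config_counts")

#' @export
posterior_config_counts.atam <- function(object, nsweeps, burnin = 0L, ...) {
  nA <- sum(!is.na(object$a))
  nT <- sum(!is.na(object$tstate))
  size <- object$A^nA * (object$Z + 2)^nT
  if (size > 5e6) stop("configuration space too large to tally")
  res <- cpp_atam_run(object$flat, a0(object$a), ts0(object$tstate),
                      priors_list(object), object$stats, active_docs0(object),
                      as.integer(nsweeps), 0L, as.integer(burnin),
                      integer(size), TRUE)
  list(counts = res$tally, object = absorb_run(object, res, nsweeps))
}

#' Collapsed joint log likelihood
#'
#' The log probability of the words and sampled latent variables with all
#' multinomial parameters integrated out: Dirichlet-multinomial normalizer
#' ratios for every count table plus the Bernoulli background terms. This is
#' the objective the interleaved hyperparameter updates must not degrade.
#'
#' @param object an \code{atam} or \code{lda_bg} state.
#' @param ... passed to methods.
#' @return a finite scalar (an error is raised if it is not finite).
#' @export
joint_log_likelihood <- function(object, ...) UseMethod("joint_log_likelihood")

#' @export
joint_log_likelihood.atam <- function(object, ...) {
  ll <- cpp_atam_joint_ll(object$flat, a0(object$a), ts0(object$tstate),
                          priors_list(object))
  if (!is.finite(ll)) stop("joint log likelihood is not finite")
  ll
}

# Independent pure-R recount of every table from the latent state.
recount_r <- function(obj) {
  D <- length(obj$a)
  A <- obj$A; Z <- obj$Z; W <- obj$W; Y <- obj$Y
  st <- list(n_ail = integer(A),
             n_doc_topic = matrix(0L, D, Z),
             n_doc_ail = integer(D), n_doc_top = integer(D),
             n_topic_word = matrix(0L, Z, W),
             n_ail_aspect_word = array(0L, c(A, Y, W)),
             n_bg_aspect_word = matrix(0L, Y, W))
  ptr <- obj$flat$doc_ptr
  word <- obj$flat$word + 1L
  aspect <- obj$flat$aspect + 1L
  for (d in seq_len(D)) {
    if (is.na(obj$a[d])) next
    i <- obj$a[d]
    st$n_ail[i] <- st$n_ail[i] + 1L
    if (ptr[d] >= ptr[d + 1]) next
    for (t in (ptr[d] + 1L):ptr[d + 1]) {
      s <- obj$tstate[t]; v <- word[t]; j <- aspect[t]
      if (s == 1L) {
        st$n_bg_aspect_word[j, v] <- st$n_bg_aspect_word[j, v] + 1L
      } else if (s == 2L) {
        st$n_ail_aspect_word[i, j, v] <- st$n_ail_aspect_word[i, j, v] + 1L
        st$n_doc_ail[d] <- st$n_doc_ail[d] + 1L
      } else {
        k <- s - 2L
        st$n_topic_word[k, v] <- st$n_topic_word[k, v] + 1L
        st$n_doc_topic[d, k] <- st$n_doc_topic[d, k] + 1L
        st$n_doc_top[d] <- st$n_doc_top[d] + 1L
      }
    }
  }
  st
}

#' Audit count-table consistency
#'
#' Recounts every sufficient-statistic table directly from the latent state
#' (in plain R, independently of the incremental bookkeeping) and compares it
#' with the maintained tables.
#'
#' @param object an \code{atam} or \code{lda_bg} state.
#' @param ... passed to methods.
#' @return \code{TRUE} invisibly; an error names the first inconsistent
#'   table otherwise.
#' @export
audit_state <- function(object, ...) UseMethod("audit_state")

#' @export
audit_state.atam <- function(object, ...) {
  fresh <- recount_r(object)
  for (nm in names(fresh)) {
    got <- object$stats[[nm]]
    want <- fresh[[nm]]
    if (!isTRUE(all.equal(as.vector(as.integer(got)),
                          as.vector(as.integer(want)))))
      stop("audit failed: table '", nm, "' is inconsistent with the latent state")
  }
  ptr <- object$flat$doc_ptr
  nd <- diff(ptr)
  act <- !is.na(object$a)
  nbg <- nd[act] - fresh$n_doc_ail[act] - fresh$n_doc_top[act]
  if (any(nbg < 0))
    stop("audit failed: negative background count for document ",
         which(act)[which(nbg < 0)[1]])
  invisible(TRUE)
}

#' Posterior-mean parameter estimates from the collapsed counts
#'
#' Every distribution is the Dirichlet (or Beta) posterior mean given the
#' current count tables and its prior, so an empty corpus returns the prior
#' means.
#'
#' @param object an \code{atam} or \code{lda_bg} state.
#' @param ... passed to methods.
#' @return for ATAM, a list with \code{eta} (ailment prevalence), \code{pi}
#'   (per-document ailment-word proportion), \code{theta} (document-topic
#'   matrix), \code{phi_T} (topic-word), \code{phi_A} (ailment x aspect x
#'   word array) and \code{phi_B} (aspect x word background).
#' @export
estimate_parameters <- function(object, ...) UseMethod("estimate_parameters")

#' @export
estimate_parameters.atam <- function(object, ...) {
  st <- object$stats
  A <- object$A; Z <- object$Z; W <- object$W; Y <- object$Y
  n_active <- sum(!is.na(object$a))
  eta <- (st$n_ail + object$sigma) / (n_active + A * object$sigma)
  pi_d <- (st$n_doc_ail + object$gamma) /
    (st$n_doc_ail + st$n_doc_top + 2 * object$gamma)
  pi_d[is.na(object$a)] <- NA_real_
  alpha_row <- object$alpha[ifelse(is.na(object$a), 1L, object$a), , drop = FALSE]
  theta <- (st$n_doc_topic + alpha_row) /
    (st$n_doc_top + rowSums(alpha_row))
  theta[is.na(object$a), ] <- NA_real_
  phi_T <- (st$n_topic_word + object$beta) /
    (rowSums(st$n_topic_word) + W * object$beta)
  phi_B <- (st$n_bg_aspect_word + object$beta) /
    (rowSums(st$n_bg_aspect_word) + W * object$beta)
  phi_A <- array(0, c(A, Y, W))
  for (j in seq_len(Y)) {
    cnt <- st$n_ail_aspect_word[, j, , drop = FALSE]
    dim(cnt) <- c(A, W)
    phi_A[, j, ] <- (cnt + object$s * object$m) / (rowSums(cnt) + object$s)
  }
  list(eta = eta, pi = pi_d, theta = theta, phi_T = phi_T, phi_A = phi_A,
       phi_B = phi_B)
}
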