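# Generative simulator: corpora drawn from the model's own generative story
# with known parameters, used for parameter-recovery studies and for the
# planted-trend evaluation of the trend-mining layer.

#' Bundle a set of true generating parameters
#'
#' @param eta ailment prevalence vector (length A, sums to 1).
#' @param alpha matrix A x Z: per-ailment Dirichlet over topic proportions.
#' @param phi_A array A x 3 x W: ailment word distributions per aspect
#'   (general, symptom, treatment).
#' @param phi_T matrix Z x W: topic word distributions.
#' @param phi_B matrix 3 x W: background word distributions per aspect.
#' @param lambda probability a token is non-background.
#' @param gamma symmetric Beta parameter for the per-document ailment/topic
#'   split proportion.
#' @param aspect_probs matrix A x 3 (rows sum to 1): per-ailment probability
#'   that a token is a general/symptom/treatment word. Default 0.7/0.2/0.1
#'   for every ailment.
#' @param vocab optional vocabulary strings (default \code{w001, w002, ...}).
#' @return a list of class \code{atam_params}.
#' @export
atam_params <- function(eta, alpha, phi_A, phi_T, phi_B, lambda = 0.2,
                        gamma = 1, aspect_probs = NULL, vocab = NULL) {
  A <- length(eta)
  Z <- nrow(phi_T)
  W <- ncol(phi_T)
  stopifnot(abs(sum(eta) - 1) < 1e-8,
            identical(dim(alpha), c(A, Z)) || all(dim(alpha) == c(A, Z)),
            all(dim(phi_A) == c(A, 3L, W)),
            all(dim(phi_B) == c(3L, W)),
            lambda >= 0, lambda <= 1, gamma > 0)
  rowsum_ok <- function(x) all(abs(rowSums(x) - 1) < 1e-8)
  stopifnot(rowsum_ok(phi_T), rowsum_ok(phi_B),
            rowsum_ok(matrix(phi_A, A * 3L, W)))
  if (is.null(aspect_probs))
    aspect_probs <- matrix(rep(c(0.7, 0.2, 0.1), each = A), A, 3)
  stopifnot(all(dim(aspect_probs) == c(A, 3L)), rowsum_ok(aspect_probs))
  if (is.null(vocab)) vocab <- sprintf("w%03d", seq_len(W))
  structure(list(A = A, Z = Z, W = W, eta = eta, alpha = alpha,
                 phi_A = phi_A, phi_T = phi_T, phi_B = phi_B,
                 lambda = lambda, gamma = gamma,
                 aspect_probs = aspect_probs, vocab = vocab),
            class = "atam_params")
}

#' Well-separated generating parameters
#'
#' Deterministic parameters in which every ailment-aspect, topic and
#' background distribution concentrates \code{block_mass} of its probability
#' uniformly on its own disjoint block of the vocabulary, with the remaining
#' mass spread over all words (so every distribution has full support).
#' Per-ailment topic priors \code{alpha} favour topic \code{i} for ailment
#' \code{i}, coupling ailments to topics the way the model's per-ailment
#' topic priors are meant to.
#'
#' @param A,Z,W numbers of ailments, topics and vocabulary size; \code{W}
#'   must be at least \code{3A + Z + 3}.
#' @param block_mass probability mass a distribution puts on its own block.
#' @param lambda,gamma as in [atam_params()].
#' @return an \code{atam_params} object.
#' @export
separated_params <- function(A = 3, Z = 3, W = 200, block_mass = 0.95,
                             lambda = 0.2, gamma = 1) {
  nblock <- 3L * A + Z + 3L
  stopifnot(W >= nblock)
  bsize <- W %/% nblock
  block_dist <- function(b) {
    p <- rep((1 - block_mass) / W, W)
    idx <- ((b - 1L) * bsize + 1L):(b * bsize)
    p[idx] <- p[idx] + block_mass / bsize
    p
  }
  b <- 0L
  phi_A <- array(0, c(A, 3L, W))
  for (i in seq_len(A)) for (j in 1:3) {
    b <- b + 1L
    phi_A[i, j, ] <- block_dist(b)
  }
  phi_T <- matrix(0, Z, W)
  for (k in seq_len(Z)) {
    b <- b + 1L
    phi_T[k, ] <- block_dist(b)
  }
  phi_B <- matrix(0, 3L, W)
  for (j in 1:3) {
    b <- b + 1L
    phi_B[j, ] <- block_dist(b)
  }
  alpha <- matrix(0.3, A, Z)
  for (i in seq_len(A)) alpha[i, ((i - 1L) %% Z) + 1L] <- 3
  atam_params(eta = rep(1 / A, A), alpha = alpha, phi_A = phi_A,
              phi_T = phi_T, phi_B = phi_B, lambda = lambda, gamma = gamma)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Simulate a corpus from the generative story
#'
#' Each document draws an ailment from \code{eta}, topic proportions from
#' the ailment's Dirichlet, and an ailment-word proportion from
#' \code{Beta(gamma, gamma)}; each token draws an aspect from the ailment's
#' aspect distribution, a background switch with non-background probability
#' \code{lambda}, then either a background word, an ailment word, or a
#' topic and topic word. Aspect labels are attached as the observed
#' per-token labels.
#'
#' With \code{trend} a matrix (bins x A), documents are generated per time
#' bin with bin-specific ailment prevalence proportional to
#' \code{eta * trend[b, ]}, and weekly timestamps are attached, which plants
#' a known temporal intensity for trend-recovery studies. \code{D} is then
#' the number of documents per bin.
#'
#' With \code{lexicon_mode = TRUE} word draws are conditioned on disjoint
#' per-aspect vocabulary pools (thirds of the vocabulary) and a toy lexicon
#' over those pools is returned, so that [label_aspects()] reproduces the
#' generated aspect labels exactly.
#'
#' @param params an \code{atam_params} object.
#' @param D number of documents (per bin when \code{trend} is given).
#' @param N tokens per document.
#' @param seed optional integer seed.
#' @param trend optional bins x A non-negative intensity matrix.
#' @param start date of the first bin (weekly bins), default 2012-01-01.
#' @param regions optional character vector; regions are assigned uniformly
#'   at random when given.
#' @param lexicon_mode sample words within aspect pools and return a
#'   matching \code{keyphrase_lexicon}.
#' @return a list with \code{corpus} (an \code{atam_corpus}),
#'   \code{truth} (list: \code{a}, \code{tstate} in the model's composite
#'   coding, \code{theta}, \code{pi}, \code{bin}, \code{params}), and
#'   \code{lexicon} (in lexicon mode).
#' @export
simulate_corpus <- function(params, D, N, seed = NULL, trend = NULL,
                            start = as.Date("2012-01-01"), regions = NULL,
                            lexicon_mode = FALSE) {
  stopifnot(inherits(params, "atam_params"), D >= 0, N >= 0)
  if (!is.null(seed)) set.seed(seed)
  A <- params$A; Z <- params$Z; W <- params$W
  nbins <- if (is.null(trend)) 1L else nrow(trend)
  ndoc <- D * nbins
  pool <- NULL
  if (lexicon_mode) {
    third <- W %/% 3L
    pool <- rep(3L, W)
    pool[seq_len(third)] <- 1L
    pool[third + seq_len(third)] <- 2L
    # aspect j tokens draw words from pool j (renormalized restriction)
  }
  draw_word <- function(p, j) {
    if (!is.null(pool)) {
      p <- p * (pool == j)
      if (sum(p) == 0) p <- as.numeric(pool == j)
    }
    sample.int(W, 1L, prob = p)
  }
  a <- integer(ndoc)
  bin <- integer(ndoc)
  theta <- matrix(0, ndoc, Z)
  pi_d <- numeric(ndoc)
  words <- vector("list", ndoc)
  aspects <- vector("list", ndoc)
  tstates <- vector("list", ndoc)
  d <- 0L
  for (b in seq_len(nbins)) {
    eta_b <- if (is.null(trend)) params$eta else {
      e <- params$eta * trend[b, ]
      if (sum(e) <= 0) stop("trend row ", b, " has zero total intensity")
      e / sum(e)
    }
    for (r in seq_len(D)) {
      d <- d + 1L
      bin[d] <- b
      a[d] <- sample.int(A, 1L, prob = eta_b)
      theta[d, ] <- rdirichlet1(params$alpha[a[d], ])
      pi_d[d] <- rbeta(1, params$gamma, params$gamma)
      w <- integer(N); y <- integer(N); st <- integer(N)
      for (t in seq_len(N)) {
        y[t] <- sample.int(3L, 1L, prob = params$aspect_probs[a[d], ])
        if (runif(1) >= params$lambda) {          # background
          st[t] <- 1L
          w[t] <- draw_word(params$phi_B[y[t], ], y[t])
        } else if (runif(1) < pi_d[d]) {          # ailment word
          st[t] <- 2L
          w[t] <- draw_word(params$phi_A[a[d], y[t], ], y[t])
        } else {                                  # topic word
          k <- sample.int(Z, 1L, prob = theta[d, ])
          st[t] <- 2L + k
          w[t] <- draw_word(params$phi_T[k, ], y[t])
        }
      }
      words[[d]] <- w; aspects[[d]] <- y; tstates[[d]] <- st
    }
  }
  timestamps <- if (is.null(trend)) as.Date(rep(NA, ndoc))
  else start + 7L * (bin - 1L)
  region <- if (is.null(regions)) rep(NA_character_, ndoc)
  else sample(regions, ndoc, replace = TRUE)
  corpus <- structure(list(
    vocab = params$vocab,
    word = words,
    aspect = aspects,
    surface = lapply(words, function(w) params$vocab[w]),
    meta = data.frame(doc_id = paste0("sim", seq_len(ndoc)),
                      timestamp = timestamps, region = region,
                      stringsAsFactors = FALSE)),
    class = "atam_corpus")
  y_true <- unlist(aspects, use.names = FALSE)
  lex <- NULL
  if (lexicon_mode) {
    lex <- keyphrase_lexicon(params$vocab[pool != 1L],
                             c("symptom", "treatment")[pool[pool != 1L] - 1L])
    # regenerate the aspect labels through the lexicon path; by construction
    # they coincide with the generated y
    corpus$aspect <- lapply(corpus$surface, label_aspects, lexicon = lex)
  }
  list(corpus = corpus,
       truth = list(a = a, tstate = unlist(tstates, use.names = FALSE),
                    y = y_true, theta = theta, pi = pi_d, bin = bin,
                    params = params),
       lexicon = lex)
}

# O(n^3) Hungarian algorithm (potentials + augmenting paths) for the
# minimum-cost assignment; rows are assigned to columns.
hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)        # p[j+1]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1]) next
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j + 1] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_col <- integer(n)   # assign_col[row] = column
  for (j in seq_len(n)) if (p[j + 1] > 0L) assign_col[p[j + 1]] <- j
  assign_col
}

#' Match estimated mixture components to true components
#'
#' Resolves label switching for evaluation: finds the permutation of the
#' estimated components minimizing the total L1 distance to the true
#' components (optimal assignment on the pairwise L1 matrix).
#'
#' @param true_dists matrix, one true distribution per row.
#' @param est_dists matrix of the same shape, one estimated distribution per
#'   row.
#' @return integer vector \code{perm} with \code{perm[i]} the estimated row
#'   matched to true row \code{i}; total L1 cost in attribute \code{"cost"}.
#' @export
match_components <- function(true_dists, est_dists) {
  true_dists <- as.matrix(true_dists)
  est_dists <- as.matrix(est_dists)
  if (!all(dim(true_dists) == dim(est_dists)))
    stop("component sets must have equal dimensions")
  n <- nrow(true_dists)
  cost <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    cost[i, j] <- sum(abs(true_dists[i, ] - est_dists[j, ]))
  perm <- hungarian(cost)
  structure(perm, cost = sum(cost[cbind(seq_len(n), perm)]))
}

#' Score parameter recovery on a simulated corpus
#'
#' Matches estimated ailments and topics to the truth with
#' [match_components()] (ailments on the flattened aspect word
#' distributions, topics on the topic word distributions) and reports
#' document-ailment accuracy, mean L1 distances between matched word
#' distributions, and the mean absolute error of the recovered prevalence.
#' Posterior-averaged estimates ([averaged_estimates()]) are used when the
#' fit accumulated them.
#'
#' @param truth the \code{truth} element returned by [simulate_corpus()].
#' @param fit a fitted \code{atam} object on that corpus.
#' @param ailment_perm,topic_perm optional precomputed permutations (as
#'   returned by [match_components()]).
#' @return a list with \code{accuracy}, \code{phi_A_l1}, \code{phi_T_l1},
#'   \code{eta_abs_err}, and the permutations used.
#' @export
recovery_report <- function(truth, fit, ailment_perm = NULL,
                            topic_perm = NULL) {
  est <- averaged_estimates(fit)
  pars <- truth$params
  A <- pars$A; Z <- pars$Z; W <- pars$W
  flatten_A <- function(phi) {
    out <- matrix(0, A, 3L * W)
    for (i in seq_len(A)) out[i, ] <- as.vector(t(phi[i, , ]))
    out
  }
  if (is.null(ailment_perm))
    ailment_perm <- match_components(flatten_A(pars$phi_A),
                                     flatten_A(est$phi_A))
  if (is.null(topic_perm))
    topic_perm <- match_components(pars$phi_T, est$phi_T)
  # ailment_perm[i] = estimated label matched to true label i
  relabel <- integer(A)
  relabel[ailment_perm] <- seq_len(A)   # estimated -> true
  accuracy <- mean(relabel[fit$a] == truth$a, na.rm = TRUE)
  phi_A_l1 <- mean(vapply(seq_len(A), function(i)
    mean(vapply(1:3, function(j)
      sum(abs(pars$phi_A[i, j, ] - est$phi_A[ailment_perm[i], j, ])),
      0)), 0))
  phi_T_l1 <- mean(vapply(seq_len(Z), function(k)
    sum(abs(pars$phi_T[k, ] - est$phi_T[topic_perm[k], ])), 0))
  eta_abs_err <- mean(abs(pars$eta - est$eta[ailment_perm]))
  list(accuracy = accuracy, phi_A_l1 = phi_A_l1, phi_T_l1 = phi_T_l1,
       eta_abs_err = eta_abs_err, ailment_perm = as.integer(ailment_perm),
       topic_perm = as.integer(topic_perm))
}
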