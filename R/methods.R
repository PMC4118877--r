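# S3 methods for fitted objects.

#' @export
print.atam <- function(x, ...) {
  cat("Ailment topic aspect model\n")
  cat("  ailments:", x$A, " topics:", x$Z, " vocabulary:", x$W, "\n")
  cat("  documents:", sum(!is.na(x$a)), "active of", length(x$a),
      "; sweeps:", x$sweeps_done, "\n")
  if (length(x$loglik))
    cat("  joint log likelihood:", format(x$loglik[length(x$loglik)]), "\n")
  invisible(x)
}

#' @export
print.atam_control <- function(x, ...) {
  cat("ATAM control settings:\n")
  flat <- vapply(x, function(v) paste(format(v), collapse = ","), "")
  cat(paste0("  ", names(flat), " = ", flat, collapse = "\n"), "\n")
  invisible(x)
}

#' Top words of each ailment and topic
#'
#' @param object a fitted \code{atam}.
#' @param n_words how many words per distribution.
#' @param ... unused.
#' @return invisibly, a list of character matrices; also printed.
#' @export
summary.atam <- function(object, n_words = 8L, ...) {
  est <- estimate_parameters(object)
  top <- function(p) object$vocab[order(p, decreasing = TRUE)[seq_len(n_words)]]
  cat("Ailments (general | symptom | treatment):\n")
  ail <- vector("list", object$A)
  for (i in seq_len(object$A)) {
    nm <- if (!is.null(object$ailments) && i <= length(object$ailments))
      object$ailments[i] else paste0("ailment ", i)
    cat(sprintf("  %-14s %s\n", nm,
                paste(top(est$phi_A[i, 1, ]), collapse = " ")))
    cat(sprintf("  %-14s [sym] %s\n", "",
                paste(top(est$phi_A[i, 2, ])[1:min(5, n_words)],
                      collapse = " ")))
    cat(sprintf("  %-14s [trt] %s\n", "",
                paste(top(est$phi_A[i, 3, ])[1:min(5, n_words)],
                      collapse = " ")))
    ail[[i]] <- rbind(top(est$phi_A[i, 1, ]), top(est$phi_A[i, 2, ]),
                      top(est$phi_A[i, 3, ]))
  }
  cat("Topics:\n")
  for (k in seq_len(object$Z))
    cat(sprintf("  topic %-7d %s\n", k, paste(top(est$phi_T[k, ]),
                                              collapse = " ")))
  invisible(list(ailments = ail,
                 topics = lapply(seq_len(object$Z),
                                 function(k) top(est$phi_T[k, ]))))
}

#' @export
coef.atam <- function(object, ...) estimate_parameters(object)

#' @export
coef.lda_bg <- function(object, ...) estimate_parameters(object)

#' @export
logLik.atam <- function(object, ...) {
  structure(joint_log_likelihood(object), class = "logLik", df = NA_integer_,
            nobs = sum(!is.na(object$a)))
}

#' @export
logLik.lda_bg <- function(object, ...) {
  structure(joint_log_likelihood(object), class = "logLik", df = NA_integer_,
            nobs = length(object$flat$doc_ptr) - 1L)
}

#' @export
plot.atam <- function(x, ...) {
  if (!length(x$loglik)) stop("no log likelihood trace recorded")
  plot(x$ll_iter, x$loglik, type = "l", xlab = "sweep",
       ylab = "joint log likelihood", ...)
  invisible(x)
}

#' @export
plot.lda_bg <- plot.atam

#' @export
print.lda_bg <- function(x, ...) {
  cat("LDA with background distribution\n")
  cat("  topics:", x$Z, " vocabulary:", x$W,
      " documents:", length(x$flat$doc_ptr) - 1L,
      "; sweeps:", x$sweeps_done, "\n")
  if (length(x$loglik))
    cat("  joint log likelihood:", format(x$loglik[length(x$loglik)]), "\n")
  invisible(x)
}

#' Assign ailments to new documents under a fitted model
#'
#' Maps the new corpus onto the model vocabulary (unknown words are skipped
#' with a warning) and initializes each document greedily from the fitted
#' conditionals, exactly as the incremental data schedule does; the fitted
#' state itself is not modified.
#'
#' @param object a fitted \code{atam}.
#' @param newdata an \code{atam_corpus}.
#' @param mode \code{"argmax"} (default) or \code{"sample"}.
#' @param ... unused.
#' @return integer vector of ailment assignments for the new documents.
#' @export
predict.atam <- function(object, newdata, mode = c("argmax", "sample"), ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(newdata, "atam_corpus"))
  aligned <- align_corpus(newdata, object$vocab)
  flat_new <- flatten_corpus(aligned)
  D_old <- length(object$a)
  flat <- list(doc_ptr = c(object$flat$doc_ptr,
                           flat_new$doc_ptr[-1] + length(object$flat$word)),
               word = c(object$flat$word, flat_new$word),
               aspect = c(object$flat$aspect, flat_new$aspect))
  Dn <- n_docs(aligned)
  a <- c(a0(object$a), rep(-1L, Dn))
  ts <- c(ts0(object$tstate), rep(-1L, length(flat_new$word)))
  res <- cpp_atam_extend(flat, a, ts, priors_list(object), NULL,
                         D_old + seq_len(Dn) - 1L, mode == "sample")
  from0(res$a)[D_old + seq_len(Dn)]
}

#' Simulate a corpus from a fitted model
#'
#' Draws a new corpus from the generative story at the fitted posterior-mean
#' parameters (a parametric-bootstrap style check of what the fitted model
#' believes the data look like).
#'
#' @param object a fitted \code{atam}.
#' @param nsim number of documents.
#' @param seed optional integer seed.
#' @param N tokens per document.
#' @param ... unused.
#' @return the list returned by [simulate_corpus()].
#' @export
simulate.atam <- function(object, nsim = 100L, seed = NULL, N = 12L, ...) {
  est <- estimate_parameters(object)
  p <- tabulate(object$flat$aspect + 1L, 3L) + 1
  aspect_probs <- matrix(rep(p / sum(p), each = object$A), object$A, 3)
  pars <- atam_params(eta = est$eta, alpha = object$alpha,
                      phi_A = est$phi_A, phi_T = est$phi_T, phi_B = est$phi_B,
                      lambda = object$lambda, gamma = object$gamma,
                      aspect_probs = aspect_probs, vocab = object$vocab)
  simulate_corpus(pars, D = nsim, N = N, seed = seed)
}
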