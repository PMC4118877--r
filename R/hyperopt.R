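# Dirichlet-multinomial hyperparameter estimation by fixed-point iteration.
# The free-vector update and the fixed-mean precision update both derive
# from a lower bound on the marginal likelihood, so each pass is
# non-decreasing in the group's Dirichlet-multinomial log likelihood.

#' Dirichlet-multinomial log likelihood of a group of count vectors
#'
#' @param counts matrix (groups x categories) of non-negative counts; a
#'   single vector is treated as one group.
#' @param alpha positive Dirichlet parameter vector.
#' @return the summed log marginal likelihood of the counts.
#' @export
dirmult_loglik <- function(counts, alpha) {
  counts <- rbind(counts)
  stopifnot(ncol(counts) == length(alpha), all(alpha > 0))
  a0 <- sum(alpha)
  n <- rowSums(counts)
  sum(lgamma(a0) - lgamma(a0 + n)) +
    sum(lgamma(sweep(counts, 2, alpha, "+")) -
          matrix(lgamma(alpha), nrow(counts), length(alpha), byrow = TRUE))
}

#' One fixed-point update of a free Dirichlet parameter vector
#'
#' Minka's digamma-ratio update for the maximum-likelihood Dirichlet of a
#' Dirichlet-multinomial, applied componentwise. Entries are clamped to a
#' positive floor; a group with no counts leaves \code{alpha} unchanged.
#'
#' @param counts matrix (groups x categories); one row per count vector
#'   sharing the prior.
#' @param alpha current positive parameter vector.
#' @param floor positive lower clamp (default \code{1e-6}).
#' @return the updated vector.
#' @export
update_alpha <- function(counts, alpha, floor = 1e-6) {
  counts <- rbind(counts)
  if (nrow(counts) == 0L || sum(counts) == 0) return(alpha)
  stopifnot(ncol(counts) == length(alpha), all(alpha > 0))
  n <- rowSums(counts)
  a0 <- sum(alpha)
  den <- sum(digamma(n + a0) - digamma(a0))
  if (den <= 0) return(alpha)
  num <- colSums(digamma(sweep(counts, 2, alpha, "+"))) -
    nrow(counts) * digamma(alpha)
  pmax(alpha * num / den, floor)
}

#' One fixed-point update of a Dirichlet precision with fixed mean
#'
#' For a prior parameterized as \eqn{s \cdot m} with the mean \eqn{m} held
#' fixed, only the scalar precision \eqn{s} is optimized.
#'
#' @param counts matrix (groups x categories).
#' @param m the fixed mean (a probability vector over categories).
#' @param s current positive precision.
#' @param floor positive lower clamp (default \code{1e-6}).
#' @return the updated precision.
#' @export
update_precision <- function(counts, m, s, floor = 1e-6) {
  counts <- rbind(counts)
  if (nrow(counts) == 0L || sum(counts) == 0) return(s)
  stopifnot(ncol(counts) == length(m), s > 0, all(m >= 0))
  n <- rowSums(counts)
  den <- sum(digamma(n + s) - digamma(s))
  if (den <= 0) return(s)
  sm <- s * m
  pos <- m > 0
  num <- sum(sweep(digamma(sweep(counts[, pos, drop = FALSE], 2, sm[pos], "+")),
                   2, digamma(sm[pos]), "-") %*% m[pos])
  max(s * num / den, floor)
}

# Interleaved optimization event: per-ailment alpha vectors (free) on the
# topic counts of that ailment's documents, and per-ailment precisions
# (mean fixed) on the three aspect word-count vectors.
optimize_hyperparameters <- function(object) {
  ctl <- object$control
  st <- object$stats
  act <- !is.na(object$a)
  trace <- list()
  for (p in seq_len(ctl$hyper_passes)) {
    if (ctl$optimize_alpha) {
      for (i in seq_len(object$A)) {
        rows <- which(act & object$a == i)
        if (length(rows) < ctl$min_group) next
        object$alpha[i, ] <- update_alpha(st$n_doc_topic[rows, , drop = FALSE],
                                          object$alpha[i, ],
                                          floor = ctl$alpha_floor)
      }
    }
    if (ctl$optimize_s) {
      for (i in seq_len(object$A)) {
        cnt <- st$n_ail_aspect_word[i, , , drop = FALSE]
        dim(cnt) <- c(object$Y, object$W)
        object$s[i] <- update_precision(cnt, object$m[i, ], object$s[i],
                                        floor = ctl$s_floor)
      }
    }
  }
  ev <- data.frame(iteration = object$sweeps_done,
                   parameter = c(paste0("alpha_sum_", seq_len(object$A)),
                                 paste0("s_", seq_len(object$A))),
                   value = c(rowSums(object$alpha), object$s))
  object$hyper_trace <- rbind(object$hyper_trace, ev)
  object
}

#' Write the hyperparameter trajectory of a fit as CSV
#'
#' One row per optimization event and parameter: iteration, parameter id,
#' value.
#'
#' @param object a fitted \code{atam} object.
#' @param path output CSV path.
#' @export
write_hyper_trace <- function(object, path) {
  stopifnot(inherits(object, "atam"))
  write.csv(object$hyper_trace %||% data.frame(), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
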