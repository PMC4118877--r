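#' Build informative ailment word priors from reference texts
#'
#' For each ailment the prior mean \eqn{m_i} over the vocabulary is the
#' empirical unigram distribution of that ailment's reference texts (e.g.
#' consumer health articles about the condition), smoothed by a pseudo-count
#' so every vocabulary word keeps support. The implied Dirichlet parameter is
#' \eqn{\beta_i = s_i m_i}, with the precision \eqn{s_i} expressing how
#' strongly the model should trust the reference distribution; precisions are
#' adjusted during fitting to maximize marginal likelihood.
#'
#' @param reference_texts named list, one element per ailment; each element a
#'   character vector of raw reference texts.
#' @param vocab the model vocabulary (character vector).
#' @param smoothing pseudo-count added to every word (default 0.01). With
#'   \code{smoothing = 0} words absent from the references get zero mass and
#'   can never be attributed to that ailment.
#' @param s_init initial precision for every ailment (default 100).
#' @return an object of class \code{ailment_priors}: list with matrix
#'   \code{m} (ailments x vocabulary, rows sum to 1), numeric \code{s}, and
#'   \code{ailments} (names).
#' @examples
#' pr <- build_prior_means(list(flu = "flu fever cough fever"),
#'                         vocab = c("flu", "fever", "cough", "tv"))
#' pr$m
#' @export
build_prior_means <- function(reference_texts, vocab, smoothing = 0.01,
                              s_init = 100) {
  stopifnot(is.list(reference_texts), smoothing >= 0, s_init > 0)
  W <- length(vocab)
  A <- length(reference_texts)
  m <- matrix(0, A, W, dimnames = list(names(reference_texts), vocab))
  for (i in seq_len(A)) {
    toks <- unlist(tokenize_many(reference_texts[[i]]), use.names = FALSE)
    cnt <- table(factor(toks, levels = vocab))
    tot <- sum(cnt) + smoothing * W
    if (sum(cnt) == 0)
      warning("ailment ", i, " has no usable reference text; uniform prior mean")
    m[i, ] <- if (tot > 0) (as.numeric(cnt) + smoothing) / tot else rep(1 / W, W)
  }
  structure(list(m = m, s = rep(s_init, A),
                 ailments = names(reference_texts)),
            class = "ailment_priors")
}

#' Construct an ailment prior set from explicit mean vectors
#'
#' @param m matrix (ailments x vocabulary) of prior means, rows summing to 1.
#' @param s precision scalar or vector (recycled).
#' @param ailments optional ailment names.
#' @return an \code{ailment_priors} object.
#' @export
ailment_priors <- function(m, s = 100, ailments = rownames(m)) {
  m <- as.matrix(m)
  stopifnot(all(m >= 0), all(abs(rowSums(m) - 1) < 1e-8))
  structure(list(m = m, s = rep_len(as.numeric(s), nrow(m)),
                 ailments = ailments),
            class = "ailment_priors")
}

#' Read per-ailment reference corpora from a directory
#'
#' Each entry of \code{path} may be a plain-text file (one ailment) or a
#' subdirectory of plain-text files; the file or directory name is the
#' ailment name.
#'
#' @param path directory.
#' @return named list of character vectors, suitable for
#'   [build_prior_means()].
#' @export
read_reference_dir <- function(path) {
  entries <- sort(list.files(path, full.names = TRUE))
  out <- list()
  for (e in entries) {
    nm <- sub("\\.[^.]*$", "", basename(e))
    if (dir.exists(e)) {
      fls <- sort(list.files(e, full.names = TRUE))
      out[[nm]] <- unlist(lapply(fls, readLines, warn = FALSE),
                          use.names = FALSE)
    } else {
      out[[nm]] <- readLines(e, warn = FALSE)
    }
  }
  out
}

#' @export
print.ailment_priors <- function(x, ...) {
  cat("Ailment prior set:", nrow(x$m), "ailments over", ncol(x$m),
      "words; precisions", paste(signif(x$s, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Control parameters for model fitting
#'
#' Collects every hyperparameter and run setting with its default. The
#' defaults are the model's standard operating point: 20 ailments and 20
#' topics, a non-background probability \code{lambda} of 0.2 (so 80% of
#' tokens are treated as background noise a priori), symmetric
#' Dirichlet/Beta regularizers \code{sigma} and \code{gamma} of 1, a flat
#' Dirichlet 0.01 on topic and background word distributions, and 8000 Gibbs
#' iterations with hyperparameter optimization every 10 sweeps.
#'
#' @param A number of ailments.
#' @param Z number of topics.
#' @param iterations total Gibbs sweeps.
#' @param lambda probability that a token is non-background, in (0,1) for
#'   ATAM fitting (the limits 0 and 1 are allowed in the conditionals).
#' @param gamma symmetric Beta parameter for each document's ailment/topic
#'   split proportion.
#' @param sigma symmetric Dirichlet parameter over ailment prevalence.
#' @param beta symmetric Dirichlet for topic and background word
#'   distributions.
#' @param s_init initial word-prior precision when no reference priors are
#'   supplied.
#' @param smoothing pseudo-count used when building prior means.
#' @param increments number of data increments (1 = feed all data at once;
#'   10 matches the incremental schedule used at scale).
#' @param shards number of count-pooling shards per sweep (1 = exact Gibbs).
#' @param hyper_every sweeps between hyperparameter optimization events
#'   (0 disables optimization).
#' @param hyper_passes fixed-point passes per optimization event.
#' @param optimize_alpha,optimize_s toggle the two update families.
#' @param min_group smallest per-ailment document group that is optimized.
#' @param alpha_floor,s_floor positive floors for the updates.
#' @param ll_every evaluate the joint log likelihood every this many sweeps.
#' @param checkpoint_every write a checkpoint every this many sweeps
#'   (\code{Inf} = only at the end when a directory is given).
#' @param checkpoint_dir directory for checkpoints (\code{NULL} = none).
#' @param extend_mode how newly activated documents are initialized:
#'   \code{"argmax"} (greedy optimum under the current state) or
#'   \code{"sample"}.
#' @param average_estimates accumulate posterior-mean parameter estimates
#'   over post-burn-in sweeps (reducing single-sample noise); the default
#'   \code{FALSE} keeps final-state estimates.
#' @param burnin_frac fraction of the run discarded before averaging.
#' @param verbose print progress.
#' @return a list of class \code{atam_control}.
#' @export
atam_control <- function(A = 20L, Z = 20L, iterations = 8000L, lambda = 0.2,
                         gamma = 1.0, sigma = 1.0, beta = 0.01,
                         s_init = 100, smoothing = 0.01,
                         increments = 1L, shards = 1L,
                         hyper_every = 10L, hyper_passes = 5L,
                         optimize_alpha = TRUE, optimize_s = TRUE,
                         min_group = 5L, alpha_floor = 1e-6, s_floor = 1e-6,
                         ll_every = 1L, checkpoint_every = Inf,
                         checkpoint_dir = NULL,
                         extend_mode = c("argmax", "sample"),
                         average_estimates = FALSE, burnin_frac = 0.5,
                         verbose = FALSE) {
  extend_mode <- match.arg(extend_mode)
  stopifnot(A >= 1, Z >= 1, iterations >= 0, lambda >= 0, lambda <= 1,
            gamma > 0, sigma > 0, beta > 0, s_init > 0, increments >= 1,
            shards >= 1)
  structure(list(A = as.integer(A), Z = as.integer(Z), Y = 3L,
                 iterations = as.integer(iterations), lambda = lambda,
                 gamma = gamma, sigma = sigma, beta = beta, s_init = s_init,
                 smoothing = smoothing, increments = as.integer(increments),
                 shards = as.integer(shards),
                 hyper_every = as.integer(hyper_every),
                 hyper_passes = as.integer(hyper_passes),
                 optimize_alpha = optimize_alpha, optimize_s = optimize_s,
                 min_group = as.integer(min_group),
                 alpha_floor = alpha_floor, s_floor = s_floor,
                 ll_every = as.integer(ll_every),
                 checkpoint_every = checkpoint_every,
                 checkpoint_dir = checkpoint_dir,
                 extend_mode = extend_mode,
                 average_estimates = average_estimates,
                 burnin_frac = burnin_frac, verbose = verbose),
            class = "atam_control")
}

#' Read fitting settings from a YAML config file
#'
#' Any field of [atam_control()] may be given; unknown fields are an error.
#' The resolved settings are echoed with \code{message()} so runs are
#' self-documenting.
#'
#' @param path YAML file.
#' @param quiet suppress the echo.
#' @return an \code{atam_control} list.
#' @export
read_atam_config <- function(path, quiet = FALSE) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(atam_control))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  ctl <- do.call(atam_control, cfg)
  if (!quiet)
    message("config: ", paste(names(cfg), unlist(cfg), sep = "=",
                              collapse = ", "))
  ctl
}

# Expand a (possibly partial) prior set to A ailments over vocabulary W:
# missing slots get uniform means with the default precision.
complete_priors <- function(priors, A, W, s_init) {
  if (is.null(priors)) {
    return(list(m = matrix(1 / W, A, W), s = rep(s_init, A),
                ailments = NULL))
  }
  stopifnot(inherits(priors, "ailment_priors"))
  if (ncol(priors$m) != W)
    stop("prior means are over ", ncol(priors$m),
         " words but the vocabulary has ", W)
  if (nrow(priors$m) > A)
    stop("more prior sets (", nrow(priors$m), ") than ailments (", A, ")")
  m <- rbind(priors$m, matrix(1 / W, A - nrow(priors$m), W))
  s <- c(priors$s, rep(s_init, A - nrow(priors$m)))
  list(m = unname(m), s = unname(s), ailments = priors$ailments)
}
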