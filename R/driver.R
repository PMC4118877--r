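# Training orchestration: incremental data schedule, sharded count pooling,
# hyperparameter interleaving, checkpoints.

#' Build an incremental training schedule
#'
#' Data are fed to the sampler in increasing fractions \eqn{t = 1/n, 2/n,
#' \ldots, 1}; the sweeps spent at fraction \eqn{t} are proportional to
#' \eqn{1/t}, so more iterations are spent on less data. Each level gets at
#' least one sweep; the remaining sweeps are distributed by a highest-quotient
#' (D'Hondt) rule on the \eqn{1/t} weights, which keeps the counts
#' non-increasing in \eqn{t} and summing exactly to \code{total_iters}.
#'
#' @param total_iters total Gibbs sweeps (at least \code{num_increments}).
#' @param num_increments number of data levels (default 10, i.e. 10\%
#'   increments).
#' @return a data frame with columns \code{fraction} and \code{sweeps}.
#' @examples
#' make_schedule(100, 10)
#' @export
make_schedule <- function(total_iters, num_increments = 10L) {
  total_iters <- as.integer(total_iters)
  num_increments <- as.integer(num_increments)
  if (num_increments < 1L || total_iters < num_increments)
    stop("total_iters must be at least num_increments (both positive)")
  frac <- seq_len(num_increments) / num_increments
  w <- 1 / frac
  sweeps <- rep.int(1L, num_increments)
  for (r in seq_len(total_iters - num_increments)) {
    q <- w / (sweeps + 1)
    pick <- which.max(q)  # ties resolve to the smallest fraction
    sweeps[pick] <- sweeps[pick] + 1L
  }
  data.frame(fraction = frac, sweeps = sweeps)
}

#' Bring new documents into a fitted sampler state
#'
#' Activates documents that were held out by the incremental schedule.
#' Each new document's ailment and token states are initialized to the
#' greedy optimum of the current conditionals (documents processed in
#' order): a prevalence-based ailment guess, token states left to right,
#' then a final ailment pass given the chosen token states. With
#' \code{mode = "sample"} draws replace the argmax.
#'
#' @param object an \code{atam} state.
#' @param docs integer vector of document indices to activate.
#' @param mode \code{"argmax"} (default) or \code{"sample"}.
#' @return the updated object (audit-consistent).
#' @export
extend_data <- function(object, docs, mode = c("argmax", "sample")) {
  stopifnot(inherits(object, "atam"))
  mode <- match.arg(mode)
  docs <- as.integer(docs)
  if (!length(docs)) return(object)
  if (any(!is.na(object$a[docs])))
    stop("document(s) already active: ",
         paste(docs[!is.na(object$a[docs])][1], collapse = ", "))
  res <- cpp_atam_extend(object$flat, a0(object$a), ts0(object$tstate),
                         priors_list(object), object$stats, docs - 1L,
                         mode == "sample")
  object$a <- from0(res$a)
  object$tstate <- from0(res$tstate)
  object$stats <- res$stats
  object
}

#' One sweep with sharded count pooling
#'
#' Approximate distributed sweep: documents are partitioned into shards;
#' each shard sweeps its own documents against a stale snapshot of the
#' global word-count tables (plus its own live document-level tables), and
#' afterwards the global tables are rebuilt from the pooled latent state.
#' With a single shard this is exactly [gibbs_sweep()].
#'
#' @param object an \code{atam} state.
#' @param shards number of shards, or a list of disjoint active document
#'   index vectors covering all active documents.
#' @param nsweeps number of pooled sweeps.
#' @return the updated object.
#' @export
pooled_sweep <- function(object, shards = 1L, nsweeps = 1L) {
  stopifnot(inherits(object, "atam"))
  act <- which(!is.na(object$a))
  if (is.numeric(shards) && length(shards) == 1L) {
    ns <- as.integer(shards)
    shards <- split(act, rep_len(seq_len(ns), length(act)))
  } else {
    stopifnot(is.list(shards))
    flat_docs <- unlist(shards, use.names = FALSE)
    if (anyDuplicated(flat_docs)) stop("shards overlap")
    if (!setequal(flat_docs, act))
      stop("shards must cover exactly the active documents")
  }
  pl <- priors_list(object)
  for (sw in seq_len(nsweeps)) {
    snapshot <- object$stats
    a_cur <- a0(object$a)
    ts_cur <- ts0(object$tstate)
    a_new <- a_cur
    ts_new <- ts_cur
    for (sh in shards) {
      if (!length(sh)) next
      res <- cpp_atam_run(object$flat, a_cur, ts_cur, pl, snapshot,
                          as.integer(sh) - 1L, 1L, 0L, 0L, integer(0), FALSE)
      a_new[sh] <- res$a[sh]
      sel <- token_slots(object$flat, sh)
      ts_new[sel] <- res$tstate[sel]
    }
    object$a <- from0(a_new)
    object$tstate <- from0(ts_new)
    object$stats <- cpp_atam_recount(object$flat, a_new, ts_new, pl)
    object$sweeps_done <- object$sweeps_done + 1L
  }
  object
}

token_slots <- function(flat, docs) {
  unlist(lapply(docs, function(d)
    if (flat$doc_ptr[d] < flat$doc_ptr[d + 1])
      (flat$doc_ptr[d] + 1L):flat$doc_ptr[d + 1] else integer(0)),
    use.names = FALSE)
}

#' Fit the ailment topic aspect model
#'
#' Runs collapsed Gibbs sampling with interleaved hyperparameter
#' optimization, optionally feeding data in increments (more sweeps on less
#' data) and pooling counts across shards within each sweep.
#'
#' @param corpus an \code{atam_corpus}.
#' @param priors optional \code{ailment_priors} built with
#'   [build_prior_means()].
#' @param control an [atam_control()] list; when \code{control} is missing,
#'   settings can be passed directly (e.g. \code{atam(x, A = 3, Z = 3,
#'   iterations = 500)}).
#' @param seed integer seed; the fit is fully reproducible from
#'   \code{(corpus, control, seed)} in single-shard mode.
#' @param ... forwarded to [atam_control()] when \code{control} is missing.
#' @return an object of class \code{atam}; see [estimate_parameters()],
#'   [coef.atam()], [summary.atam()].
#' @examples
#' sim <- simulate_corpus(separated_params(A = 2, Z = 2, W = 30),
#'                        D = 60, N = 8, seed = 1)
#' fit <- atam(sim$corpus, A = 2, Z = 2, iterations = 30, seed = 1)
#' fit
#' @export
atam <- function(corpus, priors = NULL, control, seed = NULL, ...) {
  if (missing(control)) control <- atam_control(...)
  else if (length(list(...))) stop("pass settings either via control or ...")
  if (!is.null(seed)) set.seed(seed)
  D <- n_docs(corpus)
  plan <- if (control$iterations == 0L)
    data.frame(fraction = 1, sweeps = 0L)
  else make_schedule(control$iterations, control$increments)
  doc_order <- if (control$increments > 1L) sample.int(D) else seq_len(D)
  n_at <- pmin(D, as.integer(ceiling(plan$fraction * D)))
  object <- atam_init(corpus, priors, control,
                      active = sort(doc_order[seq_len(n_at[1])]))
  object$doc_order <- doc_order
  object$call <- match.call()
  run_training(object, plan, n_at)
}

# Shared training loop (also used by resume): runs from object$sweeps_done to
# the end of `plan`, activating increments and optimizing hyperparameters at
# their boundaries.
run_training <- function(object, plan, n_at) {
  ctl <- object$control
  bounds <- cumsum(plan$sweeps)
  total <- bounds[length(bounds)]
  object$plan <- plan
  object$n_at <- n_at
  while (object$sweeps_done < total) {
    incr <- findInterval(object$sweeps_done, bounds) + 1L
    if (incr > object$increments_done) {
      prev <- sort(object$doc_order[seq_len(n_at[object$increments_done])])
      now <- sort(object$doc_order[seq_len(n_at[incr])])
      object <- extend_data(object, setdiff(now, prev),
                            mode = ctl$extend_mode)
      object$increments_done <- incr
    }
    stop_at <- bounds[incr]
    if (ctl$hyper_every > 0L) {
      next_opt <- (object$sweeps_done %/% ctl$hyper_every + 1L) *
        ctl$hyper_every
      stop_at <- min(stop_at, next_opt)
    }
    if (is.finite(ctl$checkpoint_every)) {
      next_ck <- (object$sweeps_done %/% ctl$checkpoint_every + 1L) *
        ctl$checkpoint_every
      stop_at <- min(stop_at, next_ck)
    }
    chunk <- stop_at - object$sweeps_done
    object <- if (ctl$shards > 1L)
      pooled_sweep(object, ctl$shards, nsweeps = chunk)
    else gibbs_sweep(object, nsweeps = chunk)
    # cadences coarser than the chunk are handled here rather than per sweep
    if (ctl$ll_every > chunk && object$sweeps_done %% ctl$ll_every == 0L) {
      object$loglik <- c(object$loglik, joint_log_likelihood(object))
      object$ll_iter <- c(object$ll_iter, object$sweeps_done)
    }
    if (ctl$hyper_every > 0L &&
        object$sweeps_done %% ctl$hyper_every == 0L)
      object <- optimize_hyperparameters(object)
    if (isTRUE(ctl$average_estimates) &&
        object$sweeps_done > ctl$burnin_frac * total)
      object <- accumulate_estimates(object)
    if (!is.null(ctl$checkpoint_dir) &&
        ((is.finite(ctl$checkpoint_every) &&
          object$sweeps_done %% ctl$checkpoint_every == 0L) ||
         object$sweeps_done >= total))
      save_checkpoint(object, file.path(ctl$checkpoint_dir,
                                        sprintf("checkpoint-%06d.json",
                                                object$sweeps_done)))
    if (ctl$verbose)
      message("sweep ", object$sweeps_done, "/", total, "  logLik ",
              if (length(object$loglik))
                signif(object$loglik[length(object$loglik)], 8) else NA)
  }
  object
}

# Running mean of posterior-mean estimates across post-burn-in chunks.
accumulate_estimates <- function(object) {
  e <- estimate_parameters(object)
  n <- (object$est_n %||% 0L) + 1L
  acc <- object$est_accum
  object$est_accum <- if (is.null(acc)) e
  else mapply(function(old, new) old + (new - old) / n, acc, e,
              SIMPLIFY = FALSE)
  object$est_n <- n
  object
}

#' Posterior-averaged parameter estimates
#'
#' When a fit was run with \code{average_estimates = TRUE}, returns the
#' running mean of the posterior-mean estimates over the post-burn-in
#' sweeps, which smooths out single-sample assignment noise; otherwise
#' falls back to [estimate_parameters()] on the final state.
#'
#' @param object a fitted \code{atam}.
#' @return the same list as [estimate_parameters()].
#' @export
averaged_estimates <- function(object) {
  if (!is.null(object$est_accum)) object$est_accum
  else estimate_parameters(object)
}

#' Write a sampler checkpoint
#'
#' A single JSON file holding the configuration, vocabulary hash, latent
#' assignments, hyperparameters, RNG state and iteration counters; together
#' with the corpus it restores the run bit-exactly.
#'
#' @param object an \code{atam} state.
#' @param path output file.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "atam"))
  if (!exists(".Random.seed", globalenv())) runif(1)
  ck <- list(format = "atam-checkpoint", version = 1L,
             vocab_hash = object$vocab_hash,
             control = object$control[setdiff(names(object$control),
                                              "checkpoint_dir")],
             checkpoint_dir = object$control$checkpoint_dir,
             A = object$A, Z = object$Z, W = object$W,
             alpha = object$alpha, m = object$m, s = object$s,
             a = object$a, tstate = object$tstate,
             sweeps_done = object$sweeps_done,
             increments_done = object$increments_done,
             doc_order = object$doc_order,
             plan = object$plan, n_at = object$n_at,
             loglik = object$loglik, ll_iter = object$ll_iter,
             rng_state = get(".Random.seed", globalenv()))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  writeLines(jsonlite::toJSON(ck, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null"), path)
  invisible(path)
}

#' Restore a sampler state from a checkpoint
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @param corpus the same corpus the checkpoint was trained on (verified by
#'   vocabulary hash).
#' @return an \code{atam} state.
#' @export
load_checkpoint <- function(path, corpus) {
  ck <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                           simplifyMatrix = TRUE)
  stopifnot(identical(ck$format, "atam-checkpoint"))
  if (vocab_hash(corpus$vocab) != ck$vocab_hash)
    stop("corpus vocabulary does not match the checkpoint")
  ctl <- ck$control
  ctl$checkpoint_every <- if (is.null(ctl$checkpoint_every) ||
                              is.character(ctl$checkpoint_every))
    Inf else ctl$checkpoint_every
  ctl$checkpoint_dir <- ck$checkpoint_dir
  ctl <- structure(ctl, class = "atam_control")
  obj <- structure(list(
    flat = flatten_corpus(corpus), vocab = corpus$vocab,
    vocab_hash = ck$vocab_hash, meta = corpus$meta,
    A = ck$A, Z = ck$Z, W = ck$W, Y = 3L,
    lambda = ctl$lambda, gamma = ctl$gamma, sigma = ctl$sigma,
    beta = ctl$beta,
    alpha = matrix(ck$alpha, ck$A, ck$Z),
    m = matrix(ck$m, ck$A, ck$W), s = as.numeric(ck$s),
    ailments = NULL,
    a = as.integer(ck$a), tstate = as.integer(ck$tstate), stats = NULL,
    loglik = as.numeric(ck$loglik), ll_iter = as.integer(ck$ll_iter),
    sweeps_done = as.integer(ck$sweeps_done),
    increments_done = as.integer(ck$increments_done),
    doc_order = as.integer(ck$doc_order),
    plan = as.data.frame(ck$plan), n_at = as.integer(ck$n_at),
    hyper_trace = NULL, control = ctl, call = NULL),
    class = "atam")
  obj$stats <- cpp_atam_recount(obj$flat, a0(obj$a), ts0(obj$tstate),
                                priors_list(obj))
  attr(obj, "rng_state") <- as.integer(ck$rng_state)
  obj
}

#' Resume an interrupted training run
#'
#' Continues the run to its configured total number of sweeps, reproducing
#' the uninterrupted trajectory bit-exactly (the checkpoint carries the RNG
#' state).
#'
#' @param checkpoint a checkpoint path or an object from
#'   [load_checkpoint()].
#' @param corpus the training corpus.
#' @return the completed \code{atam} fit.
#' @export
atam_resume <- function(checkpoint, corpus) {
  object <- if (is.character(checkpoint)) load_checkpoint(checkpoint, corpus)
  else checkpoint
  rng <- attr(object, "rng_state")
  if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv())
  run_training(object, object$plan, object$n_at)
}
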