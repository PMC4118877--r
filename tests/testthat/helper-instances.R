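# Small instance builders shared across tests.

rdir <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

# Build an atam_corpus directly from word-id and aspect vectors.
manual_corpus <- function(word, aspect, W, timestamps = NULL, regions = NULL) {
  vocab <- sprintf("w%02d", seq_len(W))
  D <- length(word)
  structure(list(
    vocab = vocab,
    word = lapply(word, as.integer),
    aspect = lapply(aspect, as.integer),
    surface = lapply(word, function(w) vocab[w]),
    meta = data.frame(doc_id = paste0("d", seq_len(D)),
                      timestamp = if (is.null(timestamps))
                        as.Date(rep(NA, D)) else as.Date(timestamps),
                      region = if (is.null(regions)) rep(NA_character_, D)
                      else regions,
                      stringsAsFactors = FALSE)),
    class = "atam_corpus")
}

# Random tiny ATAM state with asymmetric hyperparameters (so oracle checks
# exercise every factor).
tiny_atam <- function(A = 2, Z = 2, W = 4, doc_lens = c(2, 1, 1),
                      lambda = 0.3, gamma = 0.8, sigma = 1.2, beta = 0.05,
                      random_hypers = TRUE) {
  word <- lapply(doc_lens, function(n) sample.int(W, n, replace = TRUE))
  aspect <- lapply(doc_lens, function(n) sample.int(3L, n, replace = TRUE))
  corpus <- manual_corpus(word, aspect, W)
  ctl <- atam_control(A = A, Z = Z, lambda = lambda, gamma = gamma,
                      sigma = sigma, beta = beta, iterations = 0)
  pri <- ailment_priors(rdir(A, rep(1, W)), s = runif(A, 1, 5))
  obj <- atam_init(corpus, pri, ctl)
  if (random_hypers) obj$alpha <- matrix(runif(A * Z, 0.2, 2), A, Z)
  obj
}

tiny_lda <- function(Z = 2, W = 4, doc_lens = c(2, 1, 1), lambda = 0.3,
                     beta = 0.05) {
  word <- lapply(doc_lens, function(n) sample.int(W, n, replace = TRUE))
  aspect <- lapply(doc_lens, function(n) rep(1L, n))
  corpus <- manual_corpus(word, aspect, W)
  ctl <- atam_control(Z = Z, lambda = lambda, beta = beta, iterations = 0)
  obj <- lda_init(corpus, ctl)
  obj$alpha <- runif(Z, 0.2, 2)
  obj
}

# Random small corpus (for audit-style property checks).
random_corpus <- function(D = 5, W = 8, max_len = 6) {
  lens <- sample.int(max_len, D, replace = TRUE)
  manual_corpus(lapply(lens, function(n) sample.int(W, n, replace = TRUE)),
                lapply(lens, function(n) sample.int(3L, n, replace = TRUE)),
                W)
}
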