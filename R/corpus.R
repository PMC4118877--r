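#' @useDynLib atam, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor rbeta rgamma runif sd setNames
#' @importFrom utils head read.csv write.csv
NULL

# Aspect codes used throughout: 1 = general, 2 = symptom, 3 = treatment.
ASPECTS <- c("general", "symptom", "treatment")

#' Tokenize informal text
#'
#' Lower-cases the input and splits it into word tokens and punctuation
#' tokens. Maximal runs of punctuation or symbol characters are treated as
#' word separators but are themselves retained as tokens, which suits noisy
#' social-media text where emoticons and punctuation carry signal.
#' Whitespace is never emitted.
#'
#' @param text a single character string (may be empty).
#' @return a character vector of tokens, zero-length for empty input.
#' @examples
#' tokenize("damn flu, home with a fever watching TV.")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- tolower(text)
  mm <- gregexpr("[\\p{L}\\p{N}\\p{M}]+|[\\p{P}\\p{S}]+", x, perl = TRUE)[[1]]
  if (mm[1] == -1L) return(character(0))
  substring(x, mm, mm + attr(mm, "match.length") - 1L)
}

tokenize_many <- function(texts) lapply(texts, tokenize)

#' Build a keyphrase lexicon
#'
#' A lexicon maps lower-cased phrases (one or more tokens) to the aspect
#' category \code{"symptom"} or \code{"treatment"}. Phrases are stored
#' tokenized with [tokenize()] so that matching against tokenized documents
#' is exact. If the same phrase is supplied with two categories the first
#' occurrence wins and a warning is issued.
#'
#' @param phrases character vector of phrases.
#' @param categories character vector, each \code{"symptom"} or
#'   \code{"treatment"}.
#' @return an object of class \code{keyphrase_lexicon}.
#' @examples
#' lex <- keyphrase_lexicon(c("red eye", "eye drops"),
#'                          c("symptom", "treatment"))
#' label_aspects(c("red", "eye"), lex)
#' @export
keyphrase_lexicon <- function(phrases, categories) {
  stopifnot(length(phrases) == length(categories))
  if (!all(categories %in% c("symptom", "treatment")))
    stop("categories must be 'symptom' or 'treatment'")
  toks <- lapply(phrases, tokenize)
  keep <- lengths(toks) > 0L
  toks <- toks[keep]
  categories <- categories[keep]
  key <- vapply(toks, paste, "", collapse = " ")
  dup <- duplicated(key)
  if (any(dup)) {
    conflict <- key[dup][categories[dup] !=
                           categories[match(key[dup], key)]]
    if (length(conflict))
      warning("lexicon conflicts resolved by first occurrence: ",
              paste(unique(conflict), collapse = ", "))
    toks <- toks[!dup]
    categories <- categories[!dup]
    key <- key[!dup]
  }
  first <- vapply(toks, `[`, "", 1L)
  ord <- order(first, -lengths(toks))  # longest phrase first within prefix
  structure(list(tokens = toks[ord],
                 category = match(categories[ord], ASPECTS),
                 first = first[ord]),
            class = "keyphrase_lexicon")
}

#' Read a keyphrase lexicon from a TSV file
#'
#' Expects two tab-separated columns, phrase and category (\code{symptom} or
#' \code{treatment}); lines starting with \code{#} are comments.
#'
#' @param path file path.
#' @return a \code{keyphrase_lexicon}.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(keyphrase_lexicon(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad))
    warning(sum(bad), " malformed lexicon line(s) skipped")
  parts <- parts[!bad]
  keyphrase_lexicon(vapply(parts, `[`, "", 1L),
                    tolower(vapply(parts, `[`, "", 2L)))
}

#' @export
print.keyphrase_lexicon <- function(x, ...) {
  cat("Keyphrase lexicon:", length(x$tokens), "phrases (",
      sum(x$category == 2L), "symptom,", sum(x$category == 3L),
      "treatment )\n")
  invisible(x)
}

#' Label tokens with aspects by keyphrase matching
#'
#' Scans the token sequence left to right; at each position the longest
#' lexicon phrase starting there is matched greedily, and every token inside
#' a matched phrase receives that phrase's category. Tokens consumed by a
#' match are not re-matched; everything else is \code{general}.
#'
#' @param tokens character vector of tokens from [tokenize()].
#' @param lexicon a \code{keyphrase_lexicon} (or \code{NULL} for all-general).
#' @return integer vector of the same length: 1 = general, 2 = symptom,
#'   3 = treatment.
#' @export
label_aspects <- function(tokens, lexicon = NULL) {
  n <- length(tokens)
  out <- rep.int(1L, n)
  if (is.null(lexicon) || n == 0L || !length(lexicon$tokens)) return(out)
  i <- 1L
  while (i <= n) {
    cand <- which(lexicon$first == tokens[i])
    adv <- 1L
    for (ci in cand) {  # candidates sorted longest-first
      ph <- lexicon$tokens[[ci]]
      L <- length(ph)
      if (i + L - 1L <= n && identical(tokens[i:(i + L - 1L)], ph)) {
        out[i:(i + L - 1L)] <- lexicon$category[ci]
        adv <- L
        break
      }
    }
    i <- i + adv
  }
  out
}

has_url <- function(text) {
  words <- strsplit(tolower(text), "[[:space:]]+")[[1]]
  any(grepl("^(https?://|www\\.)", words))
}

#' Assemble a corpus from raw texts
#'
#' Tokenizes, aspect-labels and indexes a set of documents against a shared
#' vocabulary. The vocabulary is built in order of first appearance; words
#' whose document frequency is below \code{min_df} are pruned (their tokens
#' are dropped).
#'
#' @param texts character vector of raw document texts.
#' @param ids optional document identifiers (default \code{doc1, doc2, ...}).
#' @param timestamps optional \code{Date} vector (or \code{NA}).
#' @param regions optional character vector of region codes (or \code{NA}).
#' @param lexicon optional \code{keyphrase_lexicon} for aspect labels.
#' @param min_df minimum document frequency for vocabulary entries.
#' @return an object of class \code{atam_corpus}: a list with elements
#'   \code{vocab} (character), \code{word} (list of integer vectors indexing
#'   \code{vocab}), \code{aspect} (list of integer vectors), and the metadata
#'   data frame \code{meta} with columns \code{doc_id}, \code{timestamp},
#'   \code{region}.
#' @export
corpus_from_texts <- function(texts, ids = NULL, timestamps = NULL,
                              regions = NULL, lexicon = NULL, min_df = 1L) {
  n <- length(texts)
  if (is.null(ids))
    ids <- if (n) paste0("doc", seq_len(n)) else character(0)
  if (is.null(timestamps)) timestamps <- as.Date(rep(NA, n))
  if (is.null(regions)) regions <- rep(NA_character_, n)
  toks <- tokenize_many(texts)
  asps <- lapply(toks, label_aspects, lexicon = lexicon)
  vocab <- unique(unlist(toks, use.names = FALSE))
  if (is.null(vocab)) vocab <- character(0)
  if (min_df > 1L && length(vocab)) {
    df <- table(factor(unlist(lapply(toks, unique), use.names = FALSE),
                       levels = vocab))
    keep <- vocab[df >= min_df]
    sel <- lapply(toks, function(tk) tk %in% keep)
    toks <- mapply(function(tk, s) tk[s], toks, sel, SIMPLIFY = FALSE)
    asps <- mapply(function(as_, s) as_[s], asps, sel, SIMPLIFY = FALSE)
    vocab <- keep
  }
  word <- lapply(toks, function(tk) match(tk, vocab))
  structure(list(vocab = vocab,
                 word = word,
                 aspect = asps,
                 surface = toks,
                 meta = data.frame(doc_id = as.character(ids),
                                   timestamp = as.Date(timestamps),
                                   region = as.character(regions),
                                   stringsAsFactors = FALSE)),
            class = "atam_corpus")
}

#' Read a corpus of JSON-lines records
#'
#' Each line is a JSON object with fields \code{id}, \code{text} and optional
#' \code{timestamp} (\code{"YYYY-MM-DD"}) and \code{region}. Malformed lines
#' are reported with their line number and skipped. Records containing a URL
#' (a whitespace-delimited token starting \code{http://}, \code{https://} or
#' \code{www.}) are dropped when \code{drop_urls} is \code{TRUE}, which is
#' the recommended setting for social-media feeds where URL-bearing messages
#' are almost always advertisements or news.
#'
#' @param path file of JSON-lines records.
#' @param lexicon optional \code{keyphrase_lexicon}.
#' @param drop_urls drop URL-bearing records (default \code{TRUE}).
#' @param min_df vocabulary pruning threshold, see [corpus_from_texts()].
#' @return an \code{atam_corpus}.
#' @export
read_corpus <- function(path, lexicon = NULL, drop_urls = TRUE, min_df = 1L) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  skipped <- 0L
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(rec) || is.null(rec$text)) {
      warning("skipping malformed record at line ", i)
      skipped <- skipped + 1L
      next
    }
    recs[[i]] <- rec
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (skipped > 0L) message(skipped, " malformed record(s) skipped")
  if (drop_urls && length(recs)) {
    url <- vapply(recs, function(r) has_url(r$text), TRUE)
    if (any(url)) message(sum(url), " URL-bearing record(s) dropped")
    recs <- recs[!url]
  }
  texts <- vapply(recs, function(r) as.character(r$text), "")
  ids <- vapply(recs, function(r)
    if (!is.null(r$id)) as.character(r$id) else NA_character_, "")
  ids[is.na(ids)] <- paste0("doc", which(is.na(ids)))
  ts <- as.Date(vapply(recs, function(r)
    if (!is.null(r$timestamp)) as.character(r$timestamp) else NA_character_, ""))
  rg <- vapply(recs, function(r)
    if (!is.null(r$region)) as.character(r$region) else NA_character_, "")
  corpus_from_texts(texts, ids, ts, rg, lexicon = lexicon, min_df = min_df)
}

#' Write a tokenized corpus cache
#'
#' Serializes an \code{atam_corpus} as JSON-lines: a header record carrying
#' the vocabulary, then one record per document with word ids, aspect codes,
#' surfaces and metadata. [read_corpus_cache()] restores it token-for-token.
#'
#' @param corpus an \code{atam_corpus}.
#' @param path output file.
#' @export
write_corpus_cache <- function(corpus, path) {
  stopifnot(inherits(corpus, "atam_corpus"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  header <- jsonlite::toJSON(list(format = "atam-corpus-cache", version = 1L,
                                  vocab = corpus$vocab), auto_unbox = TRUE)
  writeLines(header, con)
  for (d in seq_len(n_docs(corpus))) {
    rec <- list(id = corpus$meta$doc_id[d],
                w = corpus$word[[d]], y = corpus$aspect[[d]],
                s = corpus$surface[[d]])
    if (!is.na(corpus$meta$timestamp[d]))
      rec$timestamp <- format(corpus$meta$timestamp[d])
    if (!is.na(corpus$meta$region[d])) rec$region <- corpus$meta$region[d]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read a tokenized corpus cache written by [write_corpus_cache()]
#'
#' @param path cache file.
#' @return an \code{atam_corpus}.
#' @export
read_corpus_cache <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  stopifnot(length(lines) >= 1L)
  header <- jsonlite::fromJSON(lines[1])
  stopifnot(identical(header$format, "atam-corpus-cache"))
  vocab <- as.character(header$vocab)
  body <- lapply(lines[-1], jsonlite::fromJSON)
  grab <- function(r, f, default) if (!is.null(r[[f]])) r[[f]] else default
  structure(list(
    vocab = vocab,
    word = lapply(body, function(r) as.integer(grab(r, "w", integer(0)))),
    aspect = lapply(body, function(r) as.integer(grab(r, "y", integer(0)))),
    surface = lapply(body, function(r) as.character(grab(r, "s", character(0)))),
    meta = data.frame(
      doc_id = vapply(body, function(r) as.character(grab(r, "id", NA)), ""),
      timestamp = as.Date(vapply(body, function(r)
        as.character(grab(r, "timestamp", NA)), "")),
      region = vapply(body, function(r)
        as.character(grab(r, "region", NA)), ""),
      stringsAsFactors = FALSE)),
    class = "atam_corpus")
}

n_docs <- function(corpus) length(corpus$word)

n_vocab <- function(corpus) length(corpus$vocab)

# Flat 0-based representation handed to the compiled sampler.
flatten_corpus <- function(corpus) {
  nd <- lengths(corpus$word)
  list(doc_ptr = as.integer(c(0L, cumsum(nd))),
       word = as.integer(unlist(corpus$word, use.names = FALSE)) - 1L,
       aspect = as.integer(unlist(corpus$aspect, use.names = FALSE)) - 1L)
}

# Order-insensitive rolling hash of the vocabulary, for checkpoint sanity.
vocab_hash <- function(vocab) {
  h <- 0
  mod <- 2147483647
  for (w in vocab) {
    g <- 17
    for (ci in utf8ToInt(w)) g <- (g * 31 + ci) %% mod
    h <- (h * 131 + g) %% mod
  }
  h
}

#' @export
print.atam_corpus <- function(x, ...) {
  nt <- sum(lengths(x$word))
  cat("Corpus:", n_docs(x), "documents,", nt, "tokens, vocabulary of",
      n_vocab(x), "types\n")
  asp <- table(factor(unlist(x$aspect, use.names = FALSE), levels = 1:3,
                      labels = ASPECTS))
  cat("Aspect labels:", paste(names(asp), asp, sep = "=", collapse = ", "),
      "\n")
  n_ts <- sum(!is.na(x$meta$timestamp))
  n_rg <- sum(!is.na(x$meta$region))
  if (n_ts || n_rg)
    cat("Metadata:", n_ts, "timestamped,", n_rg, "with region\n")
  invisible(x)
}

#' Map a corpus onto an existing vocabulary
#'
#' Used when scoring new documents under a fitted model: tokens whose word is
#' absent from the model vocabulary are dropped with a warning.
#'
#' @param corpus an \code{atam_corpus}.
#' @param vocab character vector, the model vocabulary.
#' @return an \code{atam_corpus} indexed against \code{vocab}.
#' @export
align_corpus <- function(corpus, vocab) {
  stopifnot(inherits(corpus, "atam_corpus"))
  unseen <- 0L
  word <- corpus$word
  aspect <- corpus$aspect
  surface <- corpus$surface
  for (d in seq_along(word)) {
    ids <- match(surface[[d]], vocab)
    drop <- is.na(ids)
    unseen <- unseen + sum(drop)
    word[[d]] <- ids[!drop]
    aspect[[d]] <- aspect[[d]][!drop]
    surface[[d]] <- surface[[d]][!drop]
  }
  if (unseen > 0L)
    warning(unseen, " token(s) outside the model vocabulary skipped")
  structure(list(vocab = vocab, word = word, aspect = aspect,
                 surface = surface, meta = corpus$meta),
            class = "atam_corpus")
}
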