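# Temporal and geographic prevalence series from model assignments, keyword
# baselines, standardization, and correlation with external series.

# Epidemiological weeks start on Sunday; a date's bin is the Sunday on or
# before it, formatted ISO.
date_bin <- function(dates, by) {
  if (by == "week") {
    wd <- as.POSIXlt(dates)$wday
    format(dates - wd)
  } else {
    format(dates, "%Y-%m")
  }
}

make_trend_series <- function(bin, hit) {
  keep <- !is.na(bin)
  bin <- bin[keep]
  hit <- hit[keep]
  if (!length(bin))
    return(structure(data.frame(bin = character(0), rate = numeric(0),
                                n = integer(0)), class = c("trend_series",
                                                           "data.frame")))
  n <- tapply(hit, bin, length)
  num <- tapply(hit, bin, sum)
  structure(data.frame(bin = names(n), rate = as.numeric(num / n),
                       n = as.integer(n), row.names = NULL),
            class = c("trend_series", "data.frame"))
}

#' Ailment prevalence series over time or regions
#'
#' The rate per bin is the fraction of that bin's documents assigned to the
#' ailment — an estimate of P(ailment | time period) or
#' P(ailment | region). Documents without the needed metadata are excluded
#' from numerator and denominator; empty bins are omitted.
#'
#' @param corpus the \code{atam_corpus} the assignments refer to.
#' @param assignments integer vector of per-document ailment (or topic)
#'   assignments, e.g. \code{fit$a}; \code{NA} entries are excluded.
#' @param ailment the ailment index whose rate is computed.
#' @param by \code{"week"}, \code{"month"} (timestamp bins) or
#'   \code{"region"}.
#' @return a \code{trend_series} data frame with columns \code{bin},
#'   \code{rate}, \code{n}.
#' @export
ailment_rate <- function(corpus, assignments, ailment,
                         by = c("week", "month", "region")) {
  by <- match.arg(by)
  stopifnot(inherits(corpus, "atam_corpus"),
            length(assignments) == n_docs(corpus))
  bin <- if (by == "region") corpus$meta$region
  else date_bin(corpus$meta$timestamp, by)
  bin[is.na(assignments)] <- NA
  excl <- sum(is.na(bin) & !is.na(assignments))
  if (excl > 0)
    message(excl, " document(s) without ", by, " metadata excluded")
  make_trend_series(bin, !is.na(assignments) & assignments == ailment)
}

#' Keyword prevalence series
#'
#' The fraction of documents per bin containing the keyword (presence, not
#' multiplicity). The keyword is tokenized with the corpus tokenizer; a
#' multi-token phrase counts when it occurs as a contiguous token
#' subsequence.
#'
#' @param corpus an \code{atam_corpus}.
#' @param keyword character string.
#' @param by \code{"week"}, \code{"month"} or \code{"region"}.
#' @return a \code{trend_series}.
#' @export
keyword_rate <- function(corpus, keyword, by = c("week", "month", "region")) {
  by <- match.arg(by)
  stopifnot(inherits(corpus, "atam_corpus"))
  kt <- tokenize(keyword)
  if (!length(kt)) stop("keyword tokenizes to nothing")
  contains <- vapply(corpus$surface, function(tk) {
    if (length(kt) == 1L) kt %in% tk
    else {
      n <- length(tk) - length(kt) + 1L
      n >= 1L && any(vapply(seq_len(n), function(i)
        identical(tk[i:(i + length(kt) - 1L)], kt), TRUE))
    }
  }, TRUE)
  bin <- if (by == "region") corpus$meta$region
  else date_bin(corpus$meta$timestamp, by)
  make_trend_series(bin, contains)
}

#' Hard topic assignment for an LDA-with-background fit
#'
#' Each document is assigned the topic with the largest number of
#' non-background tokens; ties break to the lowest topic index, and
#' documents whose tokens are all background are unassigned (\code{NA}).
#'
#' @param object a fitted \code{lda_bg}.
#' @return integer vector of topic indices (\code{NA} = unassigned).
#' @export
assign_topic_lda <- function(object) {
  stopifnot(inherits(object, "lda_bg"))
  cnt <- object$stats$n_doc_topic
  idx <- max.col(cnt, ties.method = "first")
  idx[object$stats$n_doc_top == 0L] <- NA_integer_
  idx
}

align_series <- function(a, b) {
  if (inherits(a, "trend_series") || is.data.frame(a)) {
    common <- intersect(a$bin, b$bin)
    dropped <- length(setdiff(union(a$bin, b$bin), common))
    if (dropped > 0)
      message(dropped, " bin(s) present in only one series dropped")
    list(x = a$rate[match(common, a$bin)], y = b$rate[match(common, b$bin)])
  } else {
    stopifnot(length(a) == length(b))
    list(x = as.numeric(a), y = as.numeric(b))
  }
}

#' Pearson correlation between two aligned series
#'
#' Series may be \code{trend_series} objects (aligned on common bins, with
#' bins present in only one series dropped) or plain numeric vectors of
#' equal length.
#'
#' @param a,b the two series.
#' @return the sample Pearson correlation coefficient.
#' @export
pearson_r <- function(a, b) {
  s <- align_series(a, b)
  if (length(s$x) < 3L) stop("need at least 3 common bins")
  if (sd(s$x) == 0 || sd(s$y) == 0)
    stop("zero variance in one of the series")
  cor(s$x, s$y)
}

#' Standardize a series to z-scores
#'
#' Centres to mean 0 and scales to sample standard deviation 1, so series
#' on different scales are comparable on one axis.
#'
#' @param x numeric vector or \code{trend_series} (the rates are
#'   standardized).
#' @return the standardized object, same shape as the input.
#' @export
zscore <- function(x) {
  if (inherits(x, "trend_series") || is.data.frame(x)) {
    x$rate <- zscore(x$rate)
    return(x)
  }
  if (length(x) < 2L) stop("need at least 2 values")
  s <- sd(x)
  if (s == 0) stop("zero variance")
  (x - mean(x)) / s
}

#' Read an external series from CSV
#'
#' Two columns, \code{bin} (ISO date, \code{YYYY-MM} month or region code)
#' and \code{value}.
#'
#' @param path CSV file.
#' @return a \code{trend_series} (with \code{n = NA}).
#' @export
read_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("bin", "value") %in% names(df)))
  structure(data.frame(bin = as.character(df$bin), rate = df$value,
                       n = NA_integer_),
            class = c("trend_series", "data.frame"))
}

#' Write a trend series as CSV
#'
#' @param series a \code{trend_series}.
#' @param path output file.
#' @export
write_series <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Compare two dependent correlations (approximate)
#'
#' Steiger's z-test for the difference between two correlations that share
#' a variable (e.g. two model series both correlated against the same
#' surveillance series over the same bins). The normalizing approximation
#' is standard but approximate for short series.
#'
#' @param r12 correlation of the shared series with series 1.
#' @param r13 correlation of the shared series with series 2.
#' @param r23 correlation between series 1 and series 2.
#' @param n number of common bins.
#' @return list with \code{z} and two-sided \code{p}.
#' @export
compare_correlations <- function(r12, r13, r23, n) {
  stopifnot(n > 3)
  z12 <- atanh(r12)
  z13 <- atanh(r13)
  rbar2 <- ((r12 + r13) / 2)^2
  psi <- r23 * (1 - 2 * rbar2) - 0.5 * rbar2 * (1 - 2 * rbar2 - r23^2)
  s <- psi / (1 - rbar2)^2
  z <- (z12 - z13) * sqrt((n - 3) / (2 * (1 - s)))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' @export
print.trend_series <- function(x, ...) {
  cat("Trend series:", nrow(x), "bins\n")
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' @export
plot.trend_series <- function(x, ..., standardize = FALSE) {
  y <- if (standardize) zscore(x$rate) else x$rate
  plot(seq_len(nrow(x)), y, type = "l", xaxt = "n", xlab = "bin",
       ylab = if (standardize) "rate (z-score)" else "rate", ...)
  at <- unique(round(seq(1, nrow(x), length.out = min(8, nrow(x)))))
  graphics::axis(1, at = at, labels = x$bin[at], las = 2, cex.axis = 0.7)
  invisible(x)
}
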