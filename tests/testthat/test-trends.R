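# Rate series, keyword baselines, correlation and standardization.

test_that("ailment rates are per-bin fractions of assigned documents", {
  cp <- manual_corpus(rep(list(1L), 10), rep(list(1L), 10), W = 2,
                      timestamps = rep("2012-01-04", 10))  # one Wednesday
  assign <- c(rep(2L, 4), rep(1L, 6))
  ser <- ailment_rate(cp, assign, ailment = 2, by = "week")
  expect_equal(nrow(ser), 1L)
  expect_equal(ser$rate, 0.4)
  expect_equal(ser$n, 10L)
  expect_equal(ser$bin, "2012-01-01")  # the Sunday on or before
  # documents without metadata are excluded entirely
  expect_message(
    ser0 <- ailment_rate(manual_corpus(list(1L), list(1L), W = 2),
                         1L, ailment = 1, by = "week"),
    "excluded")
  expect_equal(nrow(ser0), 0L)
  # monthly binning keys on YYYY-MM
  cp2 <- manual_corpus(rep(list(1L), 4), rep(list(1L), 4), W = 2,
                       timestamps = c("2012-01-04", "2012-01-20",
                                      "2012-02-01", "2012-02-27"))
  ser2 <- ailment_rate(cp2, c(1L, 2L, 1L, 1L), ailment = 1, by = "month")
  expect_equal(ser2$bin, c("2012-01", "2012-02"))
  expect_equal(ser2$rate, c(0.5, 1))
})

test_that("rates over all ailments sum to one in every bin", {
  set.seed(81)
  days <- as.Date("2012-01-01") + sample.int(60, 40, replace = TRUE)
  cp <- manual_corpus(rep(list(1L), 40), rep(list(1L), 40), W = 2,
                      timestamps = days)
  assign <- sample.int(3L, 40, replace = TRUE)
  total <- Reduce(`+`, lapply(1:3, function(i)
    ailment_rate(cp, assign, i, by = "week")$rate))
  expect_equal(total, rep(1, length(total)))
})

test_that("keyword rates count document presence and agree with assignment-based rates", {
  texts <- c("got the flu today", "flu flu flu", "feeling fine",
             "just tired", "all good")
  cp <- corpus_from_texts(texts, timestamps = rep(as.Date("2012-03-05"), 5))
  ser <- keyword_rate(cp, "flu", by = "week")
  expect_equal(ser$rate, 0.4)  # presence, not multiplicity
  # absent keyword: all-zero rates over the same bins
  ser0 <- keyword_rate(cp, "measles", by = "week")
  expect_equal(ser0$rate, 0)
  # keyword_rate == ailment_rate when assignment is defined as
  # "contains the keyword"
  set.seed(82)
  days <- as.Date("2012-01-01") + sample.int(40, 30, replace = TRUE)
  texts2 <- replicate(30, paste(sample(c("flu", "cold", "tv", "rest"),
                                       5, replace = TRUE), collapse = " "))
  cp2 <- corpus_from_texts(texts2, timestamps = days)
  contains <- vapply(cp2$surface, function(s) "flu" %in% s, TRUE)
  s1 <- keyword_rate(cp2, "flu", by = "week")
  s2 <- ailment_rate(cp2, ifelse(contains, 1L, 2L), ailment = 1,
                     by = "week")
  expect_equal(s1$rate, s2$rate)
  expect_equal(s1$bin, s2$bin)
  # multi-token phrases match as contiguous subsequences
  cp3 <- corpus_from_texts(c("bad eye drops here", "drops eye bad"),
                           timestamps = rep(as.Date("2012-03-05"), 2))
  expect_equal(keyword_rate(cp3, "eye drops", by = "week")$rate, 0.5)
})

test_that("LDA topic assignment uses non-background counts with declared tie rules", {
  cp <- manual_corpus(list(c(1L, 2L, 3L, 1L, 2L), c(1L, 2L), c(1L, 2L)),
                      list(rep(1L, 5), rep(1L, 2), rep(1L, 2)), W = 3)
  obj <- lda_init(cp, atam_control(Z = 3, iterations = 0), seed = 83)
  # doc 1: counts (0, 3, 2) -> topic 2; doc 2: all background -> NA;
  # doc 3: tie (1, 1, 0) -> lowest index
  obj <- set_state(obj, tstate = c(3L, 3L, 4L, 3L, 4L, 1L, 1L, 2L, 3L))
  expect_identical(assign_topic_lda(obj), c(2L, NA, 1L))
})

test_that("pearson correlation matches the textbook formula and its invariances", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, c(6, 4, 2)), -1)
  set.seed(84)
  for (r in 1:200) {
    a <- rnorm(sample(3:40, 1))
    b <- rnorm(length(a))
    expect_lt(abs(pearson_r(a, b) - oracle_pearson(a, b)), 1e-12)
    expect_lt(abs(pearson_r(2.5 * a + 1, b) - pearson_r(a, b)), 1e-12)
  }
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(c(1, 2), c(3, 4)), "at least 3")
})

test_that("series align on common bins before correlating", {
  a <- structure(data.frame(bin = c("b1", "b2", "b3", "b4"),
                            rate = c(1, 2, 3, 4), n = 1L),
                 class = c("trend_series", "data.frame"))
  b <- structure(data.frame(bin = c("b2", "b3", "b4", "b5"),
                            rate = c(5, 7, 9, 2), n = 1L),
                 class = c("trend_series", "data.frame"))
  expect_message(r <- pearson_r(a, b), "dropped")
  expect_equal(r, 1)
})

test_that("z-scoring standardizes to mean zero and unit sample deviation", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(85)
  for (r in 1:50) {
    x <- rnorm(sample(2:30, 1), sd = runif(1, 0.1, 5))
    z <- zscore(x)
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sd(z) - 1), 1e-12)
    expect_equal(zscore(z), z, tolerance = 1e-12)
  }
  expect_error(zscore(rep(2, 5)), "zero variance")
})

test_that("external series round-trip through CSV", {
  ser <- structure(data.frame(bin = c("2012-01-01", "2012-01-08"),
                              rate = c(0.1, 0.3), n = c(10L, 12L)),
                   class = c("trend_series", "data.frame"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_series(ser, f)
  back <- read_series(sub("rate", "value",
                          {writeLines(gsub("rate", "value", readLines(f)), f); f}))
  expect_equal(back$bin, ser$bin)
  expect_equal(back$rate, ser$rate)
})

test_that("dependent-correlation comparison produces sane statistics", {
  out <- compare_correlations(0.8, 0.5, 0.6, n = 50)
  expect_true(is.finite(out$z))
  expect_gt(out$z, 0)
  expect_true(out$p > 0 && out$p < 1)
})
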