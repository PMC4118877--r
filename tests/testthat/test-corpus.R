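test_that("tokenizer lower-cases and splits punctuation runs into tokens", {
  expect_identical(
    tokenize("damn flu, home with a fever watching TV."),
    c("damn", "flu", ",", "home", "with", "a", "fever", "watching", "tv", "."))
  expect_identical(tokenize(""), character(0))
  expect_identical(tokenize("don't!!"), c("don", "'", "t", "!!"))
  expect_identical(tokenize("!!!"), "!!!")
  expect_identical(tokenize("  \t \n "), character(0))
  # unicode punctuation and symbols separate words
  expect_identical(tokenize("gripe—fiebre"), c("gripe", "—", "fiebre"))
})

test_that("keyphrase matching labels whole phrases with their category", {
  lex <- keyphrase_lexicon(c("red eye", "eye drops"),
                           c("symptom", "treatment"))
  expect_identical(label_aspects(c("red", "eye"), lex), c(2L, 2L))
  expect_identical(label_aspects(c("eye", "drops"), lex), c(3L, 3L))
  expect_identical(label_aspects(c("watching", "tv"), lex), c(1L, 1L))
  # greedy longest match left to right; consumed tokens are not re-matched
  lex2 <- keyphrase_lexicon(c("sore", "sore throat"),
                            c("treatment", "symptom"))
  expect_identical(label_aspects(c("sore", "throat"), lex2), c(2L, 2L))
  expect_identical(label_aspects(c("throat", "sore"), lex2), c(1L, 3L))
  # a token consumed by a match does not start a new match
  lex3 <- keyphrase_lexicon(c("red eye", "eye drops"),
                            c("symptom", "treatment"))
  expect_identical(label_aspects(c("red", "eye", "drops"), lex3),
                   c(2L, 2L, 1L))
})

test_that("aspect labeling is deterministic, idempotent in effect, and conserves length", {
  set.seed(1)
  lex <- keyphrase_lexicon(c("red eye", "flu", "eye drops", "nasal spray"),
                           c("symptom", "symptom", "treatment", "treatment"))
  vocabulary <- c("red", "eye", "drops", "flu", "nasal", "spray", "tv", ".")
  for (r in 1:25) {
    toks <- sample(vocabulary, sample.int(12, 1), replace = TRUE)
    l1 <- label_aspects(toks, lex)
    expect_length(l1, length(toks))
    expect_identical(l1, label_aspects(toks, lex))
    expect_true(all(l1 %in% 1:3))
  }
})

test_that("lexicon conflicts resolve to the first occurrence with a warning", {
  expect_warning(lex <- keyphrase_lexicon(c("red eye", "red eye"),
                                          c("symptom", "treatment")),
                 "first occurrence")
  expect_identical(label_aspects(c("red", "eye"), lex), c(2L, 2L))
})

test_that("corpus loading drops URL records and reports malformed lines", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"id":"a","text":"damn flu, home with a fever","timestamp":"2012-01-03"}',
    '{"id":"b","text":"check this http://x.co now"}',
    'this is not json',
    '{"id":"c","text":"!!!"}'), f)
  expect_warning(cp <- read_corpus(f, drop_urls = TRUE), "line 3")
  expect_equal(n_docs(cp), 2L)
  expect_identical(cp$surface[[2]], "!!!")
  expect_identical(cp$aspect[[2]], 1L)
  expect_identical(cp$meta$timestamp[1], as.Date("2012-01-03"))
  # URL record retained when filtering is off
  expect_warning(cp2 <- read_corpus(f, drop_urls = FALSE), "line 3")
  expect_equal(n_docs(cp2), 3L)
})

test_that("an empty input yields an empty corpus with an empty vocabulary", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), f)
  cp <- read_corpus(f)
  expect_equal(n_docs(cp), 0L)
  expect_length(cp$vocab, 0L)
})

test_that("tokenized corpus cache round-trips token-for-token", {
  lex <- keyphrase_lexicon(c("red eye", "flu"), c("symptom", "symptom"))
  cp <- corpus_from_texts(
    c("I have a red eye, the flu maybe?", "watching tv at home."),
    timestamps = as.Date(c("2012-02-01", NA)),
    regions = c(NA, "MD"), lexicon = lex)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_cache(cp, f)
  cp2 <- read_corpus_cache(f)
  expect_identical(cp2$vocab, cp$vocab)
  expect_identical(cp2$word, cp$word)
  expect_identical(cp2$aspect, cp$aspect)
  expect_identical(cp2$surface, cp$surface)
  expect_identical(cp2$meta$timestamp, cp$meta$timestamp)
  expect_identical(cp2$meta$region, cp$meta$region)
  # serialize(load(x)) == load(x)
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_cache(cp2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("vocabulary pruning and alignment handle unseen words explicitly", {
  cp <- corpus_from_texts(c("apple banana apple", "banana apple cherry"),
                          min_df = 2L)
  expect_identical(cp$vocab, c("apple", "banana"))
  expect_identical(cp$surface[[2]], c("banana", "apple"))
  cp_new <- corpus_from_texts("banana durian")
  expect_warning(al <- align_corpus(cp_new, cp$vocab), "skipped")
  expect_identical(al$surface[[1]], "banana")
  expect_identical(al$word[[1]], match("banana", cp$vocab))
})

test_that("the bundled example corpus and lexicon load end to end", {
  lex <- read_lexicon(system.file("extdata", "example_lexicon.tsv",
                                  package = "atam"))
  cp <- read_corpus(system.file("extdata", "example_corpus.jsonl",
                                package = "atam"), lexicon = lex)
  expect_equal(n_docs(cp), 9L)  # the URL-bearing record is dropped
  expect_identical(cp$aspect[[1]][7], 2L)  # "fever" is a symptom token
  expect_true(all(!is.na(cp$meta$timestamp)))
  ser <- keyword_rate(cp, "flu", by = "month")
  expect_equal(ser$rate[ser$bin == "2012-01"], 2 / 3)
})

test_that("lexicon TSV reader parses phrases, comments and categories", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "red eye\tsymptom", "eye drops\ttreatment",
               "Flu\tsymptom"), f)
  lex <- read_lexicon(f)
  expect_identical(label_aspects(c("flu"), lex), 2L)
  expect_identical(label_aspects(c("eye", "drops"), lex), c(3L, 3L))
})
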