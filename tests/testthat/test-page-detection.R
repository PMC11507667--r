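mk_line <- function(text, y0 = 10, y1 = 16) {
  structure(list(chars = NULL, text = text,
                 x_range = interval(0, 100), y_range = interval(y0, y1)),
            class = "text_line")
}

test_that("line features carry context, graphics flags and page number", {
  gfx <- page_graphics(hlines = data.frame(xmin = 0, ymin = 18, xmax = 100,
                                           ymax = 18))
  f1 <- featurize_line(mk_line("First line"), list(), page_graphics(), 1)
  expect_equal(f1$prev_tokens, character(0))
  expect_false(f1$has_hline)
  expect_equal(f1$page_number, 1L)
  # a rule drawn just under the line sets the indicator
  f2 <- featurize_line(mk_line("Ruled row", 10, 16), list(), gfx, 2)
  expect_true(f2$has_hline)
  expect_false(f2$has_vline)
  # identical lines on different pages differ only in page_number
  f7 <- featurize_line(mk_line("Ruled row", 10, 16), list(), gfx, 7)
  expect_equal(f2[setdiff(names(f2), "page_number")],
               f7[setdiff(names(f7), "page_number")])
  expect_equal(f7$page_number, 7L)
  # previous-line window
  f3 <- featurize_line(mk_line("current"), list(mk_line("Cat# 12")), gfx, 1)
  expect_equal(f3$prev_tokens, c("cat", "12"))
})

test_that("tokenization lowercases and splits on punctuation", {
  expect_equal(tokenize_text("RRID:AB_123, (mouse)")[[1]],
               c("rrid", "ab", "123", "mouse"))
  expect_equal(tokenize_text("")[[1]], character(0))
})

test_that("classifier trainers reject single-class corpora", {
  all_neg <- list(list(data.frame(text = c("a b", "c d"), has_hline = FALSE,
                                  has_vline = FALSE, in_table = FALSE)))
  expect_error(train_line_classifier(all_neg), "both")
  expect_error(train_line_classifier(list()), "empty")
  expect_error(train_page_classifier(list(c("a"), c("b")), c(1, 1)),
               "both classes")
})

test_that("LSTM gradients agree with finite differences", {
  P <- restable:::lstm_init(6, 5, 7, 3, seed = 5)
  ids <- list(c(1L, 4L, 0L, 2L), 3L, c(5L, 6L))
  set.seed(7)
  aux <- matrix(rnorm(9), 3, 3)
  y <- c(1, 0, 1); w <- c(50, 1, 50)
  G <- restable:::lstm_loss_and_grads(P, ids, aux, y, w)$grads
  fn <- function(P) restable:::lstm_loss_and_grads(P, ids, aux, y, w)$loss
  eps <- 1e-5
  for (nm in names(P)) {
    for (k in sample(length(P[[nm]]), min(4, length(P[[nm]])))) {
      Pp <- P; Pp[[nm]][k] <- Pp[[nm]][k] + eps
      Pm <- P; Pm[[nm]][k] <- Pm[[nm]][k] - eps
      expect_equal(G[[nm]][k], (fn(Pp) - fn(Pm)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("a linearly separable page corpus is fit perfectly by the SVM", {
  set.seed(41)
  toks <- c(lapply(1:12, function(i) c("rrid", "antibody", sample(letters, 3))),
            lapply(1:12, function(i) sample(letters, 5)))
  labs <- rep(c(1, 0), each = 12)
  m <- train_page_classifier(toks, labs)
  expect_equal(as.integer(predict_pages(m, toks)), labs)
  # zero-variance token columns are tolerated
  toks2 <- lapply(toks, function(t) c(t, "constant"))
  expect_silent(train_page_classifier(toks2, labs))
})

test_that("word2vec-format embeddings load into the embedding table", {
  f <- tempfile()
  writeLines(c("rrid 1 2 3", "antibody 4 5 6", "junk 1"), f)
  emb <- matrix(0, 4, 3)
  out <- restable:::load_word2vec_embeddings(f, c("rrid", "x", "antibody"),
                                             3, emb)
  expect_equal(out[2, ], c(1, 2, 3))   # row offset: id 0 is row 1
  expect_equal(out[4, ], c(4, 5, 6))
  expect_equal(out[3, ], c(0, 0, 0))
})

test_that("the stacked detector flags resource-table pages on fixtures", {
  corpus <- generate_page_corpus(1, n_docs = 10, pages_per_doc = 6)
  det <- train_page_detector(corpus, config = list(line = list(epochs = 3)),
                             seed = 2)
  test_corpus <- generate_page_corpus(99, n_docs = 4, pages_per_doc = 6)
  hits <- 0; pos <- 0; fp <- 0; neg <- 0
  for (doc in test_corpus) {
    truth <- vapply(doc, function(pg) any(pg$in_table), logical(1))
    got <- detect_candidate_pages(doc, det$line_model, det$page_model)
    pos <- pos + sum(truth); hits <- hits + sum(which(truth) %in% got)
    neg <- neg + sum(!truth); fp <- fp + sum(!(got %in% which(truth)))
  }
  expect_gt(pos, 0)
  expect_gte(hits / pos, 0.7)          # catches most table pages
  expect_lte(fp / max(1, neg), 0.3)    # without flooding false positives
  expect_equal(detect_candidate_pages(list(), det$line_model, det$page_model),
               integer(0))
})

test_that("pipeline determinism: same seed, same detector output", {
  corpus <- generate_page_corpus(5, n_docs = 6, pages_per_doc = 5)
  d1 <- train_page_detector(corpus, config = list(line = list(epochs = 2)),
                            seed = 3)
  d2 <- train_page_detector(corpus, config = list(line = list(epochs = 2)),
                            seed = 3)
  expect_identical(d1$line_model$params, d2$line_model$params)
  doc <- generate_page_corpus(77, n_docs = 1, pages_per_doc = 6)[[1]]
  expect_identical(detect_candidate_pages(doc, d1$line_model, d1$page_model),
                   detect_candidate_pages(doc, d2$line_model, d2$page_model))
})

test_that("labeled line corpora round-trip through JSON lines", {
  corpus <- generate_page_corpus(3, n_docs = 2, pages_per_doc = 2)
  f <- tempfile(fileext = ".jsonl")
  write_line_labels(corpus, f)
  back <- read_line_labels(f)
  expect_length(back, 2L)
  for (d in 1:2) for (p in 1:2) {
    expect_equal(back[[d]][[p]]$text, corpus[[d]][[p]]$text)
    expect_equal(back[[d]][[p]]$in_table, corpus[[d]][[p]]$in_table)
  }
})
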