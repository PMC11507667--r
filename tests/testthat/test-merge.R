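test_that("pair encoding joins through the end-of-cell token", {
  v <- char_vocab(c("abcdx", "yz"))
  id <- function(ch) match(ch, v$chars)
  expect_equal(encode_pair("ab", "cd", v),
               c(id("a"), id("b"), v$eos_id, id("c"), id("d")))
  expect_equal(encode_pair("", "x", v), c(v$eos_id, id("x")))
})

test_that("over-long pairs are left-truncated keeping the junction", {
  v <- char_vocab("abcdefghij")
  upper <- paste(rep("a", 300), collapse = "")
  ids <- encode_pair(upper, "bcdefghijb", v, max_seq = 64L)
  expect_length(ids, 64L)
  # junction: ... a a <EOS> b c ...
  eos_pos <- which(ids == v$eos_id)
  expect_equal(eos_pos, 64L - 10L)
  expect_equal(ids[eos_pos - 1L], match("a", v$chars))
  expect_equal(ids[eos_pos + 1L], match("b", v$chars))
})

test_that("row voting averages column probabilities with a strict threshold", {
  probs <- c(0.9, 0.2, 0.4)
  clf <- stub_classifier(local({
    i <- 0
    function(u, l) { i <<- i + 1; probs[(i - 1) %% 3 + 1] }
  }))
  dec <- score_row_pair(clf, c("a", "b", "c"), c("d", "e", "f"))
  expect_equal(dec$row_score, 0.5)
  expect_false(dec$merged)                      # strictly greater than 0.5
  high <- score_row_pair(stub_classifier(function(u, l) 1),
                         c("a", "b", "c"), c("d", "e", "f"))
  expect_equal(high$row_score, 1)
  expect_true(high$merged)
  one <- score_row_pair(stub_classifier(function(u, l) 0.51), "a", "b")
  expect_true(one$merged)
  expect_error(score_row_pair(stub_classifier(function(u, l) 1),
                              c("a", "b"), "c"), "same number of columns")
})

test_that("empty-empty pairs can be excluded from the vote", {
  clf <- stub_classifier(function(u, l) if (u == "" && l == "") 0.9 else 0.2)
  both <- score_row_pair(clf, c("", "x"), c("", "y"))
  expect_equal(both$row_score, 0.55)
  skip_empties <- score_row_pair(clf, c("", "x"), c("", "y"),
                                 skip_empty_pairs = TRUE)
  expect_equal(skip_empties$row_score, 0.2)
})

test_that("grid repair cascades merges and respects the header guard", {
  grid <- table_grid(rbind(
    c("REAGENT", "SOURCE", "ID"),
    c("anti-Sox2 antibody", "Abcam", "Cat# 12;"),
    c("raised in rabbit", "", "RRID:"),
    c("", "", "AB_99"),
    c("DAPI", "Sigma", "Cat# 7")))
  # merge exactly the continuation rows (those with empty cells)
  clf <- stub_classifier(function(u, l) {
    if (l %in% c("raised in rabbit", "RRID:", "AB_99", "")) 0.95 else 0.05
  })
  out <- merge_rows(clf, grid)
  expect_equal(out$cells, rbind(
    c("REAGENT", "SOURCE", "ID"),
    c("anti-Sox2 antibody raised in rabbit", "Abcam", "Cat# 12; RRID: AB_99"),
    c("DAPI", "Sigma", "Cat# 7")))
  expect_equal(attr(out, "n_merges"), 2L)
  # a merge-everything scorer must still leave the header alone
  all_in <- merge_rows(stub_classifier(function(u, l) 1), grid)
  expect_equal(nrow(all_in$cells), 2L)
  expect_equal(all_in$cells[1, ], c("REAGENT", "SOURCE", "ID"))
  no_guard <- merge_rows(stub_classifier(function(u, l) 1), grid,
                         protect_header = FALSE)
  expect_equal(nrow(no_guard$cells), 1L)
})

test_that("repair never alters column count or column content order", {
  set.seed(21)
  clf <- stub_classifier(function(u, l) runif(1))
  for (i in 1:10) {
    R <- sample(3:7, 1)
    cells <- matrix(sample(c("", "ab", "cd e"), R * 3, TRUE), R, 3)
    g <- table_grid(cells)
    out <- merge_rows(clf, g)
    expect_equal(ncol(out$cells), 3L)
    for (j in 1:3) {
      expect_equal(gsub(" ", "", paste(out$cells[, j], collapse = "")),
                   gsub(" ", "", paste(cells[, j], collapse = "")))
    }
  }
})

test_that("a grid scoring below threshold everywhere is unchanged", {
  g <- table_grid(rbind(c("a", "b"), c("c", "d"), c("e", "f")))
  out <- merge_rows(stub_classifier(function(u, l) 0.3), g)
  expect_equal(out$cells, g$cells)
})

test_that("fine-tuning validates labels and is seeded-deterministic", {
  lm <- train_table_lm(c("ab cd", "RRID:1", "xx yy"),
                       config = tiny_lm_config(steps = 10), seed = 6)
  bad <- data.frame(upper = c("a", "b"), lower = c("c", "d"), label = c(1, 1))
  expect_error(finetune_merge_classifier(lm, bad), "both labels")
  ds <- data.frame(upper = c("ab", "cd", "RRID:", "xx"),
                   lower = c("cd", "ab", "1", "yy"),
                   label = c(1, 0, 1, 0))
  c1 <- finetune_merge_classifier(lm, ds, config = list(epochs = 1), seed = 3)
  c2 <- finetune_merge_classifier(lm, ds, config = list(epochs = 1), seed = 3)
  expect_identical(c1$params, c2$params)
  expect_identical(predict_merge_prob(c1, ds$upper, ds$lower),
                   predict_merge_prob(c2, ds$upper, ds$lower))
})
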