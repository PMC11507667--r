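test_that("content similarity is the LCS ratio against the gold length", {
  expect_equal(cell_content_similarity("abc", "abc"), 1.0)
  expect_equal(cell_content_similarity("abc", "xyz"), 0.0)
  expect_equal(cell_content_similarity("", ""), 1.0)
  expect_equal(cell_content_similarity("", "xy"), 0.0)
  expect_equal(cell_content_similarity("ab", "xaxbxababab"), 1.0)  # capped
  # substring mode is stricter than subsequence mode
  expect_equal(cell_content_similarity("abcd", "abxcd", "substring"), 0.5)
  expect_equal(cell_content_similarity("abcd", "abxcd"), 1.0)
})

test_that("the OCR worked example matches an independent DP oracle", {
  gt <- "GCACTTCATCCTTTGGTTTTG"
  pred <- "GCACTTCATCCTTTGG G"
  expect_equal(cell_content_similarity(gt, pred),
               lcs_oracle(gt, pred) / nchar(gt))
  expect_equal(cell_content_similarity(gt, pred), 17 / 21)
})

test_that("package LCS agrees with the oracle on random strings", {
  set.seed(31)
  for (i in 1:60) {
    a <- paste(sample(letters[1:4], sample(0:12, 1), TRUE), collapse = "")
    b <- paste(sample(letters[1:4], sample(0:12, 1), TRUE), collapse = "")
    expect_equal(cell_content_similarity(a, b),
                 if (!nchar(a) && !nchar(b)) 1
                 else min(1, lcs_oracle(a, b) / max(1, nchar(a))))
  }
})

test_that("topology similarity is span-rectangle IoU", {
  expect_equal(cell_topology_similarity(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1.0)
  expect_equal(cell_topology_similarity(c(0, 1, 0, 1), c(2, 3, 2, 3)), 0.0)
  expect_equal(cell_topology_similarity(c(0, 1, 0, 2), c(0, 1, 0, 1)), 0.5)
})

test_that("identity grids score perfect GriTS in both variants", {
  g <- generate_resource_table(91, n_rows = 4)
  for (v in c("content", "topology")) {
    r <- grits(g, g, v)
    expect_equal(r$f_score, 1.0)
    expect_equal(r$precision, 1.0)
    expect_equal(r$recall, 1.0)
  }
  tiny <- grits(table_grid("x"), table_grid("y"), "content")
  expect_equal(tiny$f_score, 0)
  expect_error(grits(g, table_grid(matrix(character(0), 0, 0)), "content"),
               "non-empty")
})

test_that("F is the harmonic mean of P and R, and swapping swaps P and R", {
  set.seed(32)
  for (i in 1:25) {
    A <- random_small_grid(); B <- random_small_grid()
    for (v in c("content", "topology")) {
      r <- grits(A, B, v)
      if (r$precision + r$recall > 0) {
        expect_equal(r$f_score,
                     2 * r$precision * r$recall / (r$precision + r$recall),
                     tolerance = 1e-9)
      }
      s <- grits(B, A, v)
      expect_equal(s$f_score, r$f_score, tolerance = 1e-9)
      expect_equal(s$precision, r$recall, tolerance = 1e-9)
      expect_equal(s$recall, r$precision, tolerance = 1e-9)
    }
  }
})

test_that("emptying cells of the prediction never raises content F", {
  set.seed(33)
  for (i in 1:10) {
    A <- table_grid(matrix(replicate(9, paste(
      sample(letters[1:5], sample(1:6, 1), TRUE), collapse = "")), 3, 3))
    B <- table_grid(A$cells)
    prev <- grits(A, B, "content")$f_score
    expect_equal(prev, 1.0)
    for (k in sample(9)) {
      B$cells[k] <- ""
      cur <- grits(A, B, "content")$f_score
      expect_lte(cur, prev + 1e-12)
      prev <- cur
    }
  }
})

test_that("the factored heuristic matches exhaustive enumeration (spot check)", {
  set.seed(34)
  for (i in 1:25) {
    A <- random_small_grid(); B <- random_small_grid()
    for (v in c("content", "topology")) {
      expect_equal(grits(A, B, v)$f_score, grits_exact(A, B, v)$f_score,
                   tolerance = 1e-12)
    }
  }
})

test_that("vocabulary-overlap alignment uses the 40% threshold", {
  gold <- table_grid(rbind(c("anti-Sox2", "Abcam"), c("RRID:AB_1", "Cat#2")))
  same <- table_grid(gold$cells)
  half <- table_grid(rbind(c("anti-Sox2", "Abcam"), c("zzz", "qqq")))
  none <- table_grid(rbind(c("foo", "bar"), c("baz", "quux")))
  hit <- align_tables_by_vocab(gold, list(none, same))
  expect_equal(hit$index, 2L)
  expect_equal(hit$overlap, 1.0)
  part <- align_tables_by_vocab(gold, list(half))
  expect_equal(part$overlap, 0.5)
  expect_null(align_tables_by_vocab(gold, list(none)))
  empty <- table_grid(matrix("", 2, 2))
  expect_null(align_tables_by_vocab(empty, list(same)))
})
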