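test_that("the RRID filter is a case-sensitive prefix match", {
  yes <- table_grid(matrix(c("x", "RRID:AB_90755"), 1, 2))
  no <- table_grid(matrix(c("x", "rrid:ab_90755"), 1, 2))
  expect_length(filter_resource_tables(list(yes, no)), 1L)
  expect_equal(filter_resource_tables(list()), list())
})

test_that("overflow candidates follow the 90/100/80 width rules", {
  mk <- function(n) table_grid(matrix(paste(rep("a", n), collapse = ""), 1, 1))
  long <- select_overflow_candidates(list(mk(120)))
  expect_length(long, 1L)
  expect_equal(long[[1]]$width_budget, 90L)
  mid <- select_overflow_candidates(list(mk(95)))
  expect_equal(mid[[1]]$width_budget, 80L)
  expect_length(select_overflow_candidates(list(mk(60))), 0L)
})

test_that("column widths split the budget by mean-plus-deviation weights", {
  # two columns with constant lengths 10 and 30: weights 10 and 30
  g <- table_grid(rbind(c(strrep("a", 10), strrep("b", 30)),
                        c(strrep("c", 10), strrep("d", 30))))
  expect_equal(allocate_column_widths(g, 80), c(20L, 60L))
  eq <- table_grid(matrix(strrep("x", 5), 3, 4))
  expect_equal(allocate_column_widths(eq, 80), rep(20L, 4))
  expect_equal(sum(allocate_column_widths(g, 83)), 83L)  # leftover handed out
  expect_error(allocate_column_widths(table_grid(matrix("", 2, 2)), 80),
               "all-empty")
})

test_that("cell splitting is greedy at spaces with hard splits as fallback", {
  expect_equal(as.character(split_cell("ab cd ef", 5)), c("ab cd", "ef"))
  expect_equal(as.character(split_cell("abcdefgh", 3)), c("abc", "def", "gh"))
  expect_equal(as.character(split_cell("short", 10)), "short")
  out <- split_cell("aaaa bb", 4)
  expect_equal(attr(out, "split_kind"), "space")
})

test_that("splitting round-trips exactly and never exceeds the width", {
  set.seed(14)
  for (i in 1:400) {
    n <- sample(0:120, 1)
    s <- paste(sample(c(letters, " ", " ", "-", ":", "#"), n, TRUE),
               collapse = "")
    w <- sample(1:25, 1)
    parts <- split_cell(s, w)
    expect_identical(unsplit_cell(parts), s)
    expect_true(all(nchar(parts) <= w))
  }
})

test_that("each k-line split cell contributes exactly k-1 positive pairs", {
  g <- generate_resource_table(444, n_rows = 6, overflow_rate = 0.5)
  cand <- select_overflow_candidates(filter_resource_tables(list(g)))
  expect_length(cand, 1L)
  widths <- allocate_column_widths(g, cand[[1]]$width_budget)
  expected_pos <- 0L
  for (j in seq_len(ncol(g$cells))) {
    for (s in g$cells[, j]) {
      if (nchar(s) > widths[j]) {
        expected_pos <- expected_pos + length(split_cell(s, widths[j])) - 1L
      }
    }
  }
  expect_gte(expected_pos, 2L)
  ds <- generate_pair_dataset(list(g), seed = 3)
  expect_equal(sum(ds$label == 1), expected_pos)
})

test_that("short tables yield nothing; negatives pair only intact cells", {
  short <- table_grid(matrix(c("RRID:AB_1", "b", "c", "d"), 2, 2))
  expect_equal(nrow(generate_pair_dataset(list(short), seed = 1)), 0L)
  g <- generate_resource_table(445, n_rows = 6, overflow_rate = 0.4)
  ds <- generate_pair_dataset(list(g), seed = 1)
  neg <- ds[ds$label == 0, ]
  expect_gt(nrow(neg), 0)
  expect_true(all(neg$upper %in% g$cells))
  expect_true(all(neg$lower %in% g$cells))
})

test_that("the dataset is a deterministic function of tables and seed", {
  tabs <- lapply(1:6, function(i) {
    generate_resource_table(400 + i, n_rows = 6, overflow_rate = 0.5)
  })
  a <- generate_pair_dataset(tabs, seed = 9)
  b <- generate_pair_dataset(tabs, seed = 9)
  expect_identical(a, b)
  d <- generate_pair_dataset(tabs, seed = 10)
  expect_false(identical(a$split, d$split))
  # table-level split: no table id on both sides
  both <- intersect(a$table_id[a$split == "train"],
                    a$table_id[a$split == "test"])
  expect_length(both, 0L)
  # positives' upper lines respect their column width
  cands <- select_overflow_candidates(filter_resource_tables(tabs))
  for (ti in unique(a$table_id[a$label == 1])) {
    w <- max(allocate_column_widths(cands[[ti]]$grid, cands[[ti]]$width_budget))
    expect_true(all(nchar(a$upper[a$label == 1 & a$table_id == ti]) <= w))
  }
})

test_that("pair datasets serialize to TSV and JSONL", {
  ds <- data.frame(upper = c("a", "b"), lower = c("c", "d"), label = c(1, 0),
                   table_id = 1L, split = "train")
  ft <- tempfile(fileext = ".tsv")
  write_pair_dataset(ds, ft)
  expect_equal(readLines(ft), c("a\tc\t1", "b\td\t0"))
  fj <- tempfile(fileext = ".jsonl")
  write_pair_dataset(ds, fj, "jsonl")
  rec <- jsonlite::fromJSON(readLines(fj)[1])
  expect_equal(rec$upper, "a")
  expect_equal(rec$label, 1)
})
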