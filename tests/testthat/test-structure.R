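test_that("image-to-page rescaling is the per-axis linear map", {
  r <- list(detected_region(bbox(100, 100, 200, 200), "table", 0.9))
  out <- scale_to_page(r, c(1000, 1000), c(500, 500))[[1]]
  expect_equal(as.numeric(out$box), c(50, 50, 100, 100))
  same <- scale_to_page(r, c(640, 480), c(640, 480))[[1]]
  expect_equal(as.numeric(same$box), as.numeric(r[[1]]$box))
  # round trip A -> B -> A
  fwd <- scale_to_page(r, c(1234, 777), c(612, 792))
  back <- scale_to_page(fwd, c(612, 792), c(1234, 777))[[1]]
  expect_equal(as.numeric(back$box), as.numeric(r[[1]]$box), tolerance = 1e-9)
  expect_error(scale_to_page(r, c(0, 100), c(500, 500)), "positive")
})

test_that("column count is the lower-middle median of row cell counts", {
  rows_of <- function(counts) lapply(counts, function(k) {
    lapply(seq_len(k), function(j) detected_region(bbox(j, 0, j + 0.5, 1), "cell"))
  })
  expect_equal(estimate_column_count(rows_of(c(3, 3, 3))), 3L)
  expect_equal(estimate_column_count(rows_of(c(3, 3, 4))), 3L)
  expect_equal(estimate_column_count(rows_of(c(2, 4))), 2L)
  expect_error(estimate_column_count(list()), "no rows")
})

test_that("column ranges use min/max with padding and a widened last column", {
  row <- list(list(detected_region(bbox(10, 0, 50, 10), "cell"),
                   detected_region(bbox(60, 0, 120, 10), "cell")))
  cl <- estimate_column_ranges(row, 2L, avg_char_width = 5)
  expect_equal(as.numeric(cl$ranges[[1]]), c(9, 51))
  expect_equal(as.numeric(cl$ranges[[2]]), c(59, 131))
  # rows with the wrong cell count are excluded; identical rows are a no-op
  rows3 <- c(row, row, list(list(detected_region(bbox(0, 0, 200, 10), "cell"))))
  cl3 <- estimate_column_ranges(rows3, 2L, avg_char_width = 5)
  expect_equal(as.numeric(cl3$ranges[[1]]), c(9, 51))
  expect_error(estimate_column_ranges(rows3[3], 2L, 5), "no row")
})

test_that("overlapping padded column ranges are split at the midpoint", {
  row <- list(list(detected_region(bbox(0, 0, 50, 10), "cell"),
                   detected_region(bbox(50.5, 0, 100, 10), "cell")))
  cl <- estimate_column_ranges(row, 2L, avg_char_width = 5)
  expect_equal(cl$ranges[[1]][["hi"]], cl$ranges[[2]][["lo"]])
  expect_lt(cl$ranges[[1]][["lo"]], cl$ranges[[1]][["hi"]])
})

test_that("row ranges come from TSR rows or from clustered text lines", {
  regs <- list(detected_region(bbox(0, 30, 100, 40), "row"),
               detected_region(bbox(0, 10, 100, 20), "row"))
  rr <- estimate_row_ranges("tsr_rows", rows = regs)
  expect_equal(as.numeric(rr[[1]]), c(9, 21))
  expect_equal(as.numeric(rr[[2]]), c(29, 41))
  expect_equal(estimate_row_ranges("tsr_rows", rows = list()), list())

  # five clean baselines -> five ranges; a superscript adds a spurious one
  g <- generate_resource_table(41, n_rows = 4, superscript_rate = 0)
  pg <- extract_pages(render_to_pdf(g)$pdf)[[1]]
  tls <- group_text_lines(pg$chars)
  expect_length(estimate_row_ranges("pdf_lines", text_lines = tls), 5L)

  gs <- generate_resource_table(301, n_rows = 4, superscript_rate = 1)
  pgs <- extract_pages(render_to_pdf(gs)$pdf)[[1]]
  tls2 <- group_text_lines(pgs$chars)
  expect_gt(length(estimate_row_ranges("pdf_lines", text_lines = tls2)), 5L)
})

test_that("the mock detector honours the adapter contract", {
  g <- generate_resource_table(42, n_rows = 4)
  rd <- render_to_pdf(g)
  det <- mock_detector(rd$gold, image_scale = 2)
  tdet <- detect_tables(det, 1)
  expect_length(tdet, 1L)
  expect_equal(tdet[[1]]$kind, "table")
  isz <- attr(tdet, "image_size")
  tb <- scale_to_page(tdet, isz, rd$gold$page_size)[[1]]$box
  expect_equal(as.numeric(tb), as.numeric(rd$gold$pages[[1]]$table_boxes[[1]]))
  sdet <- detect_structure(det, 1, tb)
  kinds <- vapply(sdet, `[[`, "", "kind")
  expect_setequal(unique(kinds), c("column", "row", "cell"))
  expect_equal(sum(kinds == "column"), 3L)
  expect_equal(sum(kinds == "row"), 5L)
})

test_that("detector regions survive the JSON exchange format", {
  regs <- list(detected_region(bbox(1, 2, 3, 4), "cell", 0.5),
               detected_region(bbox(0, 0, 9, 9), "table", 1))
  f <- tempfile(fileext = ".json")
  write_regions_json(regs, f)
  back <- read_regions_json(f)
  expect_equal(back[[1]]$kind, "cell")
  expect_equal(as.numeric(back[[2]]$box), c(0, 0, 9, 9))
  expect_error(detected_region(bbox(0, 0, 1, 1), "cell", 1.2), "score")
})
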