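test_that("extraction over gold ranges reproduces the rendered grid", {
  g <- generate_resource_table(51, n_rows = 5, overflow_rate = 0)
  rd <- render_to_pdf(g)
  pg <- extract_pages(rd$pdf)[[1]]
  str <- rd$gold$pages[[1]]$structures[[1]]
  columns <- column_layout(lapply(str$col_boxes, function(b)
    interval(b[["xmin"]], b[["xmax"]])))
  rowr <- lapply(str$row_boxes, function(b) interval(b[["ymin"]], b[["ymax"]]))
  grid <- extract_grid(pg$chars, rd$gold$pages[[1]]$table_boxes[[1]],
                       columns, rowr)
  expect_equal(grid$cells, g$cells)
  st <- attr(grid, "stats")
  expect_equal(st$chars_assigned, st$chars_total)
})

test_that("a character centered on a shared column boundary goes left", {
  df <- restable:::chars_df("z", 9, 10, 11, 16)  # center x = 10
  cols <- column_layout(list(interval(0, 10), interval(10, 20)))
  grid <- extract_grid(df, bbox(0, 0, 20, 20), cols, list(interval(8, 18)))
  expect_equal(grid$cells[1, ], c("z", ""))
})

test_that("overflowing cells split across text-line rows before merging", {
  g <- generate_resource_table(52, n_rows = 5, overflow_rate = 0.6)
  rd <- render_to_pdf(g)
  pg <- extract_pages(rd$pdf)[[1]]
  str <- rd$gold$pages[[1]]$structures[[1]]
  columns <- column_layout(lapply(str$col_boxes, function(b)
    interval(b[["xmin"]], b[["xmax"]])))
  tls <- group_text_lines(pg$chars)
  rowr <- estimate_row_ranges("pdf_lines", text_lines = tls)
  grid <- extract_grid(pg$chars, rd$gold$pages[[1]]$table_boxes[[1]],
                       columns, rowr)
  expect_gt(nrow(grid$cells), nrow(g$cells))
})

test_that("the 70% rectangle rule absorbs superscript rows", {
  # spurious superscript-only row above its baseline row, both inside one
  # TSR row rectangle
  cells <- rbind(c("REAGENT", "SOURCE", "ID"),
                 c("a", "", ""),             # superscript fragment
                 c("anti-Sox2", "Abcam", "RRID:AB_1"),
                 c("DAPI", "Sigma", "Cat# 1"))
  text_ranges <- list(interval(0, 8), interval(18, 22), interval(20, 28),
                      interval(32, 40))
  rect_ranges <- list(interval(-1, 9), interval(19, 29), interval(31, 41))
  out <- heuristic_row_merge(table_grid(cells), text_ranges, rect_ranges)
  gold <- rbind(c("REAGENT", "SOURCE", "ID"),
                c("a anti-Sox2", "Abcam", "RRID:AB_1"),
                c("DAPI", "Sigma", "Cat# 1"))
  expect_equal(out$cells, gold)
})

test_that("the 50% text-range rule merges continuation rows", {
  cells <- rbind(c("anti-Sox2", "Abcam", "Cat# 12; RRID:"),
                 c("", "", "AB_123456"))
  # tight leading: the continuation row's text range overlaps the row above
  text_ranges <- list(interval(0, 10), interval(5, 13))
  out <- heuristic_row_merge(table_grid(cells), text_ranges, NULL)
  expect_equal(out$cells,
               matrix(c("anti-Sox2", "Abcam", "Cat# 12; RRID: AB_123456"),
                      1, 3))
})

test_that("heuristic merging leaves complete, well-separated grids alone", {
  g <- table_grid(rbind(c("a", "b"), c("c", "d"), c("e", "f")))
  rngs <- list(interval(0, 8), interval(20, 28), interval(40, 48))
  out <- heuristic_row_merge(g, rngs, NULL)
  expect_equal(out$cells, g$cells)
  expect_equal(attr(out, "n_merges"), 0L)
})

test_that("heuristic merging never adds rows and is idempotent", {
  set.seed(9)
  for (i in 1:20) {
    R <- sample(2:6, 1)
    cells <- matrix(sample(c("", "x", "yy"), R * 3, TRUE), R, 3)
    tops <- cumsum(runif(R, 2, 12))
    rngs <- lapply(seq_len(R), function(r) interval(tops[r], tops[r] + 7))
    out <- heuristic_row_merge(table_grid(cells), rngs, NULL)
    expect_lte(nrow(out$cells), R)
    # character conservation (up to join spaces)
    strip <- function(m) sort(unlist(strsplit(gsub(" ", "", m), "")))
    expect_equal(strip(out$cells), strip(cells))
    again <- heuristic_row_merge(out, attr(out, "row_ranges"), NULL)
    expect_equal(again$cells, out$cells)
  }
})
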