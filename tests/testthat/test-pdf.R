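test_that("rendered fixture tables round-trip through the PDF reader", {
  g <- generate_resource_table(31, n_rows = 4, overflow_rate = 0,
                               superscript_rate = 0)
  rd <- render_to_pdf(g)
  pages <- extract_pages(rd$pdf)
  expect_length(pages, 1L)
  page_text <- paste(vapply(group_text_lines(pages[[1]]$chars),
                            function(l) l$text, character(1)), collapse = " ")
  for (cell in as.vector(g$cells)) {
    expect_true(grepl(cell, page_text, fixed = TRUE))
  }
})

test_that("ruled tables expose at least R+1 hlines and C+1 vlines", {
  g <- generate_resource_table(32, n_rows = 5, ruled = TRUE)
  rd <- render_to_pdf(g)
  pg <- extract_pages(rd$pdf)[[1]]
  tb <- rd$gold$pages[[1]]$table_boxes[[1]]
  inside_h <- sum(pg$graphics$hlines$ymin >= tb[["ymin"]] - 1 &
                    pg$graphics$hlines$ymin <= tb[["ymax"]] + 1)
  inside_v <- sum(pg$graphics$vlines$xmin >= tb[["xmin"]] - 1 &
                    pg$graphics$vlines$xmin <= tb[["xmax"]] + 1)
  expect_gte(inside_h, nrow(g$cells) + 1L)
  expect_gte(inside_v, ncol(g$cells) + 1L)
})

test_that("an empty page yields zero characters and graphics", {
  doc <- pdf_new()
  pdf_add_page(doc)
  pg <- extract_pages(pdf_bytes(doc))[[1]]
  expect_equal(nrow(pg$chars), 0L)
  expect_equal(nrow(pg$graphics$hlines), 0L)
})

test_that("unparseable input raises a structured PDF error", {
  expect_error(extract_pages(charToRaw("not a pdf at all")),
               class = "restable_pdf_error")
})

test_that("line grouping follows top-y and gap rules", {
  mk <- function(xs, ys, w = 4) {
    chars_df <- restable:::chars_df
    chars_df(rep("a", length(xs)), xs, ys, xs + w, ys + 6)
  }
  # two adjacent chars on one baseline form one line of two glyphs
  one <- group_text_lines(mk(c(0, 4), c(10, 10)))
  expect_length(one, 1L)
  expect_equal(nrow(one[[1]]$chars), 2L)
  # chars with x gaps 1,1,40,1 at width 5 and gap_tol 3 split into two lines
  xs <- c(0, 6, 12, 57, 63)
  df <- restable:::chars_df(rep("b", 5), xs, 20, xs + 5, 27)
  two <- group_text_lines(df, gap_tol = 3)
  expect_length(two, 2L)
  # a raised superscript beyond y_tol becomes its own (spurious) line
  sup <- rbind(mk(c(0, 4, 8), c(10, 10, 10)), mk(12, 7.5, 2.5))
  expect_length(group_text_lines(sup, y_tol = 1), 2L)
})

test_that("line grouping conserves characters and is idempotent", {
  g <- generate_resource_table(33, n_rows = 4)
  pg <- extract_pages(render_to_pdf(g)$pdf)[[1]]
  lines <- group_text_lines(pg$chars)
  all_chars <- do.call(rbind, lapply(lines, `[[`, "chars"))
  expect_equal(nrow(all_chars), nrow(pg$chars))
  expect_setequal(paste(all_chars$char, all_chars$xmin, all_chars$ymin),
                  paste(pg$chars$char, pg$chars$xmin, pg$chars$ymin))
  # regrouping each line's own chars returns the line unchanged
  for (l in lines[1:3]) {
    again <- group_text_lines(l$chars)
    expect_length(again, 1L)
    expect_equal(again[[1]]$text, l$text)
  }
})

test_that("word spacing is reconstructed from gaps", {
  doc <- pdf_new()
  pdf_add_page(doc, 200, 100)
  pdf_text_run(doc, 1, 10, 50, "Cat# 17454", 8)
  pg <- extract_pages(pdf_bytes(doc))[[1]]
  # space glyphs carry no box; the gap re-inserts the space in line text
  expect_equal(nrow(pg$chars), 9L)
  expect_equal(group_text_lines(pg$chars)[[1]]$text, "Cat# 17454")
})

test_that("duplicate glyph emissions are dropped, distinct glyphs kept", {
  # overlapping same-character pair (IoU > 0.8) collapses to one box
  df <- restable:::chars_df(c("x", "x", "y"), c(0, 0.01, 5), c(0, 0, 0),
                            c(4, 4.01, 9), c(6, 6, 6))
  expect_equal(nrow(restable:::dedupe_chars(df)), 2L)
  # different characters at the same position are not duplicates
  df2 <- restable:::chars_df(c("x", "o"), c(0, 0), c(0, 0), c(4, 4), c(6, 6))
  expect_equal(nrow(restable:::dedupe_chars(df2)), 2L)
})
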