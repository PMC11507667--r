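# Materializing a table grid from PDF characters and estimated ranges.

#' Assign characters to a grid of column and row ranges
#'
#' Every character whose box center lies inside `table_box` is assigned to
#' the column whose x-range contains its x-center (a center exactly on a
#' shared boundary goes to the left column) and to the row whose y-range
#' contains its top y (ambiguity between overlapping row ranges -- raised
#' superscripts -- resolves to the range whose top is nearest).  Cell text
#' is the character run ordered by (y, x) with the text-line spacing rule;
#' characters matching no range are dropped and counted.
#'
#' @param chars Character data frame (see [extract_pages()]).
#' @param table_box Page-coordinate [bbox()] of the table.
#' @param columns A [column_layout()].
#' @param row_ranges List of [interval()] y-ranges (see
#'   [estimate_row_ranges()]).
#' @return A [table_grid()] with attribute `"stats"`: `chars_total`,
#'   `chars_assigned`, `rows_before_merge`.
#' @export
extract_grid <- function(chars, table_box, columns, row_ranges) {
  if (!inherits(columns, "column_layout") || columns$n_cols < 1) {
    stop("extract_grid needs at least one column range")
  }
  R <- length(row_ranges); C <- columns$n_cols
  if (R == 0) stop("extract_grid needs at least one row range")
  cells <- matrix("", R, C)
  xc <- (chars$xmin + chars$xmax) / 2
  yc <- (chars$ymin + chars$ymax) / 2
  inside <- xc >= table_box[["xmin"]] & xc <= table_box[["xmax"]] &
    yc >= table_box[["ymin"]] & yc <= table_box[["ymax"]]
  sub <- chars[inside, , drop = FALSE]
  xc <- xc[inside]
  total <- nrow(chars); assigned <- 0L

  col_lo <- vapply(columns$ranges, function(r) r[["lo"]], numeric(1))
  col_hi <- vapply(columns$ranges, function(r) r[["hi"]], numeric(1))
  row_lo <- vapply(row_ranges, function(r) r[["lo"]], numeric(1))
  row_hi <- vapply(row_ranges, function(r) r[["hi"]], numeric(1))

  col_of <- integer(nrow(sub)); row_of <- integer(nrow(sub))
  for (i in seq_len(nrow(sub))) {
    jc <- which(xc[i] >= col_lo & xc[i] <= col_hi)
    jr <- which(sub$ymin[i] >= row_lo & sub$ymin[i] <= row_hi)
    if (length(jr) > 1) jr <- jr[which.min(abs(row_lo[jr] - sub$ymin[i]))]
    col_of[i] <- if (length(jc)) jc[1] else NA_integer_  # boundary tie: left
    row_of[i] <- if (length(jr)) jr[1] else NA_integer_
  }
  ok <- !is.na(col_of) & !is.na(row_of)
  assigned <- sum(ok)
  for (r in seq_len(R)) {
    for (cc in seq_len(C)) {
      sel <- ok & row_of == r & col_of == cc
      if (!any(sel)) next
      lines <- group_text_lines(sub[sel, , drop = FALSE])
      cells[r, cc] <- paste(vapply(lines, function(l) l$text, character(1)),
                            collapse = " ")
    }
  }
  out <- table_grid(cells)
  attr(out, "stats") <- list(chars_total = total, chars_assigned = assigned,
                             rows_before_merge = R)
  out
}

#' Heuristic row-merge canonicalization
#'
#' Two rules repair spurious rows created by top-y line grouping, applied
#' top to bottom with cascading re-tests:
#'
#' * Rule 1 (needs TSR row rectangles): when consecutive text rows map to
#'   the same closest row rectangle and the tested row's text range lies 70%
#'   or more inside that rectangle, the rows merge -- this absorbs
#'   superscript/subscript-only lines into their baseline row.
#' * Rule 2: when a row has empty cells, the row above has none, and the
#'   tested row's text range overlaps 50% or more with the closest other
#'   row's text range (which must be the row above), the rows merge.
#'
#' Overlap ratios are [interval_overlap_ratio()] with the tested row's text
#' range as the first argument.  Merging concatenates cells column-wise with
#' one space (an empty cell contributes nothing).
#'
#' @param grid A [table_grid()] whose rows correspond to `row_text_ranges`.
#' @param row_text_ranges List of [interval()] text y-ranges, one per row.
#' @param row_rect_ranges Optional list of [interval()] TSR row-rectangle
#'   y-ranges (rule 1 is skipped when absent).
#' @param rule1_overlap,rule2_overlap Rule thresholds.
#' @return The canonicalized [table_grid()]; attribute `"row_ranges"` holds
#'   the merged rows' text ranges, attribute `"n_merges"` the merge count.
#' @export
heuristic_row_merge <- function(grid, row_text_ranges, row_rect_ranges = NULL,
                                rule1_overlap = 0.7, rule2_overlap = 0.5) {
  cells <- grid$cells
  ranges <- row_text_ranges
  stopifnot(length(ranges) == nrow(cells))

  closest_rect <- function(rng) {
    if (!length(row_rect_ranges)) return(NA_integer_)
    cen <- interval_center(rng)
    which.min(vapply(row_rect_ranges, function(r) abs(interval_center(r) - cen),
                     numeric(1)))
  }
  n_merges <- 0L
  i <- 2L
  while (i <= nrow(cells)) {
    merged <- FALSE
    # rule 1: same closest rectangle as the row above, mostly sub/superscripts
    if (length(row_rect_ranges)) {
      ri <- closest_rect(ranges[[i]])
      rup <- closest_rect(ranges[[i - 1L]])
      if (!is.na(ri) && ri == rup &&
          interval_overlap_ratio(ranges[[i]], row_rect_ranges[[ri]]) >= rule1_overlap) {
        merged <- TRUE
      }
    }
    # rule 2: continuation row with empty cells under a complete row
    if (!merged && any(cells[i, ] == "") && all(cells[i - 1L, ] != "")) {
      cen <- interval_center(ranges[[i]])
      others <- setdiff(seq_along(ranges), i)
      j <- others[which.min(vapply(ranges[others], function(r)
        abs(interval_center(r) - cen), numeric(1)))]
      if (j == i - 1L &&
          interval_overlap_ratio(ranges[[i]], ranges[[j]]) >= rule2_overlap) {
        merged <- TRUE
      }
    }
    if (merged) {
      # order the two rows by their top so text order follows the page
      top_first <- ranges[[i - 1L]][["lo"]] <= ranges[[i]][["lo"]]
      cells[i - 1L, ] <- if (top_first) join_rows(cells[i - 1L, ], cells[i, ])
                         else join_rows(cells[i, ], cells[i - 1L, ])
      ranges[[i - 1L]] <- interval(min(ranges[[i - 1L]][["lo"]], ranges[[i]][["lo"]]),
                                   max(ranges[[i - 1L]][["hi"]], ranges[[i]][["hi"]]))
      cells <- cells[-i, , drop = FALSE]
      ranges[[i]] <- NULL
      n_merges <- n_merges + 1L
      # the merged row is re-tested against the next row (same i)
    } else {
      i <- i + 1L
    }
  }
  out <- table_grid(cells)
  attr(out, "row_ranges") <- ranges
  attr(out, "n_merges") <- n_merges
  out
}
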