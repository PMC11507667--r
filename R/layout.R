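# Column/row layout estimation from structure detections.

#' Column layout of a table
#' @param ranges List of [interval()] x-ranges, left to right.
#' @return Object of class `column_layout` with `n_cols` and `ranges`.
#' @export
column_layout <- function(ranges) {
  los <- vapply(ranges, function(r) r[["lo"]], numeric(1))
  ranges <- ranges[order(los)]
  structure(list(n_cols = length(ranges), ranges = ranges),
            class = "column_layout")
}

#' @export
print.column_layout <- function(x, ...) {
  cat(sprintf("<column_layout %d columns>\n", x$n_cols))
  for (r in x$ranges) cat(sprintf("  [%.1f, %.1f]\n", r[["lo"]], r[["hi"]]))
  invisible(x)
}

#' Group detected cell regions into rows by y-center clustering
#'
#' Cells whose vertical centers lie within half the median cell height of a
#' running row center share a row; rows are returned top to bottom with
#' their cells sorted left to right.
#'
#' @param cells List of `"cell"` [detected_region()]s in page coordinates.
#' @return List of lists of regions.
#' @export
group_cells_into_rows <- function(cells) {
  if (!length(cells)) return(list())
  yc <- vapply(cells, function(r) (r$box[["ymin"]] + r$box[["ymax"]]) / 2, numeric(1))
  hts <- vapply(cells, function(r) r$box[["ymax"]] - r$box[["ymin"]], numeric(1))
  tol <- stats::median(hts) / 2
  ord <- order(yc)
  rows <- list(); centers <- numeric(0)
  for (i in ord) {
    placed <- FALSE
    if (length(centers)) {
      j <- which.min(abs(centers - yc[i]))
      if (abs(centers[j] - yc[i]) <= tol) {
        rows[[j]] <- c(rows[[j]], list(cells[[i]]))
        centers[j] <- mean(vapply(rows[[j]], function(r)
          (r$box[["ymin"]] + r$box[["ymax"]]) / 2, numeric(1)))
        placed <- TRUE
      }
    }
    if (!placed) {
      rows[[length(rows) + 1L]] <- list(cells[[i]])
      centers <- c(centers, yc[i])
    }
  }
  ord2 <- order(centers)
  lapply(rows[ord2], function(rw) {
    rw[order(vapply(rw, function(r) r$box[["xmin"]], numeric(1)))]
  })
}

#' Effective column count: median of per-row cell counts
#'
#' An even number of rows takes the lower middle value, preferring fewer
#' columns since spurious extra cell detections are the common failure.
#'
#' @param rows List of row groups from [group_cells_into_rows()].
#' @return Integer column count.
#' @export
estimate_column_count <- function(rows) {
  if (!length(rows)) stop("no rows to estimate columns from")
  counts <- sort(vapply(rows, length, integer(1)))
  counts[(length(counts) + 1L) %/% 2L]
}

#' Column x-ranges from detected cells
#'
#' For each column the range spans the minimum xmin to the maximum xmax of
#' that column's cells across rows, padded by `pad` on both sides to absorb
#' boundary alignment error; the last column's upper bound gets two average
#' character widths extra to compensate for clipped trailing characters.
#' Rows whose cell count differs from `n_cols` are skipped for range
#' estimation.  Adjacent ranges that overlap after padding are truncated at
#' the overlap midpoint so the final ranges are disjoint.
#'
#' @param rows Row groups of cell regions in page coordinates.
#' @param n_cols Column count (see [estimate_column_count()]).
#' @param avg_char_width Average character width in points.
#' @param pad Padding in points (the "about 1 pixel" of the estimation rule).
#' @return A [column_layout()].
#' @export
estimate_column_ranges <- function(rows, n_cols, avg_char_width, pad = 1.0) {
  good <- Filter(function(rw) length(rw) == n_cols, rows)
  if (!length(good)) stop("no row with the estimated column count")
  lo <- rep(Inf, n_cols); hi <- rep(-Inf, n_cols)
  for (rw in good) {
    for (j in seq_len(n_cols)) {
      lo[j] <- min(lo[j], rw[[j]]$box[["xmin"]])
      hi[j] <- max(hi[j], rw[[j]]$box[["xmax"]])
    }
  }
  lo <- lo - pad; hi <- hi + pad
  hi[n_cols] <- hi[n_cols] + 2 * avg_char_width
  # resolve collisions introduced by padding
  for (j in seq_len(n_cols - 1L)) {
    if (hi[j] > lo[j + 1L]) {
      mid <- (hi[j] + lo[j + 1L]) / 2
      hi[j] <- mid; lo[j + 1L] <- mid
    }
  }
  column_layout(lapply(seq_len(n_cols), function(j) interval(lo[j], hi[j])))
}

#' Row y-ranges, from TSR row regions or from PDF text lines
#'
#' `tsr_rows` pads each detected row region's y-extent by `pad`; `pdf_lines`
#' clusters text lines by their top y (so superscript-only lines stay
#' separate, to be repaired later) and returns the vertical extent of each
#' cluster, top to bottom.
#'
#' @param mode `"tsr_rows"` or `"pdf_lines"`.
#' @param rows For `tsr_rows`: list of `"row"` [detected_region()]s in page
#'   coordinates.
#' @param text_lines For `pdf_lines`: list of `text_line`s (already limited
#'   to the table box).
#' @param pad Padding in points for `tsr_rows`.
#' @param y_tol Top-y clustering tolerance for `pdf_lines`.
#' @return List of [interval()] y-ranges, sorted top to bottom.
#' @export
estimate_row_ranges <- function(mode = c("tsr_rows", "pdf_lines"), rows = NULL,
                                text_lines = NULL, pad = 1.0, y_tol = 1.0) {
  mode <- match.arg(mode)
  if (mode == "tsr_rows") {
    if (!length(rows)) return(list())
    rr <- lapply(rows, function(r) interval(r$box[["ymin"]] - pad,
                                            r$box[["ymax"]] + pad))
    rr[order(vapply(rr, function(r) r[["lo"]], numeric(1)))]
  } else {
    if (!length(text_lines)) return(list())
    tops <- vapply(text_lines, function(l) l$y_range[["lo"]], numeric(1))
    ord <- order(tops)
    cl <- cumsum(c(1, diff(tops[ord]) > y_tol))
    out <- list()
    for (g in unique(cl)) {
      ls <- text_lines[ord[cl == g]]
      out[[length(out) + 1L]] <- interval(
        min(vapply(ls, function(l) l$y_range[["lo"]], numeric(1))),
        max(vapply(ls, function(l) l$y_range[["hi"]], numeric(1))))
    }
    out
  }
}
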