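#' Axis-aligned bounding box in page coordinates
#'
#' Boxes live in PDF points with the origin at the top-left of the page and
#' the y axis increasing downward.  Degenerate boxes (zero width and/or
#' height) are legal and have zero area; they are used to represent primitive
#' horizontal/vertical line graphics.
#'
#' @param xmin,ymin,xmax,ymax Numeric scalar coordinates, `xmin <= xmax` and
#'   `ymin <= ymax`.
#' @return An object of class `bbox` (named numeric vector).
#' @export
bbox <- function(xmin, ymin, xmax, ymax) {
  stopifnot(is.numeric(xmin), is.numeric(ymin), is.numeric(xmax), is.numeric(ymax))
  if (xmin > xmax || ymin > ymax) {
    stop("invalid bbox: requires xmin <= xmax and ymin <= ymax")
  }
  structure(c(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
              xmax = as.numeric(xmax), ymax = as.numeric(ymax)),
            class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox (%.2f, %.2f) -- (%.2f, %.2f)>\n",
              x[["xmin"]], x[["ymin"]], x[["xmax"]], x[["ymax"]]))
  invisible(x)
}

#' Area of a bounding box
#' @param b A [bbox()].
#' @return Non-negative numeric scalar; 0 for degenerate boxes.
#' @export
bbox_area <- function(b) {
  (b[["xmax"]] - b[["xmin"]]) * (b[["ymax"]] - b[["ymin"]])
}

#' Intersection of two boxes, or NULL when they do not meet
#' @param a,b [bbox()] objects.
#' @return A `bbox` or `NULL`.
#' @export
bbox_intersect <- function(a, b) {
  x1 <- max(a[["xmin"]], b[["xmin"]]); y1 <- max(a[["ymin"]], b[["ymin"]])
  x2 <- min(a[["xmax"]], b[["xmax"]]); y2 <- min(a[["ymax"]], b[["ymax"]])
  if (x1 > x2 || y1 > y2) return(NULL)
  bbox(x1, y1, x2, y2)
}

#' Intersection-over-union of two bounding boxes
#'
#' Used both on page-coordinate boxes and on grid-coordinate span rectangles
#' (cell topology similarity).  When the union has zero area -- both boxes
#' degenerate -- the ratio is defined as 0.
#'
#' @param a,b [bbox()] objects.
#' @return Ratio in `[0, 1]`; symmetric in its arguments.
#' @export
iou <- function(a, b) {
  inter <- bbox_intersect(a, b)
  ai <- if (is.null(inter)) 0 else bbox_area(inter)
  u <- bbox_area(a) + bbox_area(b) - ai
  if (u <= 0) return(0)
  ai / u
}

#' Closed 1-D coordinate interval
#'
#' Carrier for column x-ranges and row y-ranges.
#'
#' @param lo,hi Numeric endpoints, `lo <= hi`.
#' @return An object of class `interval` (named numeric vector).
#' @export
interval <- function(lo, hi) {
  if (lo > hi) stop("invalid interval: requires lo <= hi")
  structure(c(lo = as.numeric(lo), hi = as.numeric(hi)), class = "interval")
}

#' @export
print.interval <- function(x, ...) {
  cat(sprintf("<interval [%.2f, %.2f]>\n", x[["lo"]], x[["hi"]]))
  invisible(x)
}

interval_length <- function(a) a[["hi"]] - a[["lo"]]

#' Directed interval overlap ratio
#'
#' Length of the intersection of `a` and `b` divided by the length of `a`.
#' The ratio is deliberately asymmetric: in the row-merge rules the first
#' argument is the row range being tested for absorption, so the ratio is
#' monotone in how much of that row is covered.  A zero-length first argument
#' yields 0.
#'
#' @param a,b [interval()] objects.
#' @return Ratio in `[0, 1]`.
#' @export
interval_overlap_ratio <- function(a, b) {
  la <- interval_length(a)
  if (la <= 0) return(0)
  inter <- min(a[["hi"]], b[["hi"]]) - max(a[["lo"]], b[["lo"]])
  if (inter <= 0) return(0)
  min(1, inter / la)
}

# midpoint of an interval (internal)
interval_center <- function(a) (a[["lo"]] + a[["hi"]]) / 2

#' One PDF character with its page box
#'
#' The atomic unit all text extraction aligns to: a single Unicode code point
#' plus its bounding box and 1-based page index.
#'
#' @param char Single-character string.
#' @param box A [bbox()].
#' @param page_index 1-based page number.
#' @return An object of class `char_box`.
#' @export
char_box <- function(char, box, page_index = 1L) {
  if (!is.character(char) || length(char) != 1L || nchar(char) != 1L) {
    stop("char must be exactly one character")
  }
  structure(list(char = char, box = box, page_index = as.integer(page_index)),
            class = "char_box")
}

# Column-wise data frame of character boxes: the internal working format.
# Columns: char, xmin, ymin, xmax, ymax, page.
chars_df <- function(char, xmin, ymin, xmax, ymax, page = 1L) {
  data.frame(char = as.character(char),
             xmin = as.numeric(xmin), ymin = as.numeric(ymin),
             xmax = as.numeric(xmax), ymax = as.numeric(ymax),
             page = rep(as.integer(page), length.out = length(char)),
             stringsAsFactors = FALSE)
}

empty_chars_df <- function() {
  chars_df(character(0), numeric(0), numeric(0), numeric(0), numeric(0), integer(0))
}

#' Convert a list of `char_box` objects to the data-frame working format
#' @param chars List of [char_box()] objects (or an existing data frame,
#'   returned unchanged).
#' @return Data frame with columns char, xmin, ymin, xmax, ymax, page.
#' @export
as_chars_df <- function(chars) {
  if (is.data.frame(chars)) return(chars)
  if (length(chars) == 0) return(empty_chars_df())
  do.call(rbind, lapply(chars, function(cb) {
    chars_df(cb$char, cb$box[["xmin"]], cb$box[["ymin"]],
             cb$box[["xmax"]], cb$box[["ymax"]], cb$page_index)
  }))
}

#' Primitive line graphics of a page
#'
#' Horizontal and vertical rules harvested from PDF stroke operations, stored
#' as degenerate boxes (hlines have `ymin == ymax`, vlines `xmin == xmax`).
#'
#' @param hlines,vlines Data frames with columns xmin, ymin, xmax, ymax (may
#'   be empty).
#' @return An object of class `page_graphics`.
#' @export
page_graphics <- function(hlines = NULL, vlines = NULL) {
  empty <- data.frame(xmin = numeric(0), ymin = numeric(0),
                      xmax = numeric(0), ymax = numeric(0))
  if (is.null(hlines)) hlines <- empty
  if (is.null(vlines)) vlines <- empty
  if (nrow(hlines) && any(hlines$ymin != hlines$ymax)) stop("hlines must have ymin == ymax")
  if (nrow(vlines) && any(vlines$xmin != vlines$xmax)) stop("vlines must have xmin == xmax")
  structure(list(hlines = hlines, vlines = vlines), class = "page_graphics")
}
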