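#' Table grid: the common currency of all pipelines and of GriTS
#'
#' An R x C character matrix of cell contents (empty string = empty cell),
#' with optional per-cell grid spans and page-coordinate cell boxes.  Spans
#' are 0-based half-open rectangles `(row_start, row_end, col_start, col_end)`
#' in grid coordinates; when present they must tile the grid without overlap.
#'
#' @param cells Character matrix (or object coercible to one).
#' @param spans Optional list (same length as `cells`, row-major) of integer
#'   vectors `c(row_start, row_end, col_start, col_end)`.
#' @param cell_boxes Optional list of [bbox()] per cell (row-major), or NULL.
#' @return An object of class `table_grid`.
#' @export
table_grid <- function(cells, spans = NULL, cell_boxes = NULL) {
  if (is.data.frame(cells)) cells <- as.matrix(cells)
  if (!is.matrix(cells)) cells <- matrix(as.character(cells), nrow = 1)
  storage.mode(cells) <- "character"
  cells[is.na(cells)] <- ""
  dimnames(cells) <- NULL
  if (!is.null(spans)) {
    if (length(spans) != length(cells)) stop("spans must have one entry per cell")
    check_spans_tile(spans, nrow(cells), ncol(cells))
  }
  structure(list(cells = cells, spans = spans, cell_boxes = cell_boxes),
            class = "table_grid")
}

# verify spans tile the R x C grid exactly once
check_spans_tile <- function(spans, R, C) {
  cover <- matrix(0L, R, C)
  for (sp in spans) {
    if (is.null(sp)) next
    rs <- sp[1] + 1L; re <- sp[2]; cs <- sp[3] + 1L; ce <- sp[4]
    if (rs > re || cs > ce || re > R || ce > C) stop("span outside grid")
    cover[rs:re, cs:ce] <- cover[rs:re, cs:ce] + 1L
  }
  if (any(cover > 1L)) stop("spans overlap")
  invisible(TRUE)
}

#' @export
dim.table_grid <- function(x) dim(x$cells)

#' @export
print.table_grid <- function(x, max_width = 24, ...) {
  d <- dim(x$cells)
  cat(sprintf("<table_grid %d x %d>\n", d[1], d[2]))
  shown <- x$cells
  long <- nchar(shown) > max_width
  shown[long] <- paste0(substr(shown[long], 1, max_width - 1), "…")
  print(shown, quote = FALSE)
  invisible(x)
}

#' @export
as.matrix.table_grid <- function(x, ...) x$cells

grid_nrow <- function(g) nrow(g$cells)
grid_ncol <- function(g) ncol(g$cells)

# default spans: every cell occupies its own 1x1 grid rectangle
default_spans <- function(R, C) {
  idx <- expand.grid(col = seq_len(C), row = seq_len(R))  # row-major order
  lapply(seq_len(R * C), function(k) {
    r <- ((k - 1L) %/% C); cc <- ((k - 1L) %% C)
    c(r, r + 1L, cc, cc + 1L)
  })
}

# spans of a grid, filling in 1x1 defaults when absent; row-major list
grid_spans <- function(g) {
  if (!is.null(g$spans)) return(g$spans)
  default_spans(grid_nrow(g), grid_ncol(g))
}

# row-major linear index of cell (r, c), 1-based
cell_index <- function(g, r, c) (r - 1L) * grid_ncol(g) + c

#' Write a table grid to JSON
#'
#' Serialized as a list of rows plus optional spans, readable back with
#' [read_table_grid_json()].
#'
#' @param grid A [table_grid()].
#' @param path Output file path.
#' @export
write_table_grid_json <- function(grid, path) {
  obj <- list(cells = apply(grid$cells, 1, as.list, simplify = FALSE))
  if (!is.null(grid$spans)) obj$spans <- grid$spans
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a table grid from JSON written by [write_table_grid_json()]
#' @param path Input file path.
#' @return A [table_grid()].
#' @export
read_table_grid_json <- function(path) {
  obj <- jsonlite::read_json(path)
  rows <- lapply(obj$cells, function(r) vapply(r, as.character, character(1)))
  cells <- do.call(rbind, rows)
  spans <- if (!is.null(obj$spans)) lapply(obj$spans, function(s) as.integer(unlist(s)))
  table_grid(cells, spans = spans)
}

#' Write a table grid to CSV (cells only)
#' @param grid A [table_grid()].
#' @param path Output file path.
#' @export
write_table_grid_csv <- function(grid, path) {
  utils::write.table(grid$cells, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a table grid from CSV (cells only)
#' @param path Input file path.
#' @return A [table_grid()].
#' @export
read_table_grid_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                   colClasses = "character",
                                   blank.lines.skip = FALSE))
  table_grid(m)
}

#' Render a table grid as a minimal HTML `<table>`
#' @param grid A [table_grid()].
#' @param header Treat the first row as `<th>` cells.
#' @return A single HTML string.
#' @export
format_table_grid_html <- function(grid, header = TRUE) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  rows <- vapply(seq_len(grid_nrow(grid)), function(r) {
    tag <- if (header && r == 1L) "th" else "td"
    cells <- paste0("<", tag, ">", esc(grid$cells[r, ]), "</", tag, ">", collapse = "")
    paste0("<tr>", cells, "</tr>")
  }, character(1))
  paste0("<table>", paste(rows, collapse = ""), "</table>")
}
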