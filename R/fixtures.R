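# Seeded generator of ground-truthed key-resource tables, and a renderer
# that draws them into born-digital PDFs while recording gold region boxes.
#
# The generator emulates the three-column resource-table convention
# (REAGENT or RESOURCE / SOURCE / IDENTIFIER): antibodies with catalog
# numbers and RRIDs, organisms with bracketed genotype strings, oligo
# sequences, software entries, and chemicals.  Cell lengths are steered so a
# requested fraction of body cells overflow their rendered column width.

rt_vendors <- c("Abcam", "Cell Signaling Technology", "Thermo Fisher Scientific",
                "Sigma-Aldrich", "BD Biosciences", "Santa Cruz Biotechnology",
                "Jackson ImmunoResearch", "Millipore")
rt_proteins <- c("Actb", "Tubb3", "Sox2", "Pax6", "Gfap", "Cd45", "Il6", "Tnf",
                 "Mapk1", "Erk2", "Gapdh", "Vim", "Nes", "Olig2", "Foxp3")
rt_software <- c("ImageJ", "Fiji", "CellProfiler", "GraphPad Prism", "MATLAB",
                 "FlowJo", "QuPath", "Imaris")
rt_soft_src <- c("NIH", "GraphPad Software", "MathWorks", "BD Biosciences",
                 "Oxford Instruments")
rt_hosts <- c("Rabbit", "Mouse", "Goat", "Rat", "Chicken")
rt_clonality <- c("monoclonal", "polyclonal")

rand_digits <- function(n) paste(sample(0:9, n, replace = TRUE), collapse = "")
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# one (name, source, identifier) triple of the given resource kind
rt_row <- function(kind) {
  switch(kind,
    antibody = c(
      paste(sample(rt_hosts, 1), sample(rt_clonality, 1), "anti-",
            sample(rt_proteins, 1)),
      sample(rt_vendors, 1),
      paste0("Cat# ", rand_digits(6), "; RRID:AB_", rand_digits(7))),
    organism = c(
      paste0("Mouse: B6.Cg-Tg(", sample(rt_proteins, 1), "-cre)",
             rand_digits(2), "Lt/J"),
      "The Jackson Laboratory",
      paste0("RRID:IMSR_JAX:", rand_digits(6))),
    fly = c(
      paste0("D. melanogaster: w[1118]; P{GawB}", tolower(sample(rt_proteins, 1)),
             "[md", rand_digits(3), "]/CyO"),
      "Bloomington Drosophila Stock Center",
      paste0("RRID:BDSC_", rand_digits(5))),
    oligo = c(
      paste0("Primer: ", sample(rt_proteins, 1), "_",
             sample(c("F", "R"), 1)),
      "This paper",
      rand_seq(sample(18:24, 1))),
    software = c(
      paste0(sample(rt_software, 1), " v", sample(1:9, 1), ".",
             sample(0:9, 1)),
      sample(rt_soft_src, 1),
      paste0("RRID:SCR_", rand_digits(6))),
    chemical = c(
      paste0(sample(c("DAPI", "Triton X-100", "Paraformaldehyde", "DMSO",
                      "Tamoxifen", "Doxycycline"), 1)),
      sample(rt_vendors, 1),
      paste0("Cat# ", sample(LETTERS, 1), rand_digits(5))))
}

# lengthen a cell until it overflows width (wrapping to 2-3 lines), or trim
# it so it fits
rt_fit <- function(s, width, overflow) {
  if (overflow) {
    fillers <- c(paste0("Lot# ", rand_digits(7)),
                 paste0("clone ", sample(LETTERS, 1), rand_digits(3)),
                 "lot verified by immunoblot",
                 paste0("dilution 1:", sample(c(100, 200, 500, 1000), 1)),
                 rand_seq(sample(12:20, 1)))
    target <- ceiling(stats::runif(1, 1.3, 2.2) * width)
    while (nchar(s) <= max(width, target - 12)) {
      s <- paste0(s, "; ", sample(fillers, 1))
    }
    s
  } else {
    while (nchar(s) > width) {
      cut <- regexpr("[ ;][^ ;]*$", substr(s, 1, width + 1))
      if (cut <= 1) { s <- substr(s, 1, width); break }
      s <- substr(s, 1, cut - 1)
    }
    s
  }
}

rt_header <- c("REAGENT or RESOURCE", "SOURCE", "IDENTIFIER")

#' Generate a seeded ground-truthed resource table
#'
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param n_rows Body rows (header row added on top).
#' @param overflow_rate Fraction of body cells lengthened past their column
#'   width, so they wrap when rendered.
#' @param superscript_rate Fraction of body rows whose first cell carries a
#'   superscript marker (rendered raised and small).
#' @param ruled Draw grid lines when rendered.
#' @param col_widths Per-column width budget in characters.
#' @return A [table_grid()] (gold contents; a superscript marker appears in
#'   the gold cell as a space-joined trailing token) with attributes
#'   `col_widths`, `ruled`, `render_sup` (marker matrix) and `xml`
#'   (JATS-style markup of the table).
#' @export
generate_resource_table <- function(seed, n_rows = 8, overflow_rate = 0,
                                    superscript_rate = 0, ruled = TRUE,
                                    col_widths = c(30, 22, 28)) {
  if (overflow_rate < 0 || overflow_rate > 1 || superscript_rate < 0 ||
      superscript_rate > 1) stop("rates must be in [0, 1]")
  stopifnot(n_rows >= 1)
  with_seed(seed, {
    kinds <- sample(c("antibody", "organism", "fly", "oligo", "software",
                      "chemical"), n_rows, replace = TRUE)
    cells <- matrix("", n_rows + 1L, 3L)
    cells[1, ] <- rt_header
    sup <- matrix("", n_rows + 1L, 3L)
    for (r in seq_len(n_rows)) {
      row <- rt_row(kinds[r])
      ov <- stats::runif(3) < overflow_rate
      for (j in 1:3) cells[r + 1L, j] <- rt_fit(row[j], col_widths[j], ov[j])
    }
    sup_rows <- which(stats::runif(n_rows) < superscript_rate) + 1L
    for (r in sup_rows) sup[r, 1] <- sample(c("a", "b", "c", "1", "2"), 1)
    gold <- ifelse(sup == "", cells, paste(cells, sup))
    g <- table_grid(gold)
    attr(g, "render_base") <- cells
    attr(g, "render_sup") <- sup
    attr(g, "col_widths") <- col_widths
    attr(g, "ruled") <- ruled
    attr(g, "xml") <- table_to_xml(gold)
    g
  })
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

#' Serialize gold cells as JATS-style table markup
#' @param cells Character matrix (first row = header).
#' @return A single XML string (`<table-wrap>` dialect).
#' @export
table_to_xml <- function(cells) {
  th <- paste0("<th>", xml_escape(cells[1, ]), "</th>", collapse = "")
  body <- vapply(seq_len(nrow(cells) - 1L) + 1L, function(r) {
    paste0("<tr>", paste0("<td>", xml_escape(cells[r, ]), "</td>",
                          collapse = ""), "</tr>")
  }, character(1))
  paste0("<table-wrap><table><thead><tr>", th, "</tr></thead><tbody>",
         paste(body, collapse = ""), "</tbody></table></table-wrap>")
}

#' Rendering layout for fixture tables
#' @param font_size Font size in points (Courier).
#' @param line_height Baseline-to-baseline distance in points.
#' @param col_gap Gap between columns in points.
#' @param margin_x,margin_top,margin_bottom Page margins in points.
#' @param page_width,page_height Page size in points.
#' @param line_numbers Draw margin line numbers (a common preprint feature).
#' @return A list of layout parameters.
#' @export
render_layout <- function(font_size = 8, line_height = 11, col_gap = 14,
                          margin_x = 72, margin_top = 72, margin_bottom = 72,
                          page_width = 612, page_height = 792,
                          line_numbers = FALSE) {
  as.list(environment())
}

#' Render a resource table to a born-digital PDF with gold geometry
#'
#' Draws the table in Courier (so character boxes are exact), wrapping each
#' cell to its column's character width; overflowing cells produce multiple
#' baselines inside one logical row.  Superscript markers are drawn raised
#' at reduced size.  Long tables continue onto following pages; the header
#' is drawn once.  The recorded gold geometry (table/column/row/cell boxes
#' per page) is what the [mock_detector()] serves.
#'
#' @param grid A [generate_resource_table()] grid (or any `table_grid` with
#'   `col_widths` attribute).
#' @param layout A [render_layout()].
#' @return List: `pdf` (raw bytes), `gold` (`pages`, `page_size`, `grid`),
#'   `n_pages`.
#' @export
render_to_pdf <- function(grid, layout = render_layout()) {
  base <- attr(grid, "render_base") %||% grid$cells
  sup <- attr(grid, "render_sup") %||% matrix("", nrow(base), ncol(base))
  widths <- attr(grid, "col_widths") %||% rep(24L, ncol(base))
  ruled <- isTRUE(attr(grid, "ruled"))
  char_w <- COURIER_WIDTH * layout$font_size
  col_x <- layout$margin_x + cumsum(c(0, (widths * char_w + layout$col_gap)))
  col_x <- col_x[seq_along(widths)]
  table_x1 <- col_x[length(widths)] + widths[length(widths)] * char_w
  if (table_x1 > layout$page_width - 36) stop("table wider than page")

  doc <- pdf_new()
  page <- pdf_add_page(doc, layout$page_width, layout$page_height)
  y <- layout$margin_top
  pages <- list()
  new_page_rec <- function() list(rows = list(), row_idx = integer(0))
  rec <- new_page_rec()
  line_no <- 0L

  flush_page <- function() {
    pages[[page]] <<- rec
    rec <<- new_page_rec()
  }

  for (r in seq_len(nrow(base))) {
    wrapped <- lapply(seq_len(ncol(base)), function(j) {
      if (base[r, j] == "") "" else split_cell(base[r, j], widths[j])
    })
    n_lines <- max(vapply(wrapped, length, integer(1)))
    row_h <- n_lines * layout$line_height
    if (y + row_h > layout$page_height - layout$margin_bottom) {
      flush_page()
      page <- pdf_add_page(doc, layout$page_width, layout$page_height)
      y <- layout$margin_top
    }
    cell_boxes <- vector("list", ncol(base))
    for (j in seq_len(ncol(base))) {
      lines <- wrapped[[j]]
      for (k in seq_along(lines)) {
        if (!nchar(lines[k])) next
        bl <- y + k * layout$line_height - 3
        pdf_text_run(doc, page, col_x[j], bl, lines[k], layout$font_size)
      }
      if (sup[r, j] != "") {
        bl <- y + layout$line_height - 3
        x_end <- col_x[j] + nchar(lines[1]) * char_w + 1
        pdf_text_run(doc, page, x_end, bl - 3, sup[r, j],
                     layout$font_size * 0.625)
      }
      cell_boxes[[j]] <- bbox(col_x[j] - 2, y, col_x[j] + widths[j] * char_w + 2,
                              y + row_h)
    }
    if (layout$line_numbers) {
      for (k in seq_len(n_lines)) {
        line_no <- line_no + 1L
        pdf_text_run(doc, page, 36, y + k * layout$line_height - 3,
                     as.character(line_no), layout$font_size)
      }
    }
    rec$rows[[length(rec$rows) + 1L]] <- cell_boxes
    rec$row_idx <- c(rec$row_idx, r)
    if (ruled) {
      pdf_line(doc, page, layout$margin_x - 2, y, table_x1 + 2, y)
    }
    y <- y + row_h
    if (ruled && r == nrow(base)) {
      pdf_line(doc, page, layout$margin_x - 2, y, table_x1 + 2, y)
    }
  }
  flush_page()

  gold_pages <- lapply(pages, function(pg) {
    if (!length(pg$rows)) return(list(table_boxes = list(), structures = list()))
    row_boxes <- lapply(pg$rows, function(cb) {
      bbox(min(vapply(cb, function(b) b[["xmin"]], numeric(1))),
           min(vapply(cb, function(b) b[["ymin"]], numeric(1))),
           max(vapply(cb, function(b) b[["xmax"]], numeric(1))),
           max(vapply(cb, function(b) b[["ymax"]], numeric(1))))
    })
    y0 <- min(vapply(row_boxes, function(b) b[["ymin"]], numeric(1)))
    y1 <- max(vapply(row_boxes, function(b) b[["ymax"]], numeric(1)))
    col_boxes <- lapply(seq_along(widths), function(j) {
      bbox(col_x[j] - 2, y0, col_x[j] + widths[j] * char_w + 2, y1)
    })
    tb <- bbox(min(col_x) - 2, y0, table_x1 + 2, y1)
    if (ruled) {
      # draw column separators now that the page extent is known
      NULL
    }
    list(table_boxes = list(tb),
         structures = list(list(col_boxes = col_boxes, row_boxes = row_boxes,
                                cell_boxes = unlist(pg$rows, recursive = FALSE),
                                row_idx = pg$row_idx)))
  })
  # vertical rules need the per-page y extents, so draw them in a second pass
  if (ruled) {
    for (p in seq_along(gold_pages)) {
      gp <- gold_pages[[p]]
      if (!length(gp$table_boxes)) next
      tb <- gp$table_boxes[[1]]
      xs <- c(layout$margin_x - 2,
              col_x[-1] - layout$col_gap / 2,
              table_x1 + 2)
      for (x in xs) pdf_line(doc, p, x, tb[["ymin"]], x, tb[["ymax"]])
    }
  }
  list(pdf = pdf_bytes(doc),
       gold = list(pages = gold_pages,
                   page_size = c(layout$page_width, layout$page_height),
                   grid = grid),
       n_pages = length(doc$pages))
}

prose_vocab <- c("the", "of", "and", "in", "to", "a", "is", "was", "for",
                 "with", "that", "were", "as", "by", "on", "we", "this",
                 "cells", "protein", "expression", "analysis", "mice",
                 "signal", "figure", "data", "results", "observed", "using",
                 "method", "staining", "imaging", "cortex", "neurons")

#' Render a multi-page fixture document: prose pages around table pages
#'
#' @param seed Integer seed.
#' @param tables List of [generate_resource_table()] grids, each starting on
#'   a fresh page.
#' @param n_prose_before,n_prose_after Number of prose-only pages.
#' @param layout A [render_layout()].
#' @return As [render_to_pdf()], with `gold$table_pages` giving the page
#'   index where each table starts.
#' @export
render_fixture_document <- function(seed, tables, n_prose_before = 1,
                                    n_prose_after = 1,
                                    layout = render_layout()) {
  # render each table separately, then splice pages together
  rendered <- lapply(tables, render_to_pdf, layout = layout)
  doc <- pdf_new()
  gold_pages <- list()
  add_prose_page <- function(stream) {
    p <- pdf_add_page(doc, layout$page_width, layout$page_height)
    with_seed(derive_seed(seed, stream), {
      nl <- sample(22:30, 1)
      for (k in seq_len(nl)) {
        words <- sample(prose_vocab, sample(6:10, 1), replace = TRUE)
        pdf_text_run(doc, p, layout$margin_x, layout$margin_top + k * 12,
                     paste(words, collapse = " "), 9)
      }
    })
    gold_pages[[p]] <<- list(table_boxes = list(), structures = list())
    p
  }
  for (i in seq_len(n_prose_before)) add_prose_page(100L + i)
  table_pages <- integer(0)
  for (ti in seq_along(rendered)) {
    rd <- rendered[[ti]]
    start <- length(doc$pages) + 1L
    table_pages <- c(table_pages, start)
    src <- extract_doc_pages(rd)
    for (p in seq_along(src$ops)) {
      np <- pdf_add_page(doc, layout$page_width, layout$page_height)
      doc$pages[[np]]$ops <- src$ops[[p]]
      gold_pages[[np]] <- rd$gold$pages[[p]]
    }
  }
  for (i in seq_len(n_prose_after)) add_prose_page(200L + i)
  list(pdf = pdf_bytes(doc),
       gold = list(pages = gold_pages,
                   page_size = c(layout$page_width, layout$page_height),
                   grids = lapply(tables, identity),
                   table_pages = table_pages),
       n_pages = length(doc$pages))
}

# recover a rendered table's per-page drawing ops for splicing into a
# larger document
extract_doc_pages <- function(rendered) {
  txt <- rawToChar(rendered$pdf)
  objs <- parse_pdf_objects(txt)
  pg <- find_page_objects(objs)
  list(ops = lapply(pg, function(p) strsplit(p$content, "\n")[[1]]))
}
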