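# Minimal born-digital PDF writer.
#
# Emits uncompressed PDF 1.4 with Courier (the sole font), absolute text
# positioning via Tm, and stroked line paths.  The public API speaks the
# package's page convention -- points, origin top-left, y downward -- and the
# writer flips to PDF's bottom-left origin internally.  Courier is metrically
# trivial (every glyph advances 0.6 em), which is what lets the fixture
# renderer compute exact gold character boxes.

COURIER_WIDTH <- 0.6    # glyph advance, fraction of font size
COURIER_ASCENT <- 0.629
COURIER_DESCENT <- 0.157

#' Create an empty in-memory PDF document
#' @return An environment of class `pdf_doc`.
#' @export
pdf_new <- function() {
  doc <- new.env(parent = emptyenv())
  doc$pages <- list()
  class(doc) <- "pdf_doc"
  doc
}

#' Append a page to a [pdf_new()] document
#' @param doc A `pdf_doc`.
#' @param width,height Page size in points.
#' @return The 1-based page index, invisibly used by the drawing functions.
#' @export
pdf_add_page <- function(doc, width = 612, height = 792) {
  doc$pages[[length(doc$pages) + 1L]] <- list(width = width, height = height,
                                              ops = character(0))
  length(doc$pages)
}

pdf_escape_string <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("(", "\\(", s, fixed = TRUE)
  gsub(")", "\\)", s, fixed = TRUE)
}

#' Draw a text run at a baseline position
#'
#' @param doc A `pdf_doc`.
#' @param page Page index from [pdf_add_page()].
#' @param x Left edge of the first glyph, points.
#' @param y Baseline position in top-down page coordinates.
#' @param text ASCII string (Courier).
#' @param size Font size in points.
#' @export
pdf_text_run <- function(doc, page, x, y, text, size = 8) {
  h <- doc$pages[[page]]$height
  op <- sprintf("BT /F1 %s Tf 1 0 0 1 %s %s Tm (%s) Tj ET",
                fmtnum(size), fmtnum(x), fmtnum(h - y), pdf_escape_string(text))
  doc$pages[[page]]$ops <- c(doc$pages[[page]]$ops, op)
  invisible(doc)
}

#' Stroke a straight line segment
#' @inheritParams pdf_text_run
#' @param x1,y1,x2,y2 Endpoints in top-down page coordinates.
#' @param width Stroke width in points.
#' @export
pdf_line <- function(doc, page, x1, y1, x2, y2, width = 0.5) {
  h <- doc$pages[[page]]$height
  op <- sprintf("%s w %s %s m %s %s l S", fmtnum(width),
                fmtnum(x1), fmtnum(h - y1), fmtnum(x2), fmtnum(h - y2))
  doc$pages[[page]]$ops <- c(doc$pages[[page]]$ops, op)
  invisible(doc)
}

fmtnum <- function(x) {
  s <- formatC(x, format = "f", digits = 3)
  sub("\\.?0+$", "", s)
}

#' Serialize a `pdf_doc` to PDF bytes
#' @param doc A `pdf_doc`.
#' @return Raw vector holding the complete PDF file.
#' @export
pdf_bytes <- function(doc) {
  np <- length(doc$pages)
  # object numbering: 1 catalog, 2 pages, 3 font, then per page (page obj,
  # content obj) pairs
  objs <- character(3 + 2 * np)
  kids <- paste(sprintf("%d 0 R", 3 + 2 * seq_len(np) - 1), collapse = " ")
  objs[1] <- "<< /Type /Catalog /Pages 2 0 R >>"
  objs[2] <- sprintf("<< /Type /Pages /Kids [%s] /Count %d >>", kids, np)
  objs[3] <- "<< /Type /Font /Subtype /Type1 /BaseFont /Courier >>"
  for (p in seq_len(np)) {
    pg <- doc$pages[[p]]
    pobj <- 3 + 2 * p - 1
    cobj <- 3 + 2 * p
    objs[pobj] <- sprintf(paste0(
      "<< /Type /Page /Parent 2 0 R /MediaBox [0 0 %s %s] ",
      "/Resources << /Font << /F1 3 0 R >> >> /Contents %d 0 R >>"),
      fmtnum(pg$width), fmtnum(pg$height), cobj)
    stream <- paste(pg$ops, collapse = "\n")
    objs[cobj] <- sprintf("<< /Length %d >>\nstream\n%s\nendstream",
                          nchar(stream, type = "bytes"), stream)
  }
  header <- "%PDF-1.4\n"
  body <- character(length(objs))
  offsets <- integer(length(objs))
  pos <- nchar(header, type = "bytes")
  for (i in seq_along(objs)) {
    body[i] <- sprintf("%d 0 obj\n%s\nendobj\n", i, objs[i])
    offsets[i] <- pos
    pos <- pos + nchar(body[i], type = "bytes")
  }
  xref_pos <- pos
  xref <- c(sprintf("xref\n0 %d", length(objs) + 1),
            "0000000000 65535 f ",
            sprintf("%010d 00000 n ", offsets))
  trailer <- sprintf("trailer\n<< /Size %d /Root 1 0 R >>\nstartxref\n%d\n%%%%EOF\n",
                     length(objs) + 1, xref_pos)
  txt <- paste0(header, paste(body, collapse = ""),
                paste(xref, collapse = "\n"), "\n", trailer)
  charToRaw(txt)
}
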