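# Reader for born-digital PDFs with uncompressed content streams.
#
# Recovers per-character bounding boxes, primitive horizontal/vertical line
# graphics, and page sizes.  The interpreter covers the operator subset that
# metric-simple PDFs (Courier text positioned with Tm/Td, stroked m/l/re
# paths) use -- which includes everything the package's own renderer emits.
# Compressed streams and embedded fonts are out of scope and raise a
# structured error.

pdf_error <- function(msg) {
  stop(structure(class = c("restable_pdf_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Extract per-character boxes, line graphics and page sizes from a PDF
#'
#' @param pdf Raw vector of PDF bytes, or a file path.
#' @return List of `page_text` objects, one per page, each with `chars`
#'   (data frame: char, xmin, ymin, xmax, ymax, page), `graphics`
#'   ([page_graphics()]), `page_size` `c(width, height)` and `page_index`.
#'   Coordinates are top-left-origin points.  Space glyphs advance the pen
#'   but produce no character box (word spacing is reconstructed from gaps
#'   by [group_text_lines()]).
#' @export
extract_pages <- function(pdf) {
  if (is.character(pdf)) pdf <- readBin(pdf, "raw", file.size(pdf))
  if (!is.raw(pdf)) pdf_error("pdf must be a raw vector or file path")
  txt <- rawToChar(pdf)
  Encoding(txt) <- "latin1"
  if (!startsWith(txt, "%PDF")) pdf_error("not a PDF: missing %PDF header")

  objs <- parse_pdf_objects(txt)
  pages <- find_page_objects(objs)
  lapply(seq_along(pages), function(pi) {
    pg <- pages[[pi]]
    interp_content(pg$content, pg$width, pg$height, pi)
  })
}

# split the file into "N 0 obj ... endobj" chunks, keyed by object number
parse_pdf_objects <- function(txt) {
  starts <- gregexpr("(?m)^(\\d+) 0 obj", txt, perl = TRUE)[[1]]
  if (starts[1] == -1) pdf_error("no objects found")
  lens <- attr(starts, "match.length")
  objs <- list()
  for (i in seq_along(starts)) {
    num <- as.integer(sub(" 0 obj.*", "", substr(txt, starts[i], starts[i] + lens[i])))
    end <- regexpr("endobj", substr(txt, starts[i], nchar(txt)), fixed = TRUE)
    body <- substr(txt, starts[i] + lens[i], starts[i] + end - 2)
    objs[[as.character(num)]] <- body
  }
  objs
}

dict_of <- function(body) {
  # dictionary part before any stream
  sp <- regexpr("stream", body, fixed = TRUE)
  if (sp > 0) substr(body, 1, sp - 1) else body
}

stream_of <- function(body) {
  m <- regexpr("stream\r?\n", body)
  if (m < 0) return(NULL)
  start <- m + attr(m, "match.length")
  e <- regexpr("\r?\nendstream", body)
  if (e < 0) pdf_error("unterminated stream")
  substr(body, start, e - 1)
}

find_page_objects <- function(objs) {
  root <- NULL
  for (b in objs) if (grepl("/Type\\s*/Pages", dict_of(b))) { root <- b; break }
  if (is.null(root)) pdf_error("no /Pages object")
  kids <- regmatches(root, gregexpr("(\\d+) 0 R", root))[[1]]
  kid_ids <- as.integer(sub(" 0 R", "", kids))
  out <- list()
  for (id in kid_ids) {
    b <- objs[[as.character(id)]]
    if (is.null(b) || !grepl("/Type\\s*/Page\\b", dict_of(b))) next
    mb <- regmatches(b, regexpr("/MediaBox\\s*\\[[^]]*\\]", b))
    size <- c(612, 792)
    if (length(mb)) {
      nums <- as.numeric(regmatches(mb, gregexpr("-?[0-9.]+", mb))[[1]])
      size <- c(nums[3] - nums[1], nums[4] - nums[2])
    }
    cref <- regmatches(b, regexpr("/Contents\\s*\\d+ 0 R", b))
    content <- ""
    if (length(cref)) {
      cid <- as.integer(regmatches(cref, regexpr("\\d+", cref)))
      cb <- objs[[as.character(cid)]]
      if (!is.null(cb)) {
        if (grepl("/Filter", dict_of(cb))) {
          pdf_error("compressed content streams are not supported")
        }
        content <- stream_of(cb) %||% ""
      }
    }
    out[[length(out) + 1L]] <- list(width = size[1], height = size[2],
                                    content = content)
  }
  if (!length(out)) pdf_error("no /Page objects")
  out
}

# tokenize a content stream into strings (class marked), arrays brackets and
# plain tokens
tokenize_content <- function(s) {
  n <- nchar(s)
  toks <- vector("list", 256); nt <- 0L
  push <- function(v, str = FALSE) {
    nt <<- nt + 1L
    if (nt > length(toks)) length(toks) <<- 2L * nt
    toks[[nt]] <<- if (str) structure(v, pdfstr = TRUE) else v
  }
  i <- 1L
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch %in% c(" ", "\n", "\r", "\t")) { i <- i + 1L; next }
    if (ch == "(") {
      j <- i + 1L; buf <- character(0)
      while (j <= n) {
        cj <- substr(s, j, j)
        if (cj == "\\") { buf <- c(buf, substr(s, j + 1L, j + 1L)); j <- j + 2L; next }
        if (cj == ")") break
        buf <- c(buf, cj); j <- j + 1L
      }
      push(paste(buf, collapse = ""), str = TRUE)
      i <- j + 1L
      next
    }
    if (ch %in% c("[", "]")) { push(ch); i <- i + 1L; next }
    j <- i
    while (j <= n && !substr(s, j, j) %in% c(" ", "\n", "\r", "\t", "(", "[", "]")) j <- j + 1L
    push(substr(s, i, j - 1L))
    i <- j
  }
  toks[seq_len(nt)]
}

is_pdfstr <- function(tok) isTRUE(attr(tok, "pdfstr"))

num_or_na <- function(tok) {
  if (is_pdfstr(tok)) return(NA_real_)
  suppressWarnings(as.numeric(tok))
}

# run the content stream, collecting character boxes and line segments;
# coordinates converted to top-left origin
interp_content <- function(content, width, height, page_index) {
  toks <- tokenize_content(content)
  size <- 0; tx <- 0; ty <- 0; sx <- 1
  cur <- NULL; segs <- list()
  ch <- character(0); x1 <- numeric(0); y1 <- numeric(0)
  x2 <- numeric(0); y2 <- numeric(0)

  emit_string <- function(str) {
    if (!nchar(str)) return()
    adv <- COURIER_WIDTH * size * sx
    chars <- strsplit(str, "")[[1]]
    for (k in seq_along(chars)) {
      if (chars[k] != " ") {
        ch <<- c(ch, chars[k])
        x1 <<- c(x1, tx + (k - 1) * adv)
        x2 <<- c(x2, tx + k * adv)
        y1 <<- c(y1, height - ty - COURIER_ASCENT * size)
        y2 <<- c(y2, height - ty + COURIER_DESCENT * size)
      }
    }
    tx <<- tx + length(chars) * adv
  }

  i <- 1L; stack <- list()
  while (i <= length(toks)) {
    tok <- toks[[i]]
    if (is_pdfstr(tok) || tok %in% c("[", "]") || !is.na(num_or_na(tok)) ||
        startsWith(as.character(tok), "/")) {
      stack[[length(stack) + 1L]] <- tok
      i <- i + 1L
      next
    }
    op <- as.character(tok)
    nums <- vapply(stack, num_or_na, numeric(1))
    if (op == "Tf" && length(nums) >= 1) {
      size <- nums[length(nums)]
    } else if (op == "Tm" && length(nums) >= 6) {
      v <- utils::tail(nums[!is.na(nums)], 6)
      sx <- v[1]; tx <- v[5]; ty <- v[6]
    } else if (op %in% c("Td", "TD") && length(nums) >= 2) {
      v <- utils::tail(nums[!is.na(nums)], 2)
      tx <- tx + v[1]; ty <- ty + v[2]
    } else if (op == "Tj") {
      strs <- Filter(is_pdfstr, stack)
      if (length(strs)) emit_string(as.character(strs[[length(strs)]]))
    } else if (op == "TJ") {
      for (el in stack) {
        if (is_pdfstr(el)) emit_string(as.character(el))
        else {
          v <- num_or_na(el)
          if (!is.na(v)) tx <- tx - v / 1000 * size * sx
        }
      }
    } else if (op == "m" && length(nums) >= 2) {
      v <- utils::tail(nums[!is.na(nums)], 2)
      cur <- v
    } else if (op == "l" && length(nums) >= 2) {
      v <- utils::tail(nums[!is.na(nums)], 2)
      if (!is.null(cur)) segs[[length(segs) + 1L]] <- c(cur, v)
      cur <- v
    } else if (op == "re" && length(nums) >= 4) {
      v <- utils::tail(nums[!is.na(nums)], 4)
      xs <- v[1]; ys <- v[2]; w <- v[3]; h <- v[4]
      segs <- c(segs, list(c(xs, ys, xs + w, ys), c(xs + w, ys, xs + w, ys + h),
                           c(xs + w, ys + h, xs, ys + h), c(xs, ys + h, xs, ys)))
    }
    stack <- list()
    i <- i + 1L
  }

  hl <- list(); vl <- list()
  for (sg in segs) {
    ya <- height - sg[2]; yb <- height - sg[4]
    if (sg[2] == sg[4]) {
      hl[[length(hl) + 1L]] <- c(min(sg[1], sg[3]), ya, max(sg[1], sg[3]), ya)
    } else if (sg[1] == sg[3]) {
      vl[[length(vl) + 1L]] <- c(sg[1], min(ya, yb), sg[1], max(ya, yb))
    }
  }
  to_df <- function(lst) {
    if (!length(lst)) return(data.frame(xmin = numeric(0), ymin = numeric(0),
                                        xmax = numeric(0), ymax = numeric(0)))
    m <- do.call(rbind, lst)
    data.frame(xmin = m[, 1], ymin = m[, 2], xmax = m[, 3], ymax = m[, 4])
  }
  chars <- chars_df(ch, x1, y1, x2, y2, page_index)
  chars <- dedupe_chars(chars)
  # clamp boxes to the page
  if (nrow(chars)) {
    chars$xmin <- pmax(0, chars$xmin); chars$ymin <- pmax(0, chars$ymin)
    chars$xmax <- pmin(width, chars$xmax); chars$ymax <- pmin(height, chars$ymax)
  }
  structure(list(chars = chars,
                 graphics = page_graphics(to_df(hl), to_df(vl)),
                 page_size = c(width = width, height = height),
                 page_index = page_index),
            class = "page_text")
}

#' @export
print.page_text <- function(x, ...) {
  cat(sprintf("<page_text p%d: %d chars, %d hlines, %d vlines, %gx%g pt>\n",
              x$page_index, nrow(x$chars), nrow(x$graphics$hlines),
              nrow(x$graphics$vlines), x$page_size[1], x$page_size[2]))
  invisible(x)
}

# drop duplicate glyphs some extractors emit twice (same char, IoU > 0.8)
dedupe_chars <- function(chars, iou_thresh = 0.8) {
  if (nrow(chars) < 2) return(chars)
  key <- paste(chars$char, round(chars$xmin, 1), round(chars$ymin, 1))
  dup <- duplicated(key)
  if (!any(dup)) return(chars)
  keep <- !dup
  # confirm near-duplicates really overlap before dropping
  for (i in which(dup)) {
    j <- match(key[i], key)
    a <- bbox(chars$xmin[i], chars$ymin[i], chars$xmax[i], chars$ymax[i])
    b <- bbox(chars$xmin[j], chars$ymin[j], chars$xmax[j], chars$ymax[j])
    if (iou(a, b) <= iou_thresh) keep[i] <- TRUE
  }
  out <- chars[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group character boxes into text lines
#'
#' Characters are first bucketed into raw lines by their top y coordinate
#' (within `y_tol`), then each raw line is cut at horizontal gaps wider than
#' `gap_tol` average character widths.  Within a line, a single space is
#' inserted between consecutive characters whose gap exceeds
#' `space_frac` of the average character width.  Superscript and subscript
#' glyphs have different top y than their baseline and therefore surface as
#' spurious one-glyph lines here; the canonicalization step repairs them
#' later.
#'
#' @param chars Character data frame (see [extract_pages()]) or list of
#'   [char_box()].
#' @param y_tol Top-y tolerance in points for two characters to share a raw
#'   line.
#' @param gap_tol Gap threshold, in multiples of the average character width,
#'   beyond which a raw line is split into separate text lines.
#' @param space_frac Gap threshold, same units, beyond which a space is
#'   inserted in the line text.
#' @return List of `text_line` objects: `chars`, `text`, `x_range`,
#'   `y_range`.
#' @export
group_text_lines <- function(chars, y_tol = 1.0, gap_tol = 3.0, space_frac = 0.25) {
  chars <- as_chars_df(chars)
  if (nrow(chars) == 0) return(list())
  ord <- order(chars$ymin, chars$xmin)
  chars <- chars[ord, , drop = FALSE]
  line_id <- cumsum(c(1, diff(chars$ymin) > y_tol))
  out <- list()
  for (lid in unique(line_id)) {
    raw <- chars[line_id == lid, , drop = FALSE]
    raw <- raw[order(raw$xmin), , drop = FALSE]
    avg_w <- mean(raw$xmax - raw$xmin)
    if (!is.finite(avg_w) || avg_w <= 0) avg_w <- 1
    gaps <- if (nrow(raw) > 1) raw$xmin[-1] - raw$xmax[-nrow(raw)] else numeric(0)
    seg_id <- cumsum(c(1, gaps > gap_tol * avg_w))
    for (sid in unique(seg_id)) {
      seg <- raw[seg_id == sid, , drop = FALSE]
      sgaps <- if (nrow(seg) > 1) seg$xmin[-1] - seg$xmax[-nrow(seg)] else numeric(0)
      glue <- c("", ifelse(sgaps > space_frac * avg_w, " ", ""))
      text <- paste0(paste0(glue, seg$char), collapse = "")
      out[[length(out) + 1L]] <- structure(list(
        chars = seg,
        text = text,
        x_range = interval(min(seg$xmin), max(seg$xmax)),
        y_range = interval(min(seg$ymin), max(seg$ymax))
      ), class = "text_line")
    }
  }
  # top-to-bottom, then left-to-right reading order
  ord <- order(vapply(out, function(l) l$y_range[["lo"]], numeric(1)),
               vapply(out, function(l) l$x_range[["lo"]], numeric(1)))
  out[ord]
}

#' @export
print.text_line <- function(x, ...) {
  cat(sprintf("<text_line y=[%.1f,%.1f] %s>\n", x$y_range[["lo"]],
              x$y_range[["hi"]], x$text))
  invisible(x)
}
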