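# Pipeline C support: rasterizing detected cell regions and reading them
# back through an OCR engine contract.
#
# The engine contract is `function(image, mode = "single_block") -> string`.
# The default binding probes the PATH for a Tesseract executable; when none
# is available a structured error directs callers to pipelines A/B/D.  For
# testing without any OCR installation the package carries a synthetic
# monospaced raster font (glyph patterns derived from code points, not real
# typography) plus a template-matching mock engine that reads it back --
# enough to exercise the full image pipeline, including its preprocessing.

GLYPH_ROWS <- 8L
GLYPH_COLS <- 6L   # drawing pitch; only columns 1 (marker) and 2 (data) ink

# Bit matrix of a synthetic glyph.  Column 1: solid full-height marker bar
# (the only full-height column, so segmentation is unambiguous).  Column 2:
# the 7-bit ASCII code over rows 1-7, top bit first; row 8 stays blank so a
# data column can never masquerade as a marker.  Remaining columns blank.
glyph_bitmap <- function(char) {
  cp <- utf8ToInt(char) %% 128L
  m <- matrix(0L, GLYPH_ROWS, GLYPH_COLS)
  m[, 1] <- 1L
  m[1:7, 2] <- as.integer(intToBits(cp))[7:1]
  m
}

#' Rasterize a page region to a grayscale image
#'
#' Draws every character whose box center falls inside `box` using the
#' package's synthetic raster font, at `dpi` dots per inch with a margin.
#' White is 255, ink 0.
#'
#' @param page A `page_text` (see [extract_pages()]).
#' @param box Page-coordinate [bbox()] to crop.
#' @param dpi Raster resolution.
#' @param margin Margin around the crop, points.
#' @return Integer matrix (rows = pixels top-down).
#' @export
rasterize_region <- function(page, box, dpi = 300, margin = 2) {
  s <- dpi / 72
  x0 <- box[["xmin"]] - margin; y0 <- box[["ymin"]] - margin
  W <- max(1L, ceiling((box[["xmax"]] - box[["xmin"]] + 2 * margin) * s))
  H <- max(1L, ceiling((box[["ymax"]] - box[["ymin"]] + 2 * margin) * s))
  img <- matrix(255L, H, W)
  ch <- page$chars
  if (!nrow(ch)) return(img)
  xc <- (ch$xmin + ch$xmax) / 2; ycn <- (ch$ymin + ch$ymax) / 2
  keep <- xc >= box[["xmin"]] & xc <= box[["xmax"]] &
    ycn >= box[["ymin"]] & ycn <= box[["ymax"]]
  ch <- ch[keep, , drop = FALSE]
  for (i in seq_len(nrow(ch))) {
    bm <- glyph_bitmap(ch$char[i])
    # glyph drawn inside the character box with one glyph-pixel of spacing
    gw <- (ch$xmax[i] - ch$xmin[i]) / (GLYPH_COLS + 2)
    gh <- (ch$ymax[i] - ch$ymin[i]) / (GLYPH_ROWS + 1)
    for (gr in seq_len(GLYPH_ROWS)) {
      for (gc in seq_len(GLYPH_COLS)) {
        if (!bm[gr, gc]) next
        px0 <- floor((ch$xmin[i] + (gc - 1) * gw - x0) * s) + 1
        px1 <- ceiling((ch$xmin[i] + gc * gw - x0) * s)
        py0 <- floor((ch$ymin[i] + (gr - 1) * gh - y0) * s) + 1
        py1 <- ceiling((ch$ymin[i] + gr * gh - y0) * s)
        px0 <- max(1, px0); py0 <- max(1, py0)
        px1 <- min(W, px1); py1 <- min(H, py1)
        if (px0 <= px1 && py0 <= py1) img[py0:py1, px0:px1] <- 0L
      }
    }
  }
  img
}

#' Preprocess a cell image for OCR: grayscale + percentile contrast stretch
#'
#' Multi-channel images are averaged to one channel; intensities are then
#' linearly stretched so the 2nd/98th percentiles map to 0/255.  A constant
#' image is returned unchanged (degenerate stretch).
#'
#' @param img Numeric matrix, or 3-d array with channels in the third
#'   dimension.
#' @param lower,upper Stretch percentiles.
#' @return Numeric matrix in `[0, 255]`.
#' @export
preprocess_cell_image <- function(img, lower = 0.02, upper = 0.98) {
  if (length(img) == 0) stop("zero-size image")
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  q <- stats::quantile(img, c(lower, upper), names = FALSE)
  if (q[2] <= q[1]) return(img)
  out <- (img - q[1]) / (q[2] - q[1]) * 255
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

ocr_error <- function(msg) {
  stop(structure(class = c("restable_ocr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Mock OCR engine reading the synthetic raster font
#'
#' Template-free decoding of [rasterize_region()] output: ink bands are text
#' lines; within a band, full-height marker bars segment glyphs and the bit
#' column after each marker is read back into a code point.  `noise`
#' emulates the corruption real OCR engines show on long uninterrupted
#' tokens (sequences, URLs): with probability `noise` per long token, a
#' chunk of its characters is replaced by a space.
#'
#' @param noise Corruption probability per long (>12 char) token.
#' @param seed Seed for the corruption stream.
#' @return An engine `function(image, mode = "single_block") -> string`.
#' @export
mock_ocr_engine <- function(noise = 0, seed = 1L) {
  counter <- 0L
  function(image, mode = "single_block") {
    ink <- image < 128
    if (!any(ink)) return("")
    band_rows <- which(rowSums(ink) > 0)
    bands <- split(band_rows, cumsum(c(1, diff(band_rows) > 1)))
    out_lines <- character(0)
    for (b in bands) {
      sub <- ink[b, , drop = FALSE]
      h <- nrow(sub)
      colink <- colSums(sub)
      # marker bars: contiguous column runs with near-full band height
      is_marker <- colink >= 0.9 * h
      runs <- rle(is_marker)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1
      mstart <- starts[runs$values]
      mend <- ends[runs$values]
      if (!length(mstart)) next
      unit_y <- h / GLYPH_ROWS
      chars <- character(length(mstart))
      for (k in seq_along(mstart)) {
        mw <- mend[k] - mstart[k] + 1L
        # data column sits directly right of the marker; everything further
        # right until the next marker is blank by construction
        xs <- (mend[k] + 1L):min(ncol(sub), mend[k] + max(2L, mw))
        bits <- integer(7L)
        for (r in 1:7) {
          yc <- (r - 0.5) * unit_y  # sample the unit center, clear of smear
          ys <- max(1, floor(yc)):min(h, ceiling(yc))
          bits[r] <- as.integer(mean(sub[ys, xs, drop = FALSE]) > 0.3)
        }
        cp <- sum(bits * 2^(6:0))
        chars[k] <- if (cp >= 32 && cp < 128) intToUtf8(cp) else "?"
      }
      # spaces: gaps between consecutive markers much wider than the pitch
      if (length(mstart) > 1) {
        gaps <- diff(mstart)
        pitch <- min(gaps)
        glue <- ifelse(gaps > 1.6 * pitch, " ", "")
        line <- paste0(chars[1], paste0(glue, chars[-1], collapse = ""))
      } else line <- chars[1]
      out_lines <- c(out_lines, line)
    }
    text <- paste(out_lines, collapse = "\n")
    if (noise > 0) {
      counter <<- counter + 1L
      text <- with_seed(derive_seed(seed, counter), corrupt_long_tokens(text, noise))
    }
    text
  }
}

# drop a chunk out of long tokens with the given probability (the
# long-sequence failure mode of real OCR)
corrupt_long_tokens <- function(text, prob) {
  toks <- strsplit(text, " ", fixed = TRUE)[[1]]
  for (i in seq_along(toks)) {
    n <- nchar(toks[i])
    if (n > 12 && stats::runif(1) < prob) {
      cut0 <- sample.int(n - 6, 1)
      cut1 <- min(n, cut0 + sample(3:(max(4, n %/% 3)), 1))
      toks[i] <- paste0(substr(toks[i], 1, cut0), " ",
                        substr(toks[i], cut1 + 1, n))
    }
  }
  paste(toks, collapse = " ")
}

#' Default OCR engine: Tesseract binding when the executable exists
#'
#' @param exe Path to the Tesseract executable (located on the PATH by
#'   default).
#' @return An engine function; calling it without a Tesseract installation
#'   raises a structured error (class `restable_ocr_error`) advising
#'   pipelines A/B/D.
#' @export
default_ocr_engine <- function(exe = Sys.which("tesseract")) {
  if (!nzchar(exe)) {
    return(function(image, mode = "single_block") {
      ocr_error(paste("no OCR engine available (tesseract not on PATH);",
                      "use pipelines A, B or D, or supply an engine"))
    })
  }
  function(image, mode = "single_block") {
    tmp <- tempfile(fileext = ".pgm")
    on.exit(unlink(c(tmp, paste0(tmp, ".txt"))), add = TRUE)
    write_pgm(image, tmp)
    # psm 6: assume a single uniform block of text
    psm <- if (mode == "single_block") "6" else "3"
    out <- tempfile()
    system2(exe, c(tmp, out, "--psm", psm), stdout = FALSE, stderr = FALSE)
    txt <- tryCatch(readLines(paste0(out, ".txt"), warn = FALSE),
                    error = function(e) "")
    unlink(paste0(out, ".txt"))
    paste(txt, collapse = "\n")
  }
}

write_pgm <- function(img, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(img), nrow(img)), "255"), con)
  writeBin(as.raw(as.integer(t(img))), con)
}

#' Read one cell image through an OCR engine
#'
#' Invokes the engine in single-block segmentation mode and strips trailing
#' whitespace.  Newlines inside the block are collapsed to single spaces
#' (cell content is one logical string).
#'
#' @param img Preprocessed image matrix.
#' @param engine An engine function (see [mock_ocr_engine()],
#'   [default_ocr_engine()]); `NULL` uses the default binding.
#' @return The recognized text.
#' @export
ocr_cell <- function(img, engine = NULL) {
  if (is.null(engine)) engine <- default_ocr_engine()
  txt <- engine(img, mode = "single_block")
  txt <- gsub("\n", " ", txt, fixed = TRUE)
  sub("[[:space:]]+$", "", txt)
}
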