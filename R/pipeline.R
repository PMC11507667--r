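#' Run a table-reconstruction pipeline over a PDF document
#'
#' Shared front end: candidate pages (all non-empty pages unless page
#' detection models are supplied) are passed to the table detector; each
#' detected table's structure detections are rescaled to page coordinates
#' and reduced to a column layout.  The variants then differ in how rows
#' are formed:
#'
#' * `A`: column ranges + text-line rows from the PDF + heuristic row merge
#'   (over-segments rows whose cells overflow).
#' * `B`: column ranges + TSR row ranges.
#' * `C`: pipeline B topology with cell contents read by OCR from the page
#'   raster.
#' * `D`: pipeline A's grid repaired by the learned cell-merge classifier.
#'
#' Tables on consecutive candidate pages with equal column counts are
#' naively concatenated (multi-page continuation) and flagged.
#'
#' @param pdf Raw PDF bytes or file path.
#' @param variant `"A"`, `"B"`, `"C"` or `"D"`.
#' @param detector A detector honouring the [detect_tables()] /
#'   [detect_structure()] contract (e.g. [mock_detector()]).
#' @param merge_classifier Required for `D`: a
#'   [finetune_merge_classifier()] model.
#' @param ocr_engine Required for `C`: an OCR engine function.
#' @param line_model,page_model Optional page-detection models; when absent
#'   every page with text is a candidate.
#' @param protect_header Passed to [merge_rows()] for variant `D`.
#' @return List of [table_grid()]s (possibly empty); stitched grids carry
#'   attribute `stitched = TRUE`.
#' @export
run_pipeline <- function(pdf, variant = c("A", "B", "C", "D"), detector,
                         merge_classifier = NULL, ocr_engine = NULL,
                         line_model = NULL, page_model = NULL,
                         protect_header = TRUE) {
  variant <- match.arg(variant)
  if (variant == "D" && is.null(merge_classifier)) {
    stop("pipeline D requires a merge_classifier")
  }
  if (variant == "C" && is.null(ocr_engine)) {
    stop("pipeline C requires an ocr_engine")
  }
  pages <- extract_pages(pdf)
  if (!length(pages)) return(list())
  cand <- if (!is.null(line_model) && !is.null(page_model)) {
    detect_candidate_pages(pages, line_model, page_model)
  } else {
    which(vapply(pages, function(p) nrow(p$chars) > 0, logical(1)))
  }
  found <- list()  # entries: list(page, grid)
  for (p in cand) {
    pg <- pages[[p]]
    tdet <- detect_tables(detector, p)
    if (!length(tdet)) next
    isz <- attr(tdet, "image_size")
    tregs <- scale_to_page(tdet, isz, pg$page_size)
    tregs <- tregs[order(vapply(tregs, function(r) r$box[["ymin"]], numeric(1)))]
    for (treg in tregs) {
      g <- tryCatch(
        reconstruct_table(pg, p, treg$box, variant, detector,
                          merge_classifier, ocr_engine, protect_header),
        error = function(e) NULL)
      if (!is.null(g)) found[[length(found) + 1L]] <- list(page = p, grid = g)
    }
  }
  stitch_tables(found)
}

reconstruct_table <- function(pg, page_index, table_box, variant, detector,
                              merge_classifier, ocr_engine, protect_header) {
  sdet <- detect_structure(detector, page_index, table_box)
  isz <- attr(sdet, "image_size")
  sregs <- scale_to_page(sdet, isz, pg$page_size)
  cells <- Filter(function(r) r$kind == "cell", sregs)
  row_regs <- Filter(function(r) r$kind == "row", sregs)
  if (!length(cells)) return(NULL)
  rows_g <- group_cells_into_rows(cells)
  n_cols <- estimate_column_count(rows_g)
  in_box <- with(pg$chars, (xmin + xmax) / 2 >= table_box[["xmin"]] &
                   (xmin + xmax) / 2 <= table_box[["xmax"]] &
                   (ymin + ymax) / 2 >= table_box[["ymin"]] &
                   (ymin + ymax) / 2 <= table_box[["ymax"]])
  avg_w <- if (any(in_box)) {
    mean(pg$chars$xmax[in_box] - pg$chars$xmin[in_box])
  } else 4.8
  columns <- estimate_column_ranges(rows_g, n_cols, avg_w)

  if (variant %in% c("A", "D")) {
    tls <- group_text_lines(pg$chars[in_box, , drop = FALSE])
    rowr <- estimate_row_ranges("pdf_lines", text_lines = tls)
    grid <- extract_grid(pg$chars, table_box, columns, rowr)
    if (variant == "A") {
      heuristic_row_merge(grid, rowr)
    } else {
      merge_rows(merge_classifier, grid, protect_header = protect_header)
    }
  } else {
    rowr <- estimate_row_ranges("tsr_rows", rows = row_regs)
    if (!length(rowr)) return(NULL)
    if (variant == "B") {
      extract_grid(pg$chars, table_box, columns, rowr)
    } else {
      ocr_grid(pg, columns, rowr, ocr_engine)
    }
  }
}

ocr_grid <- function(pg, columns, rowr, engine) {
  R <- length(rowr); C <- columns$n_cols
  cells <- matrix("", R, C)
  for (r in seq_len(R)) {
    for (j in seq_len(C)) {
      cr <- columns$ranges[[j]]
      box <- bbox(cr[["lo"]], rowr[[r]][["lo"]], cr[["hi"]], rowr[[r]][["hi"]])
      img <- rasterize_region(pg, box)
      cells[r, j] <- ocr_cell(preprocess_cell_image(img), engine)
    }
  }
  table_grid(cells)
}

# naive multi-page continuation: consecutive candidate pages whose adjacent
# tables share a column count are concatenated and flagged
stitch_tables <- function(found) {
  if (!length(found)) return(list())
  out <- list()
  i <- 1L
  while (i <= length(found)) {
    cur <- found[[i]]
    stitched <- FALSE
    while (i < length(found) &&
           found[[i + 1L]]$page == found[[i]]$page + 1L &&
           ncol(found[[i + 1L]]$grid$cells) == ncol(cur$grid$cells)) {
      cur <- list(page = found[[i + 1L]]$page,
                  grid = table_grid(rbind(cur$grid$cells,
                                          found[[i + 1L]]$grid$cells)))
      stitched <- TRUE
      i <- i + 1L
    }
    g <- cur$grid
    if (stitched) attr(g, "stitched") <- TRUE
    out[[length(out) + 1L]] <- g
    i <- i + 1L
  }
  out
}
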