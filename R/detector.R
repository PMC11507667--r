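#' A detector-produced region
#'
#' @param box A [bbox()] in image or page coordinates.
#' @param kind One of `"table"`, `"cell"`, `"row"`, `"column"`.
#' @param score Confidence in `[0, 1]`.
#' @return Object of class `detected_region`.
#' @export
detected_region <- function(box, kind = c("table", "cell", "row", "column"),
                            score = 1.0) {
  kind <- match.arg(kind)
  if (score < 0 || score > 1) stop("score must be in [0, 1]")
  structure(list(box = box, kind = kind, score = score),
            class = "detected_region")
}

#' @export
print.detected_region <- function(x, ...) {
  cat(sprintf("<detected_region %s score %.2f (%.1f,%.1f)-(%.1f,%.1f)>\n",
              x$kind, x$score, x$box[["xmin"]], x$box[["ymin"]],
              x$box[["xmax"]], x$box[["ymax"]]))
  invisible(x)
}

#' Rescale detections from image coordinates to page coordinates
#'
#' Object-detection models see a scaled raster of the page; their boxes are
#' mapped back by the per-axis page/image ratio.
#'
#' @param regions List of [detected_region()]s.
#' @param image_size `c(width, height)` of the raster, pixels.
#' @param page_size `c(width, height)` of the page, points.
#' @return List of rescaled [detected_region()]s.
#' @export
scale_to_page <- function(regions, image_size, page_size) {
  if (any(image_size <= 0)) stop("image dimensions must be positive")
  fx <- page_size[1] / image_size[1]
  fy <- page_size[2] / image_size[2]
  lapply(regions, function(r) {
    detected_region(bbox(r$box[["xmin"]] * fx, r$box[["ymin"]] * fy,
                         r$box[["xmax"]] * fx, r$box[["ymax"]] * fy),
                    r$kind, r$score)
  })
}

#' Read / write detector regions as JSON (the detector plugin exchange
#' format: a list of `{box: [xmin,ymin,xmax,ymax], kind, score}`)
#' @param regions List of [detected_region()]s.
#' @param path JSON file path.
#' @export
write_regions_json <- function(regions, path) {
  jsonlite::write_json(lapply(regions, function(r) {
    list(box = as.numeric(r$box), kind = r$kind, score = r$score)
  }), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_regions_json
#' @return For `read_regions_json`, a list of [detected_region()]s.
#' @export
read_regions_json <- function(path) {
  lapply(jsonlite::read_json(path), function(o) {
    b <- as.numeric(unlist(o$box))
    detected_region(bbox(b[1], b[2], b[3], b[4]), o$kind, o$score %||% 1.0)
  })
}

#' Geometry-driven mock table detector
#'
#' Implements the same contract as an image-level table detection (TD) +
#' table structure recognition (TSR) adapter, but answers from the gold
#' region boxes a fixture render recorded, optionally jittered.  Detections
#' are reported in image coordinates at `image_scale` pixels per point, so
#' the downstream [scale_to_page()] path is exercised.
#'
#' @param gold The `gold` component of [render_to_pdf()] output (per-page
#'   region boxes).
#' @param jitter Standard deviation, in points, of seeded Gaussian noise
#'   added to every box edge.
#' @param image_scale Pixels per point of the simulated page raster.
#' @param seed Seed for the jitter stream.
#' @return Object of class `mock_detector` with elements used by
#'   [detect_tables()] / [detect_structure()].
#' @export
mock_detector <- function(gold, jitter = 0, image_scale = 2, seed = 1L) {
  structure(list(gold = gold, jitter = jitter, image_scale = image_scale,
                 seed = seed), class = "mock_detector")
}

mock_jitter_box <- function(det, box, stream) {
  if (det$jitter <= 0) return(box)
  e <- with_seed(derive_seed(det$seed, stream), stats::rnorm(4, sd = det$jitter))
  bbox(min(box[["xmin"]] + e[1], box[["xmax"]]), min(box[["ymin"]] + e[2], box[["ymax"]]),
       max(box[["xmax"]] + e[3], box[["xmin"]]), max(box[["ymax"]] + e[4], box[["ymin"]]))
}

scale_box <- function(box, f) bbox(box[["xmin"]] * f, box[["ymin"]] * f,
                                   box[["xmax"]] * f, box[["ymax"]] * f)

#' Detect table regions on a page (mock adapter)
#' @param detector A [mock_detector()].
#' @param page_index 1-based page number.
#' @return List of `"table"` [detected_region()]s in image coordinates, plus
#'   attribute `"image_size"` in pixels.
#' @export
detect_tables <- function(detector, page_index) {
  pg <- detector$gold$pages[[page_index]]
  out <- list()
  if (!is.null(pg) && length(pg$table_boxes)) {
    for (i in seq_along(pg$table_boxes)) {
      b <- mock_jitter_box(detector, pg$table_boxes[[i]], page_index * 101L + i)
      out[[i]] <- detected_region(scale_box(b, detector$image_scale), "table", 0.95)
    }
  }
  attr(out, "image_size") <- detector$gold$page_size * detector$image_scale
  out
}

#' Detect table structure (columns, rows, cells) inside a table region
#' @param detector A [mock_detector()].
#' @param page_index 1-based page number.
#' @param table_box Page-coordinate [bbox()] of the table (used to pick the
#'   gold table with the best overlap).
#' @return List of [detected_region()]s (`column`, `row`, `cell`) in image
#'   coordinates; attribute `"image_size"` as in [detect_tables()].
#' @export
detect_structure <- function(detector, page_index, table_box) {
  pg <- detector$gold$pages[[page_index]]
  out <- list()
  if (!is.null(pg) && length(pg$table_boxes)) {
    ious <- vapply(pg$table_boxes, function(b) iou(b, table_box), numeric(1))
    ti <- which.max(ious)
    str <- pg$structures[[ti]]
    k <- 0L
    add <- function(box, kind, stream) {
      b <- mock_jitter_box(detector, box, page_index * 7919L + stream)
      out[[length(out) + 1L]] <<- detected_region(
        scale_box(b, detector$image_scale), kind, 0.9)
    }
    for (i in seq_along(str$col_boxes)) add(str$col_boxes[[i]], "column", i)
    for (i in seq_along(str$row_boxes)) add(str$row_boxes[[i]], "row", 1000L + i)
    for (i in seq_along(str$cell_boxes)) add(str$cell_boxes[[i]], "cell", 2000L + i)
  }
  attr(out, "image_size") <- detector$gold$page_size * detector$image_scale
  out
}
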