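#' Keep only key-resource tables (tables mentioning an RRID)
#'
#' Resource tables are identified by the case-sensitive `"RRID:"` prefix
#' occurring in any cell, the same filter used to mine resource tables out of
#' large open-access table corpora.
#'
#' @param tables List of [table_grid()]s.
#' @return The sub-list whose grids contain `"RRID:"`.
#' @export
filter_resource_tables <- function(tables) {
  Filter(function(g) any(grepl("RRID:", g$cells, fixed = TRUE)), tables)
}

# character width of each row = total length of its cell contents
row_char_widths <- function(g) rowSums(matrix(nchar(g$cells), nrow = grid_nrow(g)))

#' Select tables that can simulate cell overflow, with their width budget
#'
#' A table qualifies when its widest row exceeds 90 characters (about the
#' most that fits on one line at a reasonable font size), so that wrapping it
#' to the budget actually forces at least one cell to overflow.  Tables whose
#' widest row is under 100 characters get the tighter 80-character budget,
#' all others 90.
#'
#' @param tables List of [table_grid()]s.
#' @return List of `list(grid =, width_budget =)` for qualifying tables.
#' @export
select_overflow_candidates <- function(tables) {
  out <- list()
  for (g in tables) {
    maxw <- max(row_char_widths(g))
    if (maxw > 90) {
      out[[length(out) + 1L]] <- list(grid = g, width_budget = if (maxw < 100) 80L else 90L)
    }
  }
  out
}

#' Divide a row-width budget across columns
#'
#' Each column's weight is the mean of its cell content lengths plus the
#' population standard deviation of those lengths, so columns with more
#' variable content get extra room -- mimicking how authors size columns to
#' minimize spillover.  Integer widths are the floored proportional shares
#' (at least 1), with the leftover characters handed out one at a time in
#' decreasing weight order.
#'
#' @param table A [table_grid()].
#' @param width_budget Total characters available for one row.
#' @return Integer vector of per-column widths.
#' @export
allocate_column_widths <- function(table, width_budget) {
  lens <- matrix(nchar(table$cells), nrow = grid_nrow(table))
  w <- apply(lens, 2, function(x) mean(x) + sd_pop(x))
  if (sum(w) <= 0) stop("cannot allocate widths for an all-empty table")
  widths <- pmax(1L, as.integer(floor(width_budget * w / sum(w))))
  leftover <- width_budget - sum(widths)
  if (leftover > 0) {
    ord <- order(-w, seq_along(w))
    for (t in seq_len(leftover)) {
      j <- ord[((t - 1L) %% length(w)) + 1L]
      widths[j] <- widths[j] + 1L
    }
  }
  widths
}

#' Wrap one cell's content to a column width
#'
#' Greedy fill: each produced line is the longest prefix of the remaining
#' content that fits the width and ends at a space; when no space falls
#' within the width (long tokens such as sequences or URLs) the line is
#' hard-split at exactly `width` characters.  The kind of each break is
#' recorded in the `"split_kind"` attribute (`"space"` or `"hard"`) so
#' [unsplit_cell()] can reconstruct the original content exactly.
#'
#' @param content Cell string.
#' @param width Maximum characters per line, >= 1.
#' @return Character vector of lines (attribute `split_kind` has length
#'   `length(lines) - 1`).
#' @export
split_cell <- function(content, width) {
  stopifnot(width >= 1)
  lines <- character(0); kinds <- character(0)
  rem <- content
  while (nchar(rem) > width) {
    head <- substr(rem, 1, width + 1)
    sp <- gregexpr(" ", head, fixed = TRUE)[[1]]
    sp <- sp[sp > 0]
    if (length(sp)) {
      p <- max(sp)
      lines <- c(lines, substr(rem, 1, p - 1))
      rem <- substr(rem, p + 1, nchar(rem))
      kinds <- c(kinds, "space")
    } else {
      lines <- c(lines, substr(rem, 1, width))
      rem <- substr(rem, width + 1, nchar(rem))
      kinds <- c(kinds, "hard")
    }
  }
  lines <- c(lines, rem)
  attr(lines, "split_kind") <- kinds
  lines
}

#' Reverse [split_cell()]
#' @param lines Output of [split_cell()] (with its `split_kind` attribute).
#' @return The reconstructed cell string.
#' @export
unsplit_cell <- function(lines) {
  kinds <- attr(lines, "split_kind")
  if (length(lines) <= 1) return(as.character(lines)[1] %||% "")
  out <- lines[1]
  for (i in seq_len(length(lines) - 1L)) {
    joiner <- if (identical(kinds[i], "hard")) "" else " "
    out <- paste0(out, joiner, lines[i + 1L])
  }
  out
}

#' Generate a labeled cell-merge pair dataset by simulating overflow
#'
#' For every qualifying table, cells are wrapped to their allocated column
#' widths.  Consecutive lines of a wrapped (overflowing) cell form positive
#' merge pairs; vertically adjacent cells that both fit their width form
#' negative pairs.  Tables -- not pairs -- are split 90/10 into train/test
#' under the seed, so no table contributes to both sides.
#'
#' @param tables List of [table_grid()]s (pre-filtering is applied:
#'   resource-table filter, then overflow candidate selection).
#' @param seed Integer seed controlling the train/test split (and the
#'   subsample when `balance` is used).
#' @param balance If `TRUE`, negatives are subsampled to the positive count.
#' @param train_fraction Fraction of tables assigned to the training split.
#' @return Data frame with columns `upper`, `lower`, `label` (1 = merge),
#'   `table_id`, `split` (`"train"`/`"test"`).
#' @export
generate_pair_dataset <- function(tables, seed = 1L, balance = FALSE,
                                  train_fraction = 0.9) {
  cands <- select_overflow_candidates(filter_resource_tables(tables))
  if (!length(cands)) {
    return(data.frame(upper = character(0), lower = character(0),
                      label = integer(0), table_id = integer(0),
                      split = character(0), stringsAsFactors = FALSE))
  }
  ups <- character(0); los <- character(0); lab <- integer(0); tid <- integer(0)
  for (ti in seq_along(cands)) {
    g <- cands[[ti]]$grid
    widths <- allocate_column_widths(g, cands[[ti]]$width_budget)
    R <- grid_nrow(g); C <- grid_ncol(g)
    fits <- matrix(nchar(g$cells), R, C) <= rep(widths, each = R)
    for (j in seq_len(C)) {
      for (i in seq_len(R)) {
        if (!fits[i, j]) {
          parts <- split_cell(g$cells[i, j], widths[j])
          k <- length(parts)
          if (k >= 2) {
            ups <- c(ups, parts[-k]); los <- c(los, parts[-1])
            lab <- c(lab, rep(1L, k - 1L)); tid <- c(tid, rep(ti, k - 1L))
          }
        }
      }
      if (R >= 2) {
        both_fit <- fits[-R, j] & fits[-1, j]
        if (any(both_fit)) {
          ii <- which(both_fit)
          ups <- c(ups, g$cells[ii, j]); los <- c(los, g$cells[ii + 1L, j])
          lab <- c(lab, rep(0L, length(ii))); tid <- c(tid, rep(ti, length(ii)))
        }
      }
    }
  }
  df <- data.frame(upper = ups, lower = los, label = lab, table_id = tid,
                   stringsAsFactors = FALSE)
  with_seed(seed, {
    ids <- seq_along(cands)
    n_train <- max(1L, floor(train_fraction * length(ids)))
    train_ids <- sort(sample(ids, n_train))
    df$split <- ifelse(df$table_id %in% train_ids, "train", "test")
    if (balance) {
      keep <- logical(nrow(df))
      for (s in c("train", "test")) {
        pos <- which(df$split == s & df$label == 1L)
        neg <- which(df$split == s & df$label == 0L)
        keep[pos] <- TRUE
        keep[sample(neg, min(length(neg), length(pos)))] <- TRUE
      }
      df <- df[keep, , drop = FALSE]
      rownames(df) <- NULL
    }
  })
  df
}

#' Write a pair dataset as TSV (`upper \t lower \t label`) or JSONL
#' @param df Data frame from [generate_pair_dataset()].
#' @param path Output path.
#' @param format `"tsv"` or `"jsonl"`.
#' @export
write_pair_dataset <- function(df, path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(df[, c("upper", "lower", "label")], path, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(list(upper = df$upper[i], lower = df$lower[i],
                                       label = df$label[i]), auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}
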