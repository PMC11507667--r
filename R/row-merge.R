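#' Encode a vertical cell pair for the merge classifier
#'
#' The classifier input is `upper`, the end-of-cell token, then `lower`.
#' When the encoding exceeds the model context, the upper string is truncated
#' from its left end so the junction -- where the merge signal lives -- is
#' always preserved.
#'
#' @param upper,lower Cell strings of rows i and i+1 in one column.
#' @param vocab A [char_vocab()].
#' @param max_seq Context length limit.
#' @return Integer id sequence of length `<= max_seq`.
#' @export
encode_pair <- function(upper, lower, vocab, max_seq = 256L) {
  u <- encode_chars(vocab, upper)
  l <- encode_chars(vocab, lower)
  ids <- c(u, vocab$eos_id, l)
  if (length(ids) > max_seq) {
    over <- length(ids) - max_seq
    if (over >= length(u)) {
      # upper fully gone: keep the junction and trim the lower tail instead
      ids <- c(vocab$eos_id, l)[seq_len(max_seq)]
    } else {
      ids <- c(u[-seq_len(over)], vocab$eos_id, l)
    }
  }
  ids
}

#' Fine-tune the table LM into a binary cell-merge classifier
#'
#' The LM head is replaced by a single sigmoid neuron reading the final
#' position's representation; all other weights start from the pre-trained
#' LM.  Defaults follow the transfer recipe: 2 epochs of Adam at learning
#' rate 2e-4.
#'
#' @param lm A [train_table_lm()] model.
#' @param dataset Data frame with `upper`, `lower`, `label` columns (see
#'   [generate_pair_dataset()]); rows with both labels must be present.
#' @param config Optional overrides: `epochs` (2), `learning_rate` (2e-4),
#'   `batch_size` (32), `max_seq` (the LM's), `dropout`.
#' @param seed Integer seed (shuffling, head init, dropout).
#' @param verbose Print running loss.
#' @return Object of class `merge_classifier`.
#' @export
finetune_merge_classifier <- function(lm, dataset, config = list(), seed = 1L,
                                      verbose = FALSE) {
  stopifnot(inherits(lm, "table_lm"))
  if (length(unique(dataset$label)) < 2) stop("dataset must contain both labels")
  cfg <- lm$config
  cfg$max_seq <- as.integer(config$max_seq %||% cfg$max_seq)
  cfg$dropout <- config$dropout %||% cfg$dropout
  epochs <- config$epochs %||% 2L
  lr <- config$learning_rate %||% 2e-4
  batch_size <- config$batch_size %||% 32L

  P <- lm$params
  with_seed(derive_seed(seed, 2L), {
    P$Whead <- matrix(stats::rnorm(cfg$embed_dim, sd = 0.02), ncol = 1)
    P$bhead <- 0
  })
  ids <- lapply(seq_len(nrow(dataset)), function(i) {
    encode_pair(dataset$upper[i], dataset$lower[i], lm$vocab, cfg$max_seq)
  })
  labels <- as.numeric(dataset$label)
  opt <- adam_init(P, lr = lr)
  losses <- numeric(0)
  n <- length(ids)
  with_seed(derive_seed(seed, 3L), {
    for (ep in seq_len(epochs)) {
      # bucket by length so batches stack with little padding waste, then
      # visit buckets in shuffled order
      ord <- order(vapply(ids, length, integer(1)) +
                     stats::runif(n, 0, 0.5))
      starts <- seq(1, n, by = batch_size)
      for (bs in sample(starts)) {
        take <- ord[bs:min(bs + batch_size - 1L, n)]
        lg <- clf_loss_and_grads(P, cfg, ids[take], labels[take], train = TRUE)
        upd <- adam_step(opt, P, lg$grads)
        opt <- upd$opt; P <- upd$params
        losses <- c(losses, lg$loss)
        if (verbose && length(losses) %% 50 == 0) {
          message(sprintf("epoch %d  step %d  loss %.4f", ep, length(losses),
                          mean(utils::tail(losses, 50))))
        }
      }
    }
  })
  structure(list(config = cfg, vocab = lm$vocab, params = P,
                 loss_curve = losses), class = "merge_classifier")
}

#' @export
print.merge_classifier <- function(x, ...) {
  cat(sprintf("<merge_classifier %d layers, %d dim, vocab %d>\n",
              x$config$n_layers, x$config$embed_dim, x$config$vocab_size))
  invisible(x)
}

#' Merge probabilities for vectors of cell pairs
#'
#' Generic so that alternative scorers honouring the same contract can stand
#' in for the transformer classifier.
#'
#' @param classifier A [finetune_merge_classifier()] model (or another
#'   object with a method).
#' @param upper,lower Character vectors of equal length.
#' @return Numeric vector of merge probabilities.
#' @export
predict_merge_prob <- function(classifier, upper, lower) {
  UseMethod("predict_merge_prob")
}

#' @export
predict_merge_prob.merge_classifier <- function(classifier, upper, lower) {
  stopifnot(length(upper) == length(lower))
  if (!length(upper)) return(numeric(0))
  ids <- lapply(seq_along(upper), function(i) {
    encode_pair(upper[i], lower[i], classifier$vocab, classifier$config$max_seq)
  })
  clf_predict_probs(classifier$params, classifier$config, ids)
}

#' Max-voting merge decision for one pair of adjacent rows
#'
#' Applies the cell-pair classifier to every column and averages the column
#' probabilities; the rows merge when the mean row score strictly exceeds
#' 0.5.  Empty-empty column pairs contribute their predicted probability
#' like any other pair unless `skip_empty_pairs`.
#'
#' @param classifier A `merge_classifier`.
#' @param row_upper,row_lower Character vectors of the two rows' cells (equal
#'   length).
#' @param skip_empty_pairs Exclude both-empty column pairs from the mean.
#' @return Object of class `row_merge_decision`: `col_probs`, `row_score`,
#'   `merged`.
#' @export
score_row_pair <- function(classifier, row_upper, row_lower,
                           skip_empty_pairs = FALSE) {
  if (length(row_upper) != length(row_lower)) {
    stop("row_upper and row_lower must have the same number of columns")
  }
  probs <- predict_merge_prob(classifier, row_upper, row_lower)
  use <- rep(TRUE, length(probs))
  if (skip_empty_pairs) use <- !(row_upper == "" & row_lower == "")
  score <- if (any(use)) mean(probs[use]) else 0
  structure(list(col_probs = probs, row_score = score, merged = score > 0.5),
            class = "row_merge_decision")
}

#' @export
print.row_merge_decision <- function(x, ...) {
  cat(sprintf("<row_merge_decision score %.3f -> %s>\n", x$row_score,
              if (x$merged) "merge" else "keep"))
  invisible(x)
}

# column-wise concatenation of two rows with a single joining space
join_rows <- function(a, b) {
  ifelse(a == "", b, ifelse(b == "", a, paste(a, b)))
}

#' Repair an over-segmented grid with the learned merge classifier
#'
#' Scans row pairs top to bottom; when a pair merges, cell strings are
#' concatenated column-wise with a single space and the merged row is
#' immediately re-tested against the following row, so multi-way overflow
#' splits collapse by cascading.  With `protect_header` the first row never
#' absorbs the row below it.
#'
#' @param classifier A `merge_classifier`.
#' @param grid A [table_grid()].
#' @param protect_header Keep row 1 out of any merge (default `TRUE`).
#' @param skip_empty_pairs Passed to [score_row_pair()].
#' @return The repaired [table_grid()]; attribute `"n_merges"` counts merges.
#' @export
merge_rows <- function(classifier, grid, protect_header = TRUE,
                       skip_empty_pairs = FALSE) {
  cells <- grid$cells
  i <- if (protect_header) 2L else 1L
  n_merges <- 0L
  while (i < nrow(cells)) {
    dec <- score_row_pair(classifier, cells[i, ], cells[i + 1L, ],
                          skip_empty_pairs = skip_empty_pairs)
    if (dec$merged) {
      cells[i, ] <- join_rows(cells[i, ], cells[i + 1L, ])
      cells <- cells[-(i + 1L), , drop = FALSE]
      n_merges <- n_merges + 1L
      # merged row is re-tested against the next row on the next iteration
    } else {
      i <- i + 1L
    }
  }
  out <- table_grid(cells)
  attr(out, "n_merges") <- n_merges
  out
}
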