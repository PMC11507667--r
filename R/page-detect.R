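# Candidate-page detection: a recurrent line-level classifier whose
# predictions feed a page-level linear SVM (stacked generalizer).

#' Tokenize text for the page-detection models
#'
#' Lowercases and splits on whitespace and punctuation boundaries.
#'
#' @param s Character vector.
#' @return List of token vectors.
#' @export
tokenize_text <- function(s) {
  lapply(strsplit(tolower(s), "[^a-z0-9]+"), function(t) t[nzchar(t)])
}

#' Line-level feature bundle
#'
#' Combines the token context (current line and a window of previous lines)
#' with structural indicators: whether any horizontal/vertical primitive
#' graphics segment vertically overlaps the line's y-range (within `y_pad`),
#' for the current and previous line, plus the page number.
#'
#' @param line A `text_line`.
#' @param prev_lines List of previous `text_line`s (most recent last); only
#'   the last `window` are used, missing slots are empty.
#' @param graphics A [page_graphics()].
#' @param page_number 1-based page number.
#' @param window Number of previous lines in the context.
#' @param y_pad Vertical tolerance in points for the graphics indicators.
#' @return List: `tokens`, `prev_tokens`, `has_hline`, `has_vline`,
#'   `prev_has_hline`, `prev_has_vline`, `page_number`.
#' @export
featurize_line <- function(line, prev_lines, graphics, page_number,
                           window = 1L, y_pad = 3) {
  overlap_flags <- function(l) {
    if (is.null(l)) return(c(FALSE, FALSE))
    lo <- l$y_range[["lo"]] - y_pad; hi <- l$y_range[["hi"]] + y_pad
    hl <- nrow(graphics$hlines) > 0 &&
      any(graphics$hlines$ymin <= hi & graphics$hlines$ymax >= lo)
    vl <- nrow(graphics$vlines) > 0 &&
      any(graphics$vlines$ymin <= hi & graphics$vlines$ymax >= lo)
    c(hl, vl)
  }
  prev <- if (length(prev_lines)) prev_lines[[length(prev_lines)]] else NULL
  cur_f <- overlap_flags(line)
  prev_f <- overlap_flags(prev)
  list(tokens = tokenize_text(line$text)[[1]],
       prev_tokens = if (is.null(prev)) character(0)
                     else tokenize_text(prev$text)[[1]],
       has_hline = cur_f[1], has_vline = cur_f[2],
       prev_has_hline = prev_f[1], prev_has_vline = prev_f[2],
       page_number = as.integer(page_number))
}

# ---- line corpus plumbing -------------------------------------------------
#
# A labeled corpus is a list of documents; each document is a list of pages;
# each page is a data frame with columns text, has_hline, has_vline,
# in_table.  as_page_lines() converts an extracted page_text into that
# format (unlabeled).

#' Convert an extracted `page_text` into page-line records
#' @param page A `page_text` from [extract_pages()].
#' @param y_pad Graphics indicator tolerance, points.
#' @return Data frame with text, has_hline, has_vline.
#' @export
as_page_lines <- function(page, y_pad = 3) {
  lines <- group_text_lines(page$chars)
  if (!length(lines)) {
    return(data.frame(text = character(0), has_hline = logical(0),
                      has_vline = logical(0)))
  }
  flags <- t(vapply(lines, function(l) {
    lo <- l$y_range[["lo"]] - y_pad; hi <- l$y_range[["hi"]] + y_pad
    c(nrow(page$graphics$hlines) > 0 &&
        any(page$graphics$hlines$ymin <= hi & page$graphics$hlines$ymax >= lo),
      nrow(page$graphics$vlines) > 0 &&
        any(page$graphics$vlines$ymin <= hi & page$graphics$vlines$ymax >= lo))
  }, logical(2)))
  data.frame(text = vapply(lines, function(l) l$text, character(1)),
             has_hline = flags[, 1], has_vline = flags[, 2])
}

# encode one page's lines into model inputs: token id sequences (previous
# line window + separator + current line) and auxiliary indicator matrix
encode_page_lines <- function(page_df, page_number, vocab, window = 1L,
                              max_tokens = 24L) {
  toks <- tokenize_text(page_df$text)
  n <- nrow(page_df)
  sep_id <- length(vocab) + 1L  # last id is the separator pseudo-token
  ids <- vector("list", n)
  aux <- matrix(0, n, 5L)
  for (i in seq_len(n)) {
    cur <- match(toks[[i]], vocab); cur[is.na(cur)] <- 0L
    prev <- if (i > 1L && window >= 1L) {
      p <- match(toks[[i - 1L]], vocab); p[is.na(p)] <- 0L; p
    } else integer(0)
    v <- c(prev, sep_id, cur)
    ids[[i]] <- utils::tail(v, max_tokens)
    aux[i, ] <- c(page_df$has_hline[i], page_df$has_vline[i],
                  if (i > 1L) page_df$has_hline[i - 1L] else 0,
                  if (i > 1L) page_df$has_vline[i - 1L] else 0,
                  page_number)
  }
  list(ids = ids, aux = aux)
}

build_token_vocab <- function(corpus, max_vocab = 2000L) {
  tab <- table(unlist(lapply(corpus, function(doc) {
    unlist(lapply(doc, function(pg) unlist(tokenize_text(pg$text))))
  })))
  names(utils::head(sort(tab, decreasing = TRUE), max_vocab))
}

#' Train the line-level recurrent classifier
#'
#' An LSTM reads the token window (previous line, separator, current line);
#' its final state, concatenated with the structural indicator features and
#' the page number, feeds a logistic output.  Class imbalance is handled by
#' weighting positive-class errors `pos_weight` times (default 50) in the
#' loss.  Token embeddings are trainable, randomly initialized or loaded
#' from a word2vec-format text file.
#'
#' @param corpus List of documents (see above) with `in_table` labels.
#' @param config Overrides: `embed_dim` (32), `hidden` (48), `window` (1),
#'   `pos_weight` (50), `epochs` (6), `batch_size` (64), `learning_rate`
#'   (5e-3), `max_vocab` (2000), `embeddings_file` (optional word2vec text
#'   vectors).
#' @param seed Integer seed.
#' @param verbose Print epoch losses.
#' @return Object of class `line_model`.
#' @export
train_line_classifier <- function(corpus, config = list(), seed = 1L,
                                  verbose = FALSE) {
  if (!length(corpus)) stop("empty corpus")
  labels_all <- unlist(lapply(corpus, function(doc)
    lapply(doc, function(pg) pg$in_table)))
  if (length(unique(labels_all)) < 2) {
    stop("line corpus must contain both in-table and out-of-table lines")
  }
  embed_dim <- config$embed_dim %||% 32L
  hidden <- config$hidden %||% 48L
  window <- config$window %||% 1L
  pos_weight <- config$pos_weight %||% 50
  epochs <- config$epochs %||% 6L
  batch_size <- config$batch_size %||% 64L
  lr <- config$learning_rate %||% 5e-3
  vocab <- build_token_vocab(corpus, config$max_vocab %||% 2000L)

  ids <- list(); aux <- list(); y <- numeric(0)
  for (doc in corpus) {
    for (pi in seq_along(doc)) {
      enc <- encode_page_lines(doc[[pi]], pi, vocab, window)
      ids <- c(ids, enc$ids)
      aux[[length(aux) + 1L]] <- enc$aux
      y <- c(y, as.numeric(doc[[pi]]$in_table))
    }
  }
  aux <- do.call(rbind, aux)
  P <- lstm_init(length(vocab) + 1L, embed_dim, hidden, ncol(aux),
                 seed = derive_seed(seed, 11L))
  if (!is.null(config$embeddings_file)) {
    P$emb <- load_word2vec_embeddings(config$embeddings_file, vocab, embed_dim,
                                      P$emb)
  }
  w <- ifelse(y == 1, pos_weight, 1)
  opt <- adam_init(P, lr = lr)
  n <- length(y)
  with_seed(derive_seed(seed, 12L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (bs in seq(1, n, by = batch_size)) {
        take <- ord[bs:min(bs + batch_size - 1L, n)]
        lg <- lstm_loss_and_grads(P, ids[take], aux[take, , drop = FALSE],
                                  y[take], w[take])
        upd <- adam_step(opt, P, lg$grads)
        opt <- upd$opt; P <- upd$params
        ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
      }
      if (verbose) message(sprintf("epoch %d  loss %.4f", ep, ep_loss / nb))
    }
  })
  structure(list(params = P, vocab = vocab, window = window,
                 config = list(embed_dim = embed_dim, hidden = hidden,
                               pos_weight = pos_weight)),
            class = "line_model")
}

#' @export
print.line_model <- function(x, ...) {
  cat(sprintf("<line_model LSTM %d-dim emb, %d hidden, vocab %d>\n",
              x$config$embed_dim, x$config$hidden, length(x$vocab)))
  invisible(x)
}

# read word2vec text format ("word v1 v2 ...") into the embedding table
load_word2vec_embeddings <- function(path, vocab, dim, emb) {
  lines <- readLines(path, warn = FALSE)
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(parts) != dim + 1L) next
    j <- match(parts[1], vocab)
    if (!is.na(j)) emb[j + 1L, ] <- as.numeric(parts[-1])
  }
  emb
}

#' Per-line in-table probabilities for one page
#' @param model A [train_line_classifier()] model.
#' @param page_df Page-line data frame (text, has_hline, has_vline).
#' @param page_number 1-based page number.
#' @return Numeric vector of probabilities.
#' @export
predict_line_probs <- function(model, page_df, page_number) {
  if (!nrow(page_df)) return(numeric(0))
  enc <- encode_page_lines(page_df, page_number, model$vocab, model$window)
  lstm_fwd(model$params, enc$ids, enc$aux)$p
}

# ---- page-level SVM -------------------------------------------------------

page_tfidf <- function(token_lists, vocab, idf) {
  X <- matrix(0, length(token_lists), length(vocab))
  for (i in seq_along(token_lists)) {
    t <- table(match(token_lists[[i]], vocab))
    t <- t[!is.na(as.integer(names(t)))]
    if (length(t)) X[i, as.integer(names(t))] <- as.numeric(t)
  }
  X <- sweep(X, 2, idf, `*`)
  nrm <- sqrt(rowSums(X^2)); nrm[nrm == 0] <- 1
  X / nrm
}

#' Train the page-level linear SVM
#'
#' Pages are represented by the TF-IDF scores of the training vocabulary
#' (bag of words), optionally extended with the count of in-table lines
#' predicted by the line classifier (the stacked-generalizer feature).
#' Positive-class errors carry a penalty factor of `penalty` (default 5) in
#' the SVM objective.
#'
#' @param token_lists List of per-page token vectors.
#' @param labels Logical/0-1 page labels (contains a resource table).
#' @param n_in_table Integer vector of predicted in-table line counts, or
#'   `NULL` for a BoW-only model.
#' @param config Overrides: `penalty` (5), `cost` (1), `max_vocab` (3000).
#' @return Object of class `page_model`.
#' @export
train_page_classifier <- function(token_lists, labels, n_in_table = NULL,
                                  config = list()) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("page labels must contain both classes")
  penalty <- config$penalty %||% 5
  max_vocab <- config$max_vocab %||% 3000L
  tab <- sort(table(unlist(token_lists)), decreasing = TRUE)
  vocab <- names(utils::head(tab, max_vocab))
  df <- vapply(vocab, function(v) sum(vapply(token_lists, function(t)
    v %in% t, logical(1))), numeric(1))
  idf <- log(length(token_lists) / (1 + df)) + 1
  X <- page_tfidf(token_lists, vocab, idf)
  nscale <- 10
  if (!is.null(n_in_table)) X <- cbind(X, n_in_table / nscale)
  colnames(X) <- NULL
  fit <- e1071::svm(x = X, y = factor(labels, levels = c(0, 1)),
                    kernel = "linear", cost = config$cost %||% 1,
                    class.weights = c("0" = 1, "1" = penalty), scale = FALSE)
  structure(list(svm = fit, vocab = vocab, idf = idf,
                 use_line_feature = !is.null(n_in_table), nscale = nscale,
                 penalty = penalty),
            class = "page_model")
}

#' @export
print.page_model <- function(x, ...) {
  cat(sprintf("<page_model linear SVM, %d tf-idf terms%s, penalty %g>\n",
              length(x$vocab),
              if (x$use_line_feature) " + line-count feature" else "",
              x$penalty))
  invisible(x)
}

#' Predict page labels
#' @param model A [train_page_classifier()] model.
#' @param token_lists Per-page token vectors.
#' @param n_in_table Predicted in-table line counts (required when the model
#'   uses the stacked feature).
#' @return Logical vector.
#' @export
predict_pages <- function(model, token_lists, n_in_table = NULL) {
  X <- page_tfidf(token_lists, model$vocab, model$idf)
  if (model$use_line_feature) {
    if (is.null(n_in_table)) stop("model needs n_in_table")
    X <- cbind(X, n_in_table / model$nscale)
  }
  colnames(X) <- NULL
  as.integer(as.character(stats::predict(model$svm, X))) == 1L
}

#' Train the full stacked page detector on a labeled line corpus
#'
#' Level 1: the recurrent line classifier.  Level 2: the linear SVM over
#' page TF-IDF plus the count of lines the level-1 model predicts in-table
#' (probability threshold 0.5).
#'
#' @param corpus Labeled corpus (list of documents of pages).
#' @param config Sub-lists `line` and `page` forwarded to the two trainers.
#' @param seed Integer seed.
#' @return List with `line_model`, `page_model` (class `page_detector`).
#' @export
train_page_detector <- function(corpus, config = list(), seed = 1L) {
  lm <- train_line_classifier(corpus, config$line %||% list(), seed = seed)
  toks <- list(); labs <- integer(0); nin <- integer(0)
  for (doc in corpus) {
    for (pi in seq_along(doc)) {
      pg <- doc[[pi]]
      toks[[length(toks) + 1L]] <- unlist(tokenize_text(pg$text))
      labs <- c(labs, as.integer(any(pg$in_table)))
      nin <- c(nin, sum(predict_line_probs(lm, pg, pi) > 0.5))
    }
  }
  pm <- train_page_classifier(toks, labs, nin, config$page %||% list())
  structure(list(line_model = lm, page_model = pm), class = "page_detector")
}

#' Candidate resource-table pages of a document
#'
#' @param doc List of `page_text` objects ([extract_pages()]) or of
#'   page-line data frames.
#' @param line_model A `line_model`.
#' @param page_model A `page_model` (stacked or BoW-only).
#' @return Integer vector of positive page indices (empty for an empty
#'   document).
#' @export
detect_candidate_pages <- function(doc, line_model, page_model) {
  if (!length(doc)) return(integer(0))
  toks <- list(); nin <- integer(0)
  for (pi in seq_along(doc)) {
    pg <- doc[[pi]]
    df <- if (inherits(pg, "page_text")) as_page_lines(pg) else pg
    toks[[pi]] <- unlist(tokenize_text(df$text))
    nin <- c(nin, if (nrow(df)) sum(predict_line_probs(line_model, df, pi) > 0.5)
                  else 0L)
  }
  which(predict_pages(page_model, toks,
                      if (page_model$use_line_feature) nin else NULL))
}

# ---- fixture corpus generator --------------------------------------------

ref_authors <- c("Smith", "Chen", "Garcia", "Okafor", "Tanaka", "Muller",
                 "Rossi", "Novak")

#' Generate a labeled fixture corpus for page-detection experiments
#'
#' Emulates preprint-like documents at the line level: prose pages,
#' reference/distractor pages that mention resource vocabulary (vendors,
#' antibodies, even RRIDs) in running text without table structure, and
#' resource-table pages whose table lines carry ruled-line indicators.  A
#' fraction of the tables (oligo tables) contain no RRID token at all, so
#' bag-of-words vocabulary alone does not separate the classes.
#'
#' @param seed Integer seed.
#' @param n_docs Number of documents.
#' @param pages_per_doc Pages per document.
#' @param p_table,p_distractor Per-page probabilities of the two non-prose
#'   page types.
#' @return List of documents; each document is a list of page data frames
#'   (text, has_hline, has_vline, in_table).
#' @export
generate_page_corpus <- function(seed, n_docs = 30, pages_per_doc = 8,
                                 p_table = 0.25, p_distractor = 0.25) {
  with_seed(seed, {
    lapply(seq_len(n_docs), function(d) {
      lapply(seq_len(pages_per_doc), function(p) {
        u <- stats::runif(1)
        if (u < p_table) fixture_table_page()
        else if (u < p_table + p_distractor) fixture_distractor_page()
        else fixture_prose_page()
      })
    })
  })
}

fixture_prose_line <- function() {
  paste(sample(prose_vocab, sample(6:10, 1), replace = TRUE), collapse = " ")
}

fixture_prose_page <- function() {
  n <- sample(18:26, 1)
  data.frame(text = vapply(seq_len(n), function(i) fixture_prose_line(),
                           character(1)),
             has_hline = FALSE, has_vline = FALSE, in_table = FALSE)
}

fixture_distractor_page <- function() {
  n <- sample(14:22, 1)
  txt <- vapply(seq_len(n), function(i) {
    if (stats::runif(1) < 0.5) {
      paste0(i, ". ", sample(ref_authors, 1), " et al. validation of the ",
             sample(rt_proteins, 1), " antibody ", sample(rt_vendors, 1),
             " RRID:AB_", rand_digits(7))
    } else {
      paste0(i, ". ", sample(ref_authors, 1), " et al. ", fixture_prose_line())
    }
  }, character(1))
  data.frame(text = txt, has_hline = FALSE, has_vline = FALSE,
             in_table = FALSE)
}

fixture_table_page <- function() {
  n_pre <- sample(3:7, 1)
  n_rows <- sample(6:12, 1)
  oligo_table <- stats::runif(1) < 0.4  # sequence tables carry no RRID
  pre <- vapply(seq_len(n_pre), function(i) fixture_prose_line(), character(1))
  header <- paste(rt_header, collapse = "  ")
  rows <- vapply(seq_len(n_rows), function(i) {
    kind <- if (oligo_table) "oligo"
            else sample(c("antibody", "organism", "software", "chemical"), 1)
    paste(rt_row(kind), collapse = "  ")
  }, character(1))
  data.frame(
    text = c(pre, header, rows),
    has_hline = c(rep(FALSE, n_pre), rep(TRUE, n_rows + 1L)),
    has_vline = c(rep(FALSE, n_pre), rep(TRUE, n_rows + 1L)),
    in_table = c(rep(FALSE, n_pre), rep(TRUE, n_rows + 1L)))
}

#' Write / read labeled line corpora as JSON lines
#'
#' One record per line of each document:
#' `{doc, page, line_index, text, has_hline, has_vline, in_table}`.
#'
#' @param corpus List of documents (lists of page data frames).
#' @param path File path.
#' @export
write_line_labels <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (d in seq_along(corpus)) {
    for (p in seq_along(corpus[[d]])) {
      pg <- corpus[[d]][[p]]
      for (i in seq_len(nrow(pg))) {
        writeLines(jsonlite::toJSON(list(
          doc = d, page = p, line_index = i, text = pg$text[i],
          has_hline = pg$has_hline[i], has_vline = pg$has_vline[i],
          in_table = pg$in_table[i]), auto_unbox = TRUE), con)
      }
    }
  }
  invisible(path)
}

#' @rdname write_line_labels
#' @return For `read_line_labels`, the reconstructed corpus.
#' @export
read_line_labels <- function(path) {
  recs <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON)
  docs <- list()
  for (r in recs) {
    d <- r$doc; p <- r$page
    if (length(docs) < d || is.null(docs[d][[1]])) docs[[d]] <- list()
    row <- data.frame(text = r$text, has_hline = isTRUE(r$has_hline),
                      has_vline = isTRUE(r$has_vline),
                      in_table = isTRUE(r$in_table))
    if (length(docs[[d]]) < p || is.null(docs[[d]][p][[1]])) {
      docs[[d]][[p]] <- row
    } else {
      docs[[d]][[p]] <- rbind(docs[[d]][[p]], row)
    }
  }
  docs
}
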