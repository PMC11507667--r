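#' Character vocabulary for the table language model
#'
#' Maps every character observed in a corpus to an integer id, with the
#' `"<EOS>"` end-of-cell token as its own entry and id 0 reserved for
#' unknown/padding.  Characters unseen at inference map to 0 rather than
#' erroring, since real tables carry unbounded glyph inventories.
#'
#' @param corpus Character vector of cell strings.
#' @return Object of class `char_vocab`: list with `chars` (id order) and
#'   `eos_id`.
#' @export
char_vocab <- function(corpus) {
  chars <- sort(unique(unlist(strsplit(corpus, ""), use.names = FALSE)))
  structure(list(chars = chars, eos_id = length(chars) + 1L), class = "char_vocab")
}

vocab_size <- function(vocab) length(vocab$chars) + 1L  # chars + <EOS>

#' @export
print.char_vocab <- function(x, ...) {
  cat(sprintf("<char_vocab %d characters + <EOS>>\n", length(x$chars)))
  invisible(x)
}

#' Encode a string as character ids (0 = unknown)
#' @param vocab A [char_vocab()].
#' @param s A string.
#' @return Integer vector, one id per character.
#' @export
encode_chars <- function(vocab, s) {
  if (!nchar(s)) return(integer(0))
  m <- match(strsplit(s, "")[[1]], vocab$chars)
  m[is.na(m)] <- 0L
  m
}

decode_chars <- function(vocab, ids) {
  out <- character(length(ids))
  known <- ids >= 1L & ids <= length(vocab$chars)
  out[known] <- vocab$chars[ids[known]]
  out[ids == vocab$eos_id] <- "<EOS>"
  paste(out, collapse = "")
}

#' Stream training cell strings out of table XML files
#'
#' Reads a JATS-style subset (`<table-wrap>`/`<table>` with `<tr>` rows of
#' `<td>`/`<th>` cells); every cell -- header rows included -- yields one
#' training sequence.  Malformed files are reported per-file and skipped so
#' the stream continues.
#'
#' @param files Character vector of XML file paths.
#' @param max_seq Truncation length (the end-of-cell token takes one slot).
#' @return Character vector of cell strings in deterministic document order;
#'   attribute `"errors"` names files that failed to parse.
#' @export
build_cell_corpus <- function(files, max_seq = 256L) {
  cells <- character(0); errs <- character(0)
  for (f in files) {
    doc <- tryCatch(xml2::read_xml(f), error = function(e) e)
    if (inherits(doc, "error")) {
      warning(sprintf("skipping malformed XML %s: %s", f, conditionMessage(doc)))
      errs <- c(errs, f)
      next
    }
    nodes <- xml2::xml_find_all(doc, ".//tr/*[self::td or self::th]")
    txt <- xml2::xml_text(nodes)
    cells <- c(cells, substr(txt, 1, max_seq - 1L))
  }
  attr(cells, "errors") <- errs
  cells
}

#' Train the character-level autoregressive table language model
#'
#' A decoder-only transformer (causal multi-head self-attention) trained to
#' predict the next character of table cell contents; each training sequence
#' is one cell plus the end-of-cell token.  The published full-scale recipe
#' (6 layers, 6 heads, 384-dim embeddings, 256-step context, batch 256 for
#' 250k steps) is expressible through `config`; tests and examples use a
#' reduced configuration.
#'
#' @param corpus Character vector of cell strings.
#' @param config List overriding [transformer_config()] fields
#'   (`n_layers`, `n_heads`, `embed_dim`, `max_seq`, `dropout`) and training
#'   fields `batch_size`, `steps`, `learning_rate`.
#' @param seed Integer seed; fixed seed implies an identical loss curve.
#' @param verbose Print loss every 50 steps.
#' @return Object of class `table_lm`: `config`, `vocab`, `params`,
#'   `loss_curve`.
#' @export
train_table_lm <- function(corpus, config = list(), seed = 1L, verbose = FALSE) {
  corpus <- corpus[nchar(corpus) >= 0]
  if (length(corpus) == 0) stop("empty corpus")
  vocab <- char_vocab(corpus)
  if (vocab_size(vocab) < 2L) stop("vocabulary too small (need at least 2 symbols)")
  cfg <- transformer_config(
    vocab_size = vocab_size(vocab),
    n_layers = config$n_layers %||% 6L,
    n_heads = config$n_heads %||% 6L,
    embed_dim = config$embed_dim %||% 384L,
    max_seq = config$max_seq %||% 256L,
    dropout = config$dropout %||% 0.1)
  batch_size <- config$batch_size %||% 32L
  steps <- config$steps %||% 1000L
  lr <- config$learning_rate %||% 1e-3

  # target sequences: cell characters + EOS, truncated to the context length
  seqs <- lapply(corpus, function(s) {
    ids <- encode_chars(vocab, substr(s, 1, cfg$max_seq - 1L))
    c(ids, vocab$eos_id)
  })
  P <- transformer_init(cfg, seed = seed, head = "lm")
  opt <- adam_init(P, lr = lr)
  losses <- numeric(steps)
  with_seed(derive_seed(seed, 1L), {
    for (st in seq_len(steps)) {
      take <- sample.int(length(seqs), min(batch_size, length(seqs)),
                         replace = length(seqs) < batch_size)
      lg <- lm_loss_and_grads(P, cfg, seqs[take], vocab$eos_id, train = TRUE)
      upd <- adam_step(opt, P, lg$grads)
      opt <- upd$opt; P <- upd$params
      losses[st] <- lg$loss
      if (verbose && st %% 50 == 0) {
        message(sprintf("step %d  loss %.4f", st, lg$loss))
      }
    }
  })
  structure(list(config = cfg, vocab = vocab, params = P, loss_curve = losses),
            class = "table_lm")
}

#' @export
print.table_lm <- function(x, ...) {
  npar <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<table_lm %d layers, %d dim, vocab %d, %.2fM params>\n",
              x$config$n_layers, x$config$embed_dim, x$config$vocab_size,
              npar / 1e6))
  invisible(x)
}

#' Next-character logits given a prefix
#'
#' @param model A [train_table_lm()] model.
#' @param prefix Character string (may be empty); must be shorter than the
#'   model context minus the start slot.
#' @return Numeric vector of logits, one per vocabulary entry (named by
#'   character, `<EOS>` last).
#' @export
next_char_logits <- function(model, prefix) {
  cfg <- model$config
  ids <- encode_chars(model$vocab, prefix)
  if (length(ids) + 1L > cfg$max_seq) stop("prefix at maximum context length")
  input <- c(model$vocab$eos_id, ids)
  fw <- transformer_fwd(model$params, cfg, list(input), train = FALSE)
  z <- as.numeric(fw$Y[fw$N, , drop = FALSE] %*% model$params$Whead) +
    model$params$bhead
  names(z) <- c(model$vocab$chars, "<EOS>")
  z
}

#' Next-character probability distribution (softmax of the logits)
#' @inheritParams next_char_logits
#' @return Named probability vector summing to 1.
#' @export
next_char_probs <- function(model, prefix) {
  z <- next_char_logits(model, prefix)
  e <- exp(z - max(z))
  e / sum(e)
}

#' Greedy/temperature sampling from the table LM
#' @inheritParams next_char_logits
#' @param max_len Maximum characters to generate.
#' @param greedy Take the argmax at each step (otherwise sample).
#' @return Generated string (without the end token).
#' @export
generate_cell <- function(model, prefix = "", max_len = 50, greedy = TRUE) {
  out <- prefix
  for (i in seq_len(max_len)) {
    if (nchar(out) + 1L >= model$config$max_seq) break
    p <- next_char_probs(model, out)
    k <- if (greedy) which.max(p) else sample.int(length(p), 1, prob = p)
    if (names(p)[k] == "<EOS>") break
    out <- paste0(out, names(p)[k])
  }
  out
}

#' Save / load a table LM or merge classifier checkpoint
#'
#' Single-file archive holding config, vocabulary and weights; a loaded
#' checkpoint is bit-identical to the saved model.
#'
#' @param model A `table_lm` or `merge_classifier`.
#' @param path File path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return For `load_checkpoint`, the restored model object.
#' @export
load_checkpoint <- function(path) readRDS(path)
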