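# Shared fixture builders and a per-session cache for the expensively
# trained models, so the merge classifier is trained once and reused by the
# pipeline and acceptance tests.

.cache <- new.env(parent = emptyenv())

# random small grid for GriTS property tests
random_small_grid <- function(max_dim = 4, alphabet = letters[1:6],
                              max_len = 6) {
  R <- sample(seq_len(max_dim), 1)
  C <- sample(seq_len(max_dim), 1)
  table_grid(matrix(replicate(R * C, paste(
    sample(alphabet, sample(0:max_len, 1), replace = TRUE), collapse = "")),
    R, C))
}

# independent in-test LCS oracle (plain R dynamic programming)
lcs_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) return(0L)
  dp <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    dp[i + 1, j + 1] <- if (x[i] == y[j]) dp[i, j] + 1L
                        else max(dp[i, j + 1], dp[i + 1, j])
  }
  dp[n + 1, m + 1]
}

# reduced-scale model configuration used across LM tests
tiny_lm_config <- function(steps = 60) {
  list(n_layers = 2L, n_heads = 4L, embed_dim = 64L, max_seq = 64L,
       steps = steps, batch_size = 8L, dropout = 0, learning_rate = 3e-3)
}

# the study-condition merge classifier: pre-trained table LM on a fixture
# cell corpus, fine-tuned on simulated overflow pairs (2 epochs, lr 2e-4)
trained_merge_models <- function() {
  if (!is.null(.cache$merge)) return(.cache$merge)
  tabs <- lapply(1:240, function(i) {
    generate_resource_table(1000 + i, n_rows = 10, overflow_rate = 0.35)
  })
  pairs <- generate_pair_dataset(tabs, seed = 5)
  corpus_tabs <- lapply(1:80, function(i) {
    generate_resource_table(5000 + i, n_rows = 8, overflow_rate = 0.3)
  })
  corpus <- unlist(lapply(corpus_tabs, function(g) as.vector(g$cells)))
  lm <- train_table_lm(corpus, config = list(
    n_layers = 2L, n_heads = 4L, embed_dim = 128L, max_seq = 128L,
    steps = 300L, batch_size = 32L, learning_rate = 1e-3), seed = 7)
  clf <- finetune_merge_classifier(lm, pairs[pairs$split == "train", ],
                                   seed = 8)
  .cache$merge <- list(lm = lm, classifier = clf, pairs = pairs)
  .cache$merge
}

# a stub classifier whose column probabilities are scripted, for testing the
# voting and merging rules in isolation
stub_classifier <- function(prob_fn) {
  structure(list(prob_fn = prob_fn), class = "stub_classifier")
}

predict_merge_prob.stub_classifier <- function(classifier, upper, lower) {
  mapply(classifier$prob_fn, upper, lower, USE.NAMES = FALSE)
}
registerS3method("predict_merge_prob", "stub_classifier",
                 predict_merge_prob.stub_classifier,
                 envir = asNamespace("restable"))
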