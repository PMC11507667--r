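# Decoder-only transformer over character ids, with hand-derived backprop.
#
# Sequences in a batch are stacked into one (sum of lengths) x embed_dim
# matrix so that all projections run as single BLAS calls; causal attention
# loops over sequences and heads.  Id 0 is reserved for unknown/padding and
# embeds through a dedicated row of the token table.

transformer_config <- function(vocab_size, n_layers = 6, n_heads = 6,
                               embed_dim = 384, max_seq = 256, mlp_mult = 4,
                               dropout = 0.1) {
  stopifnot(embed_dim %% n_heads == 0)
  list(vocab_size = as.integer(vocab_size), n_layers = as.integer(n_layers),
       n_heads = as.integer(n_heads), embed_dim = as.integer(embed_dim),
       max_seq = as.integer(max_seq), mlp_mult = as.integer(mlp_mult),
       dropout = dropout)
}

transformer_init <- function(cfg, seed = 1L, head = c("lm", "sigmoid")) {
  head <- match.arg(head)
  d <- cfg$embed_dim; hd <- cfg$mlp_mult * d; V <- cfg$vocab_size
  with_seed(seed, {
    rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
    P <- list(tok = rn(V + 1L, d), pos = rn(cfg$max_seq, d))
    for (l in seq_len(cfg$n_layers)) {
      pre <- sprintf("L%d.", l)
      P[[paste0(pre, "ln1g")]] <- rep(1, d); P[[paste0(pre, "ln1b")]] <- rep(0, d)
      P[[paste0(pre, "Wqkv")]] <- rn(d, 3 * d); P[[paste0(pre, "bqkv")]] <- rep(0, 3 * d)
      P[[paste0(pre, "Wo")]] <- rn(d, d); P[[paste0(pre, "bo")]] <- rep(0, d)
      P[[paste0(pre, "ln2g")]] <- rep(1, d); P[[paste0(pre, "ln2b")]] <- rep(0, d)
      P[[paste0(pre, "W1")]] <- rn(d, hd); P[[paste0(pre, "b1")]] <- rep(0, hd)
      P[[paste0(pre, "W2")]] <- rn(hd, d); P[[paste0(pre, "b2")]] <- rep(0, d)
    }
    P$lnfg <- rep(1, d); P$lnfb <- rep(0, d)
    if (head == "lm") {
      P$Whead <- rn(d, V); P$bhead <- rep(0, V)
    } else {
      P$Whead <- rn(d, 1); P$bhead <- 0
    }
    P
  })
}

# ids: list of integer vectors (values 0..V). Returns stacked activations and
# caches for backward.  train toggles dropout (masks drawn from the current
# RNG stream).
transformer_fwd <- function(P, cfg, ids, train = FALSE) {
  lens <- vapply(ids, length, integer(1))
  stopifnot(all(lens >= 1), all(lens <= cfg$max_seq))
  nseq <- length(ids)
  offs <- cumsum(c(0L, lens[-nseq]))
  flat <- unlist(ids, use.names = FALSE)
  pos <- unlist(lapply(lens, seq_len), use.names = FALSE)
  N <- length(flat); d <- cfg$embed_dim
  dk <- d %/% cfg$n_heads
  drop_p <- if (train) cfg$dropout else 0

  X <- P$tok[flat + 1L, , drop = FALSE] + P$pos[pos, , drop = FALSE]
  caches <- vector("list", cfg$n_layers)
  rows_of <- lapply(seq_len(nseq), function(s) offs[s] + seq_len(lens[s]))

  new_drop <- function() {
    if (drop_p > 0) {
      m <- matrix(stats::runif(N * d) >= drop_p, N, d) / (1 - drop_p)
    } else NULL
  }

  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("L%d.", l)
    ln1 <- layernorm_fwd(X, P[[paste0(pre, "ln1g")]], P[[paste0(pre, "ln1b")]])
    QKV <- ln1$y %*% P[[paste0(pre, "Wqkv")]] +
      rep(P[[paste0(pre, "bqkv")]], each = N)
    O <- matrix(0, N, d)
    probs <- vector("list", nseq)
    for (s in seq_len(nseq)) {
      rs <- rows_of[[s]]; Tn <- lens[s]
      ph <- vector("list", cfg$n_heads)
      for (h in seq_len(cfg$n_heads)) {
        hc <- (h - 1L) * dk + seq_len(dk)
        Q <- QKV[rs, hc, drop = FALSE]
        K <- QKV[rs, d + hc, drop = FALSE]
        V <- QKV[rs, 2L * d + hc, drop = FALSE]
        S <- tcrossprod(Q, K) / sqrt(dk)
        S[upper.tri(S)] <- -Inf
        Pm <- softmax_rows(S)
        if (Tn == 1L) Pm <- matrix(Pm, 1, 1)
        O[rs, hc] <- Pm %*% V
        ph[[h]] <- Pm
      }
      probs[[s]] <- ph
    }
    AO <- O %*% P[[paste0(pre, "Wo")]] + rep(P[[paste0(pre, "bo")]], each = N)
    dm1 <- new_drop()
    if (!is.null(dm1)) AO <- AO * dm1
    X1 <- X + AO
    ln2 <- layernorm_fwd(X1, P[[paste0(pre, "ln2g")]], P[[paste0(pre, "ln2b")]])
    H1 <- ln2$y %*% P[[paste0(pre, "W1")]] + rep(P[[paste0(pre, "b1")]], each = N)
    G <- gelu(H1)
    M <- G %*% P[[paste0(pre, "W2")]] + rep(P[[paste0(pre, "b2")]], each = N)
    dm2 <- new_drop()
    if (!is.null(dm2)) M <- M * dm2
    X2 <- X1 + M
    caches[[l]] <- list(ln1 = ln1, QKV = QKV, probs = probs, O = O, X = X,
                        X1 = X1, ln2 = ln2, H1 = H1, G = G,
                        dm1 = dm1, dm2 = dm2)
    X <- X2
  }
  lnf <- layernorm_fwd(X, P$lnfg, P$lnfb)
  list(Y = lnf$y, lnf = lnf, Xf = X, caches = caches, flat = flat, pos = pos,
       lens = lens, rows_of = rows_of, N = N)
}

# dY: gradient w.r.t. final normalized activations. Returns grads for every
# parameter (same names as P).
transformer_bwd <- function(P, cfg, fw, dY) {
  d <- cfg$embed_dim; dk <- d %/% cfg$n_heads
  N <- fw$N
  G <- nn_zeros_like(P)
  lb <- layernorm_bwd(dY, fw$lnf, P$lnfg)
  G$lnfg <- lb$dg; G$lnfb <- lb$db
  dX <- lb$dx
  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- sprintf("L%d.", l)
    cc <- fw$caches[[l]]
    dM <- dX
    if (!is.null(cc$dm2)) dM <- dM * cc$dm2
    G[[paste0(pre, "W2")]] <- crossprod(cc$G, dM)
    G[[paste0(pre, "b2")]] <- colSums(dM)
    dG <- dM %*% t(P[[paste0(pre, "W2")]])
    dH1 <- dG * gelu_grad(cc$H1)
    G[[paste0(pre, "W1")]] <- crossprod(cc$ln2$y, dH1)
    G[[paste0(pre, "b1")]] <- colSums(dH1)
    dln2y <- dH1 %*% t(P[[paste0(pre, "W1")]])
    lb2 <- layernorm_bwd(dln2y, cc$ln2, P[[paste0(pre, "ln2g")]])
    G[[paste0(pre, "ln2g")]] <- lb2$dg; G[[paste0(pre, "ln2b")]] <- lb2$db
    dX1 <- dX + lb2$dx
    dAO <- dX1
    if (!is.null(cc$dm1)) dAO <- dAO * cc$dm1
    G[[paste0(pre, "Wo")]] <- crossprod(cc$O, dAO)
    G[[paste0(pre, "bo")]] <- colSums(dAO)
    dO <- dAO %*% t(P[[paste0(pre, "Wo")]])
    dQKV <- matrix(0, N, 3 * d)
    for (s in seq_along(fw$rows_of)) {
      rs <- fw$rows_of[[s]]
      for (h in seq_len(cfg$n_heads)) {
        hc <- (h - 1L) * dk + seq_len(dk)
        Pm <- cc$probs[[s]][[h]]
        Q <- cc$QKV[rs, hc, drop = FALSE]
        K <- cc$QKV[rs, d + hc, drop = FALSE]
        V <- cc$QKV[rs, 2L * d + hc, drop = FALSE]
        dOh <- dO[rs, hc, drop = FALSE]
        dPm <- tcrossprod(dOh, V)
        dV <- crossprod(Pm, dOh)
        dS <- Pm * (dPm - rowSums(dPm * Pm))
        dS <- dS / sqrt(dk)
        dQ <- dS %*% K
        dK <- crossprod(dS, Q)
        dQKV[rs, hc] <- dQKV[rs, hc] + dQ
        dQKV[rs, d + hc] <- dQKV[rs, d + hc] + dK
        dQKV[rs, 2L * d + hc] <- dQKV[rs, 2L * d + hc] + dV
      }
    }
    G[[paste0(pre, "Wqkv")]] <- crossprod(cc$ln1$y, dQKV)
    G[[paste0(pre, "bqkv")]] <- colSums(dQKV)
    dln1y <- dQKV %*% t(P[[paste0(pre, "Wqkv")]])
    lb1 <- layernorm_bwd(dln1y, cc$ln1, P[[paste0(pre, "ln1g")]])
    G[[paste0(pre, "ln1g")]] <- lb1$dg; G[[paste0(pre, "ln1b")]] <- lb1$db
    dX <- dX1 + lb1$dx
  }
  # embeddings: scatter-add row gradients by token / position index
  idx <- fw$flat + 1L
  dtok <- matrix(0, nrow(P$tok), d)
  rs <- rowsum(dX, idx)
  dtok[as.integer(rownames(rs)), ] <- rs
  dpos <- matrix(0, nrow(P$pos), d)
  rs2 <- rowsum(dX, fw$pos)
  dpos[as.integer(rownames(rs2)), ] <- rs2
  G$tok <- dtok; G$pos <- dpos
  G
}

# LM loss: next-character cross-entropy.  ids: list of target sequences
# (already including EOS); the model input is EOS-prefixed.  Returns loss and
# grads.
lm_loss_and_grads <- function(P, cfg, ids, eos_id, train = TRUE) {
  inputs <- lapply(ids, function(v) c(eos_id, v[-length(v)]))
  fw <- transformer_fwd(P, cfg, inputs, train = train)
  targets <- unlist(ids, use.names = FALSE)
  logits <- fw$Y %*% P$Whead + rep(P$bhead, each = fw$N)
  probs <- softmax_rows(logits)
  n <- fw$N
  keep <- targets >= 1L
  idx <- cbind(seq_len(n)[keep], targets[keep])
  loss <- -sum(log(pmax(probs[idx], 1e-12))) / sum(keep)
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  dlogits[!keep, ] <- 0
  dlogits <- dlogits / sum(keep)
  G <- transformer_bwd(P, cfg, fw, dlogits %*% t(P$Whead))
  G$Whead <- crossprod(fw$Y, dlogits)
  G$bhead <- colSums(dlogits)
  list(loss = loss, grads = G)
}

# Binary head loss: probability read from the final position of each
# sequence.  labels in {0,1}.
clf_loss_and_grads <- function(P, cfg, ids, labels, train = TRUE) {
  fw <- transformer_fwd(P, cfg, ids, train = train)
  last <- vapply(fw$rows_of, function(r) r[length(r)], integer(1))
  z <- as.numeric(fw$Y[last, , drop = FALSE] %*% P$Whead) + P$bhead
  p <- sigmoid(z)
  n <- length(labels)
  loss <- -mean(labels * log(pmax(p, 1e-12)) + (1 - labels) * log(pmax(1 - p, 1e-12)))
  dz <- (p - labels) / n
  dY <- matrix(0, fw$N, cfg$embed_dim)
  dY[last, ] <- outer(dz, as.numeric(P$Whead))
  G <- transformer_bwd(P, cfg, fw, dY)
  G$Whead <- crossprod(fw$Y[last, , drop = FALSE], matrix(dz, ncol = 1))
  G$bhead <- sum(dz)
  list(loss = loss, grads = G, probs = p)
}

clf_predict_probs <- function(P, cfg, ids) {
  out <- numeric(length(ids))
  # process in length-sorted chunks to limit padding-free stacking cost
  ord <- order(vapply(ids, length, integer(1)))
  bs <- 64L
  for (start in seq(1, length(ids), by = bs)) {
    take <- ord[start:min(start + bs - 1L, length(ids))]
    fw <- transformer_fwd(P, cfg, ids[take], train = FALSE)
    last <- vapply(fw$rows_of, function(r) r[length(r)], integer(1))
    z <- as.numeric(fw$Y[last, , drop = FALSE] %*% P$Whead) + P$bhead
    out[take] <- sigmoid(z)
  }
  out
}
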