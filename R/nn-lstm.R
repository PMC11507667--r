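# Batched single-layer LSTM with a logistic head over the final hidden
# state concatenated with auxiliary indicator features.  Hand-derived BPTT;
# sequences are left-padded (mask carries state through pad steps).

lstm_init <- function(vocab_n, embed_dim, hidden, n_aux, seed = 1L) {
  with_seed(seed, {
    rn <- function(nr, nc, sd = 0.08) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
    P <- list(emb = rn(vocab_n + 1L, embed_dim),
              Wx = rn(embed_dim, 4L * hidden),
              Wh = rn(hidden, 4L * hidden),
              b = rep(0, 4L * hidden),
              Wout = rn(hidden + n_aux, 1L, sd = 0.2),
              bout = 0)
    # forget-gate bias starts positive so state persists early in training
    P$b[hidden + seq_len(hidden)] <- 1
    P
  })
}

# ids: list of integer vectors (0 = unknown token, embeds row 1); aux: B x
# n_aux matrix.  Returns probabilities and caches.
lstm_fwd <- function(P, ids, aux) {
  B <- length(ids)
  H <- ncol(P$Wh) %/% 4L
  lens <- vapply(ids, length, integer(1))
  Tm <- max(lens, 1L)
  # left-pad so every sequence ends at step Tm
  idm <- matrix(NA_integer_, B, Tm)
  for (s in seq_len(B)) if (lens[s]) idm[s, (Tm - lens[s] + 1L):Tm] <- ids[[s]]
  h <- matrix(0, B, H); cst <- matrix(0, B, H)
  steps <- vector("list", Tm)
  for (t in seq_len(Tm)) {
    m <- as.numeric(!is.na(idm[, t]))
    look <- ifelse(is.na(idm[, t]), 0L, idm[, t]) + 1L
    x <- P$emb[look, , drop = FALSE] * m
    raw <- x %*% P$Wx + h %*% P$Wh + rep(P$b, each = B)
    i_g <- sigmoid(raw[, seq_len(H), drop = FALSE])
    f_g <- sigmoid(raw[, H + seq_len(H), drop = FALSE])
    o_g <- sigmoid(raw[, 2L * H + seq_len(H), drop = FALSE])
    g_g <- tanh(raw[, 3L * H + seq_len(H), drop = FALSE])
    c_new <- f_g * cst + i_g * g_g
    tc <- tanh(c_new)
    h_new <- o_g * tc
    steps[[t]] <- list(m = m, look = look, x = x, i = i_g, f = f_g, o = o_g,
                       g = g_g, c_prev = cst, tc = tc, h_prev = h)
    cst <- c_new * m + cst * (1 - m)
    h <- h_new * m + h * (1 - m)
  }
  feat <- cbind(h, aux)
  z <- as.numeric(feat %*% P$Wout) + P$bout
  list(p = sigmoid(z), z = z, feat = feat, steps = steps, h = h, Tm = Tm, B = B)
}

# weighted binary cross-entropy loss and full gradients
lstm_loss_and_grads <- function(P, ids, aux, y, w) {
  fw <- lstm_fwd(P, ids, aux)
  p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
  sw <- sum(w)
  loss <- -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sw
  dz <- w * (p - y) / sw
  G <- nn_zeros_like(P)
  G$Wout <- crossprod(fw$feat, matrix(dz, ncol = 1))
  G$bout <- sum(dz)
  H <- ncol(P$Wh) %/% 4L
  dh <- outer(dz, as.numeric(P$Wout[seq_len(H), 1]))
  dc <- matrix(0, fw$B, H)
  for (t in rev(seq_len(fw$Tm))) {
    st <- fw$steps[[t]]
    m <- st$m
    dh_m <- dh * m
    dc_m <- dc * m
    dc_new <- dc_m + dh_m * st$o * (1 - st$tc^2)
    di <- dc_new * st$g
    df <- dc_new * st$c_prev
    dg <- dc_new * st$i
    do_ <- dh_m * st$tc
    draw <- cbind(di * st$i * (1 - st$i),
                  df * st$f * (1 - st$f),
                  do_ * st$o * (1 - st$o),
                  dg * (1 - st$g^2))
    G$Wx <- G$Wx + crossprod(st$x, draw)
    G$Wh <- G$Wh + crossprod(st$h_prev, draw)
    G$b <- G$b + colSums(draw)
    dx <- draw %*% t(P$Wx)
    dx <- dx * m
    emb_add <- rowsum(dx, st$look)
    rows <- as.integer(rownames(emb_add))
    G$emb[rows, ] <- G$emb[rows, ] + emb_add
    dh <- draw %*% t(P$Wh) + dh * (1 - m)
    dc <- dc_new * st$f + dc * (1 - m)
  }
  list(loss = loss, grads = G, probs = fw$p)
}
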