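# Shared neural-network plumbing: parameter containers and Adam.
#
# Parameters are flat named lists of numeric matrices/vectors; gradients are
# lists of the same shape.  Everything runs on base-R matrices so the heavy
# lifting lands in BLAS.

nn_zeros_like <- function(params) lapply(params, function(p) p * 0)

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = nn_zeros_like(params), v = nn_zeros_like(params))
}

adam_step <- function(opt, params, grads, clip = 1.0) {
  if (!is.null(clip)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
    if (is.finite(gn) && gn > clip) grads <- lapply(grads, function(g) g * (clip / gn))
  }
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (k in names(params)) {
    g <- grads[[k]]
    opt$m[[k]] <- b1 * opt$m[[k]] + (1 - b1) * g
    opt$v[[k]] <- b2 * opt$v[[k]] + (1 - b2) * g * g
    params[[k]] <- params[[k]] -
      opt$lr * (opt$m[[k]] / c1) / (sqrt(opt$v[[k]] / c2) + opt$eps)
  }
  list(opt = opt, params = params)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# row-wise softmax of a matrix
softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

# layer norm over rows; returns list(y, xhat, inv_sd)
layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, g, `*`) + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * inv
  list(dx = dx, dg = dg, db = db)
}
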