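# Neural-network primitives with hand-derived backward passes.
#
# No autodiff framework is used: every layer is a pure function returning its
# output plus a cache, with a matching *_bwd taking the cache and the output
# gradient. All tensors are base-R matrices/arrays in double precision;
# gradients are verified against central finite differences in the tests.

# broadcast a length-d vector across the columns of an L x d matrix
bcast_cols <- function(v, L) rep(v, each = L)

# ---- layer norm (per row) --------------------------------------------------

LN_EPS <- 1e-5

ln_fwd <- function(x, g, b) {
  L <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + LN_EPS)
  xhat <- xc * inv
  y <- xhat * bcast_cols(g, L) + bcast_cols(b, L)
  list(y = y, cache = list(xhat = xhat, inv = inv, g = g))
}

ln_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  L <- nrow(xhat)
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * bcast_cols(cache$g, L)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = dg, db = db)
}

# ---- multi-head self-attention --------------------------------------------

# x: L x d; real: logical length L (TRUE = real position, FALSE = padding)
attn_fwd <- function(x, p, nh, real) {
  L <- nrow(x)
  d <- ncol(x)
  dh <- d %/% nh
  Q <- x %*% p$Wq + bcast_cols(p$bq, L)
  K <- x %*% p$Wk + bcast_cols(p$bk, L)
  V <- x %*% p$Wv + bcast_cols(p$bv, L)
  scale <- 1 / sqrt(dh)
  heads <- vector("list", nh)
  Ocat <- matrix(0, L, d)
  for (h in seq_len(nh)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) * scale
    S[, !real] <- -1e30  # padded keys receive no attention
    E <- exp(S - apply(S, 1L, max))
    P <- E / rowSums(E)
    Ocat[, idx] <- P %*% V[, idx, drop = FALSE]
    heads[[h]] <- P
  }
  y <- Ocat %*% p$Wo + bcast_cols(p$bo, L)
  list(y = y, cache = list(x = x, Q = Q, K = K, V = V, Ocat = Ocat,
                           heads = heads, nh = nh, dh = dh, scale = scale))
}

attn_bwd <- function(dy, p, cache) {
  x <- cache$x
  L <- nrow(x)
  grads <- list(
    Wo = crossprod(cache$Ocat, dy), bo = colSums(dy))
  dOcat <- tcrossprod(dy, p$Wo)
  dQ <- matrix(0, L, ncol(x))
  dK <- dQ
  dV <- dQ
  for (h in seq_len(cache$nh)) {
    idx <- ((h - 1L) * cache$dh + 1L):(h * cache$dh)
    P <- cache$heads[[h]]
    dO <- dOcat[, idx, drop = FALSE]
    dP <- tcrossprod(dO, cache$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(P, dO)
    dS <- P * (dP - rowSums(dP * P))      # masked entries have P = 0
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] * cache$scale
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE]) * cache$scale
  }
  grads$Wq <- crossprod(x, dQ); grads$bq <- colSums(dQ)
  grads$Wk <- crossprod(x, dK); grads$bk <- colSums(dK)
  grads$Wv <- crossprod(x, dV); grads$bv <- colSums(dV)
  dx <- tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv)
  list(dx = dx, grads = grads)
}

# ---- position-wise feed-forward -------------------------------------------

ffn_fwd <- function(x, p) {
  L <- nrow(x)
  H <- x %*% p$W1 + bcast_cols(p$b1, L)
  R <- pmax(H, 0)
  y <- R %*% p$W2 + bcast_cols(p$b2, L)
  list(y = y, cache = list(x = x, H = H, R = R))
}

ffn_bwd <- function(dy, p, cache) {
  dR <- tcrossprod(dy, p$W2)
  dH <- dR * (cache$H > 0)
  list(dx = tcrossprod(dH, p$W1),
       grads = list(W1 = crossprod(cache$x, dH), b1 = colSums(dH),
                    W2 = crossprod(cache$R, dy), b2 = colSums(dy)))
}

# ---- pre-LN transformer encoder layer -------------------------------------

enc_layer_fwd <- function(x, p, nh, real) {
  l1 <- ln_fwd(x, p$ln1_g, p$ln1_b)
  at <- attn_fwd(l1$y, p, nh, real)
  x2 <- x + at$y
  l2 <- ln_fwd(x2, p$ln2_g, p$ln2_b)
  ff <- ffn_fwd(l2$y, p)
  list(y = x2 + ff$y, cache = list(l1 = l1$cache, at = at$cache,
                                   l2 = l2$cache, ff = ff$cache))
}

enc_layer_bwd <- function(dy, p, cache) {
  fb <- ffn_bwd(dy, p, cache$ff)
  l2b <- ln_bwd(fb$dx, cache$l2)
  dx2 <- dy + l2b$dx
  ab <- attn_bwd(dx2, p, cache$at)
  l1b <- ln_bwd(ab$dx, cache$l1)
  dx <- dx2 + l1b$dx
  grads <- c(ab$grads, fb$grads,
             list(ln1_g = l1b$dg, ln1_b = l1b$db,
                  ln2_g = l2b$dg, ln2_b = l2b$db))
  list(dx = dx, grads = grads)
}

# ---- pairwise feature grid -------------------------------------------------

# h: L x d encoder states -> (L, L, 3d) grid with F[i, j, ] = [h_i, h_j, h_i*h_j]
pairwise_fwd <- function(h) {
  L <- nrow(h)
  d <- ncol(h)
  A <- array(h, c(L, d, L))                # A[i, k, j] = h[i, k]
  X1 <- aperm(A, c(1L, 3L, 2L))            # X1[i, j, k] = h[i, k]
  X2 <- aperm(A, c(3L, 1L, 2L))            # X2[i, j, k] = h[j, k]
  array(c(X1, X2, X1 * X2), c(L, L, 3L * d))
}

# sum an (L, L, d) gradient block over its second (j) index -> L x d
sum_over_j <- function(X) {
  L <- dim(X)[1L]
  d <- dim(X)[3L]
  matrix(rowSums(matrix(aperm(X, c(1L, 3L, 2L)), L * d, L)), L, d)
}

pairwise_bwd <- function(dF, h) {
  L <- nrow(h)
  d <- ncol(h)
  d1 <- dF[, , 1:d, drop = FALSE]
  d2 <- dF[, , (d + 1L):(2L * d), drop = FALSE]
  d3 <- dF[, , (2L * d + 1L):(3L * d), drop = FALSE]
  A <- array(h, c(L, d, L))
  X1 <- aperm(A, c(1L, 3L, 2L))
  X2 <- aperm(A, c(3L, 1L, 2L))
  # d2[i, j, k] flows to h[j, k]: transpose the (i, j) grid first
  sum_over_j(d1) + sum_over_j(aperm(d2, c(2L, 1L, 3L))) +
    sum_over_j(d3 * X2) + sum_over_j(aperm(d3 * X1, c(2L, 1L, 3L)))
}

# ---- convolutions and resampling ------------------------------------------

conv3_fwd <- function(x, W, b) {
  d <- dim(x)
  col <- im2col3_cpp(as.numeric(x), d[1L], d[2L], d[3L])
  y <- col %*% W + rep(b, each = d[1L] * d[2L])
  list(y = array(y, c(d[1L], d[2L], ncol(W))), cache = list(col = col, dim = d))
}

conv3_bwd <- function(dy, W, cache) {
  d <- cache$dim
  dY2 <- matrix(dy, d[1L] * d[2L], ncol(W))
  list(dx = array(col2im3_cpp(dY2 %*% t(W), d[1L], d[2L], d[3L]), d),
       dW = crossprod(cache$col, dY2), db = colSums(dY2))
}

relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dy, cache) dy * cache

avgpool2_fwd <- function(x) {
  d <- dim(x)
  o <- seq(1L, d[1L], 2L)
  e <- seq(2L, d[1L], 2L)
  (x[o, o, , drop = FALSE] + x[e, o, , drop = FALSE] +
     x[o, e, , drop = FALSE] + x[e, e, , drop = FALSE]) / 4
}

avgpool2_bwd <- function(dy, dims) {
  dx <- array(0, dims)
  o <- seq(1L, dims[1L], 2L)
  e <- seq(2L, dims[1L], 2L)
  q <- dy / 4
  dx[o, o, ] <- q; dx[e, o, ] <- q; dx[o, e, ] <- q; dx[e, e, ] <- q
  dx
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), ,
    drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  o <- seq(1L, d[1L], 2L)
  e <- seq(2L, d[1L], 2L)
  dy[o, o, , drop = FALSE] + dy[e, o, , drop = FALSE] +
    dy[o, e, , drop = FALSE] + dy[e, e, , drop = FALSE]
}

# zero every grid cell whose row or column lies wholly in the padded region;
# keeps the network's real-region output independent of the padding length
zero_beyond <- function(x, r) {
  n <- dim(x)[1L]
  if (r < n) {
    x[(r + 1L):n, , ] <- 0
    x[, (r + 1L):n, ] <- 0
  }
  x
}

concat_channels <- function(a, b) {
  da <- dim(a)
  array(c(a, b), c(da[1L], da[2L], da[3L] + dim(b)[3L]))
}

# ---- sinusoidal positional encoding ---------------------------------------

positional_encoding <- function(L, d) {
  pos <- seq_len(L)
  pe <- matrix(0, L, d)
  for (k in seq_len(ceiling(d / 2))) {
    freq <- 1 / 10000^((2 * (k - 1)) / d)
    pe[, 2L * k - 1L] <- sin(pos * freq)
    if (2L * k <= d) pe[, 2L * k] <- cos(pos * freq)
  }
  pe
}

# ---- Adam optimiser --------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
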