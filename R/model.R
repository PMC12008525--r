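# Scoring network: token embedding + sinusoidal positions -> pre-LN
# Transformer encoder -> pairwise feature grid [h_i, h_j, h_i*h_j] ->
# U-Net-style convolutional trunk -> one raw score matrix M per sequence.
# The published architecture's exact layer inventory is not public; this is a
# configurable network in the same Transformer + U-Net family, and nothing
# downstream depends on its details: the decoder guarantees valid output for
# any score matrix.

#' Scoring-network configuration
#'
#' @param embed_dim width of the token embedding / encoder states.
#' @param n_layers number of Transformer encoder layers.
#' @param n_heads attention heads (must divide `embed_dim`).
#' @param ff_dim hidden width of the position-wise feed-forward blocks.
#' @param unet_depth number of down/up resolution levels in the
#'   convolutional trunk; sequences are right-padded to a multiple of
#'   `2^unet_depth` so pooling halves cleanly.
#' @param base_channels channel count at the top U-Net level (doubled at
#'   each level down).
#' @param max_len maximum supported sequence length; must be a multiple of
#'   `2^unet_depth`.
#' @param dropout dropout rate on the attention and feed-forward branches
#'   during training.
#' @param seed seed for parameter initialization.
#' @return A validated config object of class `fold_config`.
#' @export
model_config <- function(embed_dim = 24L, n_layers = 2L, n_heads = 4L,
                         ff_dim = 48L, unet_depth = 1L, base_channels = 10L,
                         max_len = 512L, dropout = 0, seed = 1L) {
  cfg <- list(embed_dim = as.integer(embed_dim), n_layers = as.integer(n_layers),
              n_heads = as.integer(n_heads), ff_dim = as.integer(ff_dim),
              unet_depth = as.integer(unet_depth),
              base_channels = as.integer(base_channels),
              max_len = as.integer(max_len), dropout = dropout,
              seed = as.integer(seed))
  with(cfg, {
    if (any(c(embed_dim, n_layers, n_heads, ff_dim, base_channels, max_len) < 1L)
        || unet_depth < 0L)
      stop("config error: all dimensions must be positive", call. = FALSE)
    if (embed_dim %% n_heads != 0L)
      stop("config error: embed_dim must be divisible by n_heads", call. = FALSE)
    if (max_len %% 2L^unet_depth != 0L)
      stop("config error: max_len must be a multiple of 2^unet_depth ",
           "so pooling halves cleanly", call. = FALSE)
    if (dropout < 0 || dropout >= 1)
      stop("config error: dropout must be in [0, 1)", call. = FALSE)
  })
  structure(cfg, class = "fold_config")
}

init_mat <- function(nr, nc, fan_in = nr) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

#' Build a scoring network
#'
#' Parameter initialization is fully determined by `cfg$seed`: identical
#' configs give bitwise-identical networks. The total parameter count is
#' reported with a message.
#'
#' @param cfg a [model_config()].
#' @return An object of class `fold_model` holding the parameter list, the
#'   config, and a fresh optimiser state.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "fold_config"))
  set.seed(cfg$seed)
  d <- cfg$embed_dim
  p <- list(E = init_mat(4L, d, fan_in = 4L))
  for (l in seq_len(cfg$n_layers)) {
    nm <- function(s) paste0("L", l, ".", s)
    p[[nm("ln1_g")]] <- rep(1, d); p[[nm("ln1_b")]] <- rep(0, d)
    p[[nm("Wq")]] <- init_mat(d, d); p[[nm("bq")]] <- rep(0, d)
    p[[nm("Wk")]] <- init_mat(d, d); p[[nm("bk")]] <- rep(0, d)
    p[[nm("Wv")]] <- init_mat(d, d); p[[nm("bv")]] <- rep(0, d)
    p[[nm("Wo")]] <- init_mat(d, d); p[[nm("bo")]] <- rep(0, d)
    p[[nm("ln2_g")]] <- rep(1, d); p[[nm("ln2_b")]] <- rep(0, d)
    p[[nm("W1")]] <- init_mat(d, cfg$ff_dim); p[[nm("b1")]] <- rep(0, cfg$ff_dim)
    p[[nm("W2")]] <- init_mat(cfg$ff_dim, d); p[[nm("b2")]] <- rep(0, d)
  }
  p$lnf_g <- rep(1, d); p$lnf_b <- rep(0, d)
  ch <- cfg$base_channels * 2L^(0:cfg$unet_depth)
  p$enc0_W <- init_mat(9L * 3L * d, ch[1L]); p$enc0_b <- rep(0, ch[1L])
  for (k in seq_len(cfg$unet_depth)) {
    p[[paste0("down", k, "_W")]] <- init_mat(9L * ch[k], ch[k + 1L])
    p[[paste0("down", k, "_b")]] <- rep(0, ch[k + 1L])
    p[[paste0("up", k, "_W")]] <- init_mat(9L * (ch[k + 1L] + ch[k]), ch[k])
    p[[paste0("up", k, "_b")]] <- rep(0, ch[k])
  }
  p$head_W <- init_mat(ch[1L], 1L); p$head_b <- 0
  n_par <- sum(vapply(p, length, integer(1L)))
  message(sprintf("built scoring network: %d parameters", n_par))
  structure(list(params = p, cfg = cfg, opt = adam_init(p), n_params = n_par,
                 trace = numeric(0)), class = "fold_model")
}

#' @export
print.fold_model <- function(x, ...) {
  cat(sprintf("<fold_model> %d parameters (d = %d, %d encoder layers, U-Net depth %d)\n",
              x$n_params, x$cfg$embed_dim, x$cfg$n_layers, x$cfg$unet_depth))
  invisible(x)
}

one_hot_bases <- function(seq, Lp) {
  X <- matrix(0, Lp, 4L)
  idx <- match(seq_chars(seq), RNA_BASES)
  X[cbind(seq_along(idx), idx)] <- 1
  X
}

padded_length <- function(L, depth) {
  m <- 2L^depth
  as.integer(ceiling(L / m) * m)
}

# full forward pass for one sequence; returns raw real-block scores plus the
# cache needed for the backward pass
forward_single <- function(net, seq, Lp = NULL, train = FALSE) {
  cfg <- net$cfg
  p <- net$params
  L <- length(seq)
  if (L > cfg$max_len)
    stop(sprintf("sequence '%s' has length %d > configured maximum %d",
                 seq$id, L, cfg$max_len), call. = FALSE)
  if (is.null(Lp)) Lp <- padded_length(L, cfg$unet_depth)
  stopifnot(Lp >= L, Lp %% 2L^cfg$unet_depth == 0L)
  real <- c(rep(TRUE, L), rep(FALSE, Lp - L))
  X <- one_hot_bases(seq, Lp)
  h <- X %*% p$E
  h[real, ] <- h[real, , drop = FALSE] +
    positional_encoding(Lp, cfg$embed_dim)[real, , drop = FALSE]
  enc_caches <- vector("list", cfg$n_layers)
  drop_caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    lp <- p[paste0("L", l, ".", c("ln1_g", "ln1_b", "Wq", "bq", "Wk", "bk",
                                  "Wv", "bv", "Wo", "bo", "ln2_g", "ln2_b",
                                  "W1", "b1", "W2", "b2"))]
    names(lp) <- sub("^L[0-9]+\\.", "", names(lp))
    step <- enc_layer_fwd(h, lp, cfg$n_heads, real)
    h <- step$y
    if (train && cfg$dropout > 0) {
      mask <- matrix(stats::rbinom(length(h), 1L, 1 - cfg$dropout),
                     nrow(h), ncol(h)) / (1 - cfg$dropout)
      h <- h * mask
      drop_caches[[l]] <- mask
    }
    enc_caches[[l]] <- step$cache
  }
  lf <- ln_fwd(h, p$lnf_g, p$lnf_b)
  h <- lf$y
  h[!real, ] <- 0  # padded states carry nothing into the grid
  # real-region extent at each resolution level; all-pad cells are zeroed
  # after every operation so real-region scores are padding-invariant
  r_lvl <- c(L, ceiling(L / 2L^seq_len(cfg$unet_depth)))
  Fg <- zero_beyond(pairwise_fwd(h), L)
  c0 <- conv3_fwd(Fg, p$enc0_W, p$enc0_b)
  r0 <- relu_fwd(c0$y)
  g <- zero_beyond(r0$y, L)
  skips <- list(g)
  conv_caches <- list(c0$cache)
  relu_caches <- list(r0$cache)
  pool_dims <- list()
  for (k in seq_len(cfg$unet_depth)) {
    pool_dims[[k]] <- dim(g)
    pk <- zero_beyond(avgpool2_fwd(g), r_lvl[k + 1L])
    ck <- conv3_fwd(pk, p[[paste0("down", k, "_W")]], p[[paste0("down", k, "_b")]])
    rk <- relu_fwd(ck$y)
    g <- zero_beyond(rk$y, r_lvl[k + 1L])
    skips[[k + 1L]] <- g
    conv_caches[[k + 1L]] <- ck$cache
    relu_caches[[k + 1L]] <- rk$cache
  }
  up_conv_caches <- list()
  up_relu_caches <- list()
  up_in_channels <- list()
  for (k in rev(seq_len(cfg$unet_depth))) {
    u <- zero_beyond(upsample2_fwd(g), r_lvl[k])
    cat_in <- concat_channels(u, skips[[k]])
    up_in_channels[[k]] <- c(dim(u)[3L], dim(skips[[k]])[3L])
    ck <- conv3_fwd(cat_in, p[[paste0("up", k, "_W")]], p[[paste0("up", k, "_b")]])
    rk <- relu_fwd(ck$y)
    g <- zero_beyond(rk$y, r_lvl[k])
    up_conv_caches[[k]] <- ck$cache
    up_relu_caches[[k]] <- rk$cache
  }
  Umat <- matrix(g, Lp * Lp, dim(g)[3L])
  M <- matrix(Umat %*% p$head_W + p$head_b, Lp, Lp)
  list(M = M[seq_len(L), seq_len(L), drop = FALSE],
       cache = list(L = L, Lp = Lp, real = real, X = X, h = h,
                    enc_caches = enc_caches, drop_caches = drop_caches,
                    lf = lf$cache, Fg_dim = dim(Fg),
                    conv_caches = conv_caches, relu_caches = relu_caches,
                    pool_dims = pool_dims, r_lvl = r_lvl,
                    up_conv_caches = up_conv_caches,
                    up_relu_caches = up_relu_caches,
                    up_in_channels = up_in_channels, Umat = Umat,
                    g_dim = dim(g)))
}

# backward pass: dM is the gradient on the real-block raw scores
backward_single <- function(net, fwd, dM) {
  cfg <- net$cfg
  p <- net$params
  cc <- fwd$cache
  Lp <- cc$Lp
  grads <- list()
  dMfull <- matrix(0, Lp, Lp)
  dMfull[seq_len(cc$L), seq_len(cc$L)] <- dM
  dvec <- matrix(as.numeric(dMfull), Lp * Lp, 1L)
  grads$head_W <- crossprod(cc$Umat, dvec)
  grads$head_b <- sum(dvec)
  dg <- array(dvec %*% t(p$head_W), cc$g_dim)
  # up convs were applied in order k = depth..1, so walk back in order 1..depth;
  # every zero_beyond projection in the forward pass is self-adjoint and must
  # be mirrored here at the same point
  r_lvl <- cc$r_lvl
  skip_grads <- vector("list", cfg$unet_depth)
  for (k in seq_len(cfg$unet_depth)) {
    dg <- zero_beyond(dg, r_lvl[k])
    dg <- relu_bwd(dg, cc$up_relu_caches[[k]])
    cb <- conv3_bwd(dg, p[[paste0("up", k, "_W")]], cc$up_conv_caches[[k]])
    grads[[paste0("up", k, "_W")]] <- cb$dW
    grads[[paste0("up", k, "_b")]] <- cb$db
    nu <- cc$up_in_channels[[k]][1L]
    skip_grads[[k]] <- cb$dx[, , nu + seq_len(cc$up_in_channels[[k]][2L]),
                             drop = FALSE]
    dg <- upsample2_bwd(zero_beyond(cb$dx[, , seq_len(nu), drop = FALSE],
                                    r_lvl[k]))
  }
  # dg now sits at the bottom encoder output; walk back up the encoder path,
  # adding each level's skip-connection gradient after unpooling
  for (k in rev(seq_len(cfg$unet_depth))) {
    dg <- zero_beyond(dg, r_lvl[k + 1L])
    dg <- relu_bwd(dg, cc$relu_caches[[k + 1L]])
    cb <- conv3_bwd(dg, p[[paste0("down", k, "_W")]], cc$conv_caches[[k + 1L]])
    grads[[paste0("down", k, "_W")]] <- cb$dW
    grads[[paste0("down", k, "_b")]] <- cb$db
    dg <- avgpool2_bwd(zero_beyond(cb$dx, r_lvl[k + 1L]), cc$pool_dims[[k]]) +
      skip_grads[[k]]
  }
  dg <- zero_beyond(dg, r_lvl[1L])
  dg <- relu_bwd(dg, cc$relu_caches[[1L]])
  cb <- conv3_bwd(dg, p$enc0_W, cc$conv_caches[[1L]])
  grads$enc0_W <- cb$dW
  grads$enc0_b <- cb$db
  dh <- pairwise_bwd(zero_beyond(cb$dx, r_lvl[1L]), cc$h)
  dh[!cc$real, ] <- 0
  lfb <- ln_bwd(dh, cc$lf)
  grads$lnf_g <- lfb$dg
  grads$lnf_b <- lfb$db
  dh <- lfb$dx
  for (l in rev(seq_len(cfg$n_layers))) {
    lp <- p[paste0("L", l, ".", c("ln1_g", "ln1_b", "Wq", "bq", "Wk", "bk",
                                  "Wv", "bv", "Wo", "bo", "ln2_g", "ln2_b",
                                  "W1", "b1", "W2", "b2"))]
    names(lp) <- sub("^L[0-9]+\\.", "", names(lp))
    if (!is.null(cc$drop_caches[[l]])) dh <- dh * cc$drop_caches[[l]]
    lb <- enc_layer_bwd(dh, lp, cc$enc_caches[[l]])
    dh <- lb$dx
    for (nm in names(lb$grads)) grads[[paste0("L", l, ".", nm)]] <- lb$grads[[nm]]
  }
  grads$E <- crossprod(cc$X, dh)
  grads
}
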