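#' Architecture settings of the segment scorer
#'
#' The feature extractor has a deep path (four 1-D conv blocks, kernel 5,
#' widths 16-32-64-64, each batch-norm + ReLU + max-pool 2) over the 2x180
#' 1-min input and a shallow path (two conv blocks, kernel 11, widths 16-32,
#' max-pool 4) over the 2x900 5-min input. Both paths are global-average
#' pooled per channel, concatenated, passed through squeeze-and-excitation
#' channel attention (reduction 8) and a fully connected layer to a
#' 128-dimensional feature vector. A gated recurrent unit (hidden 128,
#' unidirectional by default) processes the per-recording feature sequence;
#' a final fully connected layer and sigmoid yield one score per 10-s step.
#'
#' @param fd_channels,fd_kernel,fd_pool deep-path widths, kernel, pool.
#' @param fs_channels,fs_kernel,fs_pool shallow-path widths, kernel, pool.
#' @param se_reduction squeeze-and-excitation reduction ratio.
#' @param feature_dim length of the per-step feature vector.
#' @param gru_hidden,gru_layers GRU hidden size and layer count (1 supported).
#' @param bidirectional run a second GRU over the reversed sequence and
#'   concatenate.
#' @param dropout dropout rate on the GRU output during training.
#' @return an object of class `model_config`.
#' @export
model_config <- function(fd_channels = c(16L, 32L, 64L, 64L), fd_kernel = 5L,
                         fd_pool = 2L,
                         fs_channels = c(16L, 32L), fs_kernel = 11L,
                         fs_pool = 4L,
                         se_reduction = 8L, feature_dim = 128L,
                         gru_hidden = 128L, gru_layers = 1L,
                         bidirectional = FALSE, dropout = 0.1) {
  stopifnot(all(fd_channels > 0), all(fs_channels > 0),
            fd_kernel %% 2 == 1, fs_kernel %% 2 == 1,
            se_reduction >= 1, feature_dim > 0, gru_hidden > 0,
            gru_layers == 1L, dropout >= 0, dropout < 1)
  structure(list(fd_channels = as.integer(fd_channels),
                 fd_kernel = as.integer(fd_kernel),
                 fd_pool = as.integer(fd_pool),
                 fs_channels = as.integer(fs_channels),
                 fs_kernel = as.integer(fs_kernel),
                 fs_pool = as.integer(fs_pool),
                 se_reduction = as.integer(se_reduction),
                 feature_dim = as.integer(feature_dim),
                 gru_hidden = as.integer(gru_hidden),
                 gru_layers = 1L,
                 bidirectional = isTRUE(bidirectional),
                 dropout = dropout),
            class = "model_config")
}

he_init <- function(nrow, ncol) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / ncol)), nrow, ncol)
}

init_conv_path <- function(channels, k, in_ch) {
  path <- vector("list", length(channels))
  cin <- in_ch
  for (l in seq_along(channels)) {
    path[[l]] <- list(W = he_init(channels[l], cin * k),
                      gamma = rep(1, channels[l]),
                      beta = rep(0, channels[l]))
    cin <- channels[l]
  }
  path
}

init_gru <- function(input_dim, hidden) {
  s <- sqrt(1 / hidden)
  list(Wx = matrix(runif(3 * hidden * input_dim, -s, s), 3 * hidden, input_dim),
       Wh = matrix(runif(3 * hidden * hidden, -s, s), 3 * hidden, hidden),
       bx = rep(0, 3 * hidden),
       bh = rep(0, 3 * hidden))
}

#' Instantiate an untrained segment-scoring model
#'
#' Builds the parameter set of the architecture described in
#' [model_config()], with He-initialised convolutions and uniform GRU
#' initialisation. Normalisation statistics default to the identity until a
#' training run supplies them.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialisation.
#' @return an object of class `apnea_model`.
#' @export
apnea_model <- function(config = model_config(), seed = 1L) {
  set.seed(derive_seed(seed, 101L))
  c_total <- tail(config$fd_channels, 1L) + tail(config$fs_channels, 1L)
  c_mid <- max(1L, c_total %/% config$se_reduction)
  params <- list(
    fd = init_conv_path(config$fd_channels, config$fd_kernel, 2L),
    fs = init_conv_path(config$fs_channels, config$fs_kernel, 2L),
    se = list(W1 = he_init(c_mid, c_total), b1 = rep(0, c_mid),
              W2 = he_init(c_total, c_mid), b2 = rep(0, c_total)),
    fc1 = list(W = he_init(config$feature_dim, c_total),
               b = rep(0, config$feature_dim)),
    gru = init_gru(config$feature_dim, config$gru_hidden),
    fc2 = list(W = matrix(rnorm((1 + config$bidirectional) *
                                  config$gru_hidden, 0,
                                sqrt(1 / config$gru_hidden)),
                          nrow = 1L),
               b = 0)
  )
  if (config$bidirectional) {
    params$gru_rev <- init_gru(config$feature_dim, config$gru_hidden)
  }
  bn_state <- list(
    fd = lapply(config$fd_channels,
                function(ch) list(mean = rep(0, ch), var = rep(1, ch))),
    fs = lapply(config$fs_channels,
                function(ch) list(mean = rep(0, ch), var = rep(1, ch)))
  )
  structure(list(params = params, bn_state = bn_state, config = config,
                 norm = list(mean = c(r1_rri = 0, r1_rpa = 0,
                                      r5_rri = 0, r5_rpa = 0),
                             sd = c(r1_rri = 1, r1_rpa = 1,
                                    r5_rri = 1, r5_rpa = 1)),
                 trained = FALSE),
            class = "apnea_model")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- convolution blocks -------------------------------------------------

# Forward through one conv + batch-norm + ReLU + max-pool block.
# X: array (C_in, L, M). The convolution is an im2col unfold followed by one
# BLAS matrix product; normalisation, rectification and pooling run in the
# fused compiled kernel. Returns pooled activations and, when `cache`,
# everything the backward pass needs.
conv_block_forward <- function(X, par, bn, k, pool, train, cache = FALSE,
                               bn_eps = 1e-5, bn_momentum = 0.1) {
  d <- dim(X)
  C_in <- d[1]; L <- d[2]; M <- d[3]
  pad <- (k - 1L) %/% 2L
  col <- im2col1d(as.numeric(X), C_in, L, M, k, pad)
  Z <- par$W %*% col
  C_out <- nrow(Z)
  f <- bn_relu_pool_fwd(Z, C_out, L, M, par$gamma, par$beta,
                        bn$mean, bn$var, train, bn_eps, pool)
  new_bn <- if (train) {
    list(mean = (1 - bn_momentum) * bn$mean + bn_momentum * f$mu,
         var = (1 - bn_momentum) * bn$var + bn_momentum * f$var)
  } else {
    bn
  }
  Y <- f$Y
  dim(Y) <- c(C_out, L %/% pool, M)
  out <- list(Y = Y, bn = new_bn)
  if (cache) {
    out$cache <- list(col = col, dims = d, Z = Z, mu = f$mu, ivar = f$ivar,
                      arg = f$arg, k = k, pool = pool,
                      pad = pad, L = L, M = M, C_out = C_out, train = train)
  }
  out
}

conv_block_backward <- function(dY, par, cache, need_dx = TRUE) {
  dim(dY) <- c(cache$C_out, length(dY) / cache$C_out)
  b <- bn_relu_pool_bwd(dY, cache$arg, cache$Z, cache$mu, par$gamma,
                        par$beta, cache$ivar, cache$C_out, cache$L, cache$M,
                        cache$pool, cache$train)
  dX <- NULL
  if (need_dx) {
    dcol <- crossprod(par$W, b$dZ)
    d_in <- cache$dims
    dX <- col2im1d(dcol, d_in[1], d_in[2], d_in[3], cache$k, cache$pad)
    dim(dX) <- d_in
  }
  dW <- tcrossprod(b$dZ, cache$col)
  list(dX = dX, grads = list(W = dW, gamma = b$dgamma, beta = b$dbeta))
}

gap_forward <- function(A) {
  colMeans(aperm(A, c(2L, 1L, 3L)))  # (C, M)
}

gap_backward <- function(dF, L) {
  C <- nrow(dF); M <- ncol(dF)
  aperm(array(dF / L, dim = c(C, M, L)), c(1L, 3L, 2L))
}

# ---- feature extractor --------------------------------------------------

# X1: (2, 180, M), X5: (2, 900, M) already normalised.
extractor_forward <- function(params, bn_state, config, X1, X5,
                              train = FALSE, cache = FALSE) {
  caches <- list(fd = list(), fs = list())
  run_path <- function(X, path, bns, k, pool) {
    cs <- list()
    for (l in seq_along(path)) {
      r <- conv_block_forward(X, path[[l]], bns[[l]], k, pool, train, cache)
      X <- r$Y
      bns[[l]] <- r$bn
      if (cache) cs[[l]] <- r$cache
    }
    list(Y = X, bns = bns, caches = cs)
  }
  fd <- run_path(X1, params$fd, bn_state$fd, config$fd_kernel, config$fd_pool)
  fs <- run_path(X5, params$fs, bn_state$fs, config$fs_kernel, config$fs_pool)
  Fd <- gap_forward(fd$Y)
  Fs <- gap_forward(fs$Y)
  Fc <- rbind(Fd, Fs)                       # (C_total, M)
  z1 <- params$se$W1 %*% Fc + params$se$b1
  z1[z1 < 0] <- 0
  att <- sigmoid(params$se$W2 %*% z1 + params$se$b2)
  Fa <- Fc * att
  H <- params$fc1$W %*% Fa + params$fc1$b
  H[H < 0] <- 0
  out <- list(H = H, bn_state = list(fd = fd$bns, fs = fs$bns))
  if (cache) {
    out$cache <- list(fd = fd$caches, fs = fs$caches,
                      fd_L = dim(fd$Y)[2], fs_L = dim(fs$Y)[2],
                      n_fd = nrow(Fd), Fc = Fc, z1 = z1, att = att,
                      Fa = Fa, H = H)
  }
  out
}

extractor_backward <- function(params, config, cache, dH) {
  dH <- dH * (cache$H > 0)
  g_fc1 <- list(W = tcrossprod(dH, cache$Fa), b = rowSums(dH))
  dFa <- crossprod(params$fc1$W, dH)
  datt <- dFa * cache$Fc
  dFc <- dFa * cache$att
  ds2 <- datt * cache$att * (1 - cache$att)
  g_se <- list(W1 = NULL, b1 = NULL,
               W2 = tcrossprod(ds2, cache$z1), b2 = rowSums(ds2))
  dz1 <- crossprod(params$se$W2, ds2)
  dz1[cache$z1 <= 0] <- 0
  g_se$W1 <- tcrossprod(dz1, cache$Fc)
  g_se$b1 <- rowSums(dz1)
  dFc <- dFc + crossprod(params$se$W1, dz1)
  n_fd <- cache$n_fd
  dFd <- dFc[seq_len(n_fd), , drop = FALSE]
  dFs <- dFc[-seq_len(n_fd), , drop = FALSE]
  back_path <- function(dTop, path, caches, L_top) {
    dY <- gap_backward(dTop, L_top)
    gs <- vector("list", length(path))
    for (l in rev(seq_along(path))) {
      r <- conv_block_backward(dY, path[[l]], caches[[l]], need_dx = l > 1L)
      gs[[l]] <- r$grads
      dY <- r$dX
    }
    gs
  }
  list(fd = back_path(dFd, params$fd, cache$fd, cache$fd_L),
       fs = back_path(dFs, params$fs, cache$fs, cache$fs_L),
       se = g_se, fc1 = g_fc1)
}

# ---- GRU ----------------------------------------------------------------

# H: (D, T, B). Gate order along rows of Wx/Wh: reset, update, candidate
# (PyTorch convention: n = tanh(Wxn x + bxn + r * (Whn h + bhn))).
gru_forward <- function(H, par, cache = FALSE) {
  d <- dim(H)
  D <- d[1]; TT <- d[2]; B <- d[3]
  hid <- length(par$bx) / 3L
  ir <- seq_len(hid); iz <- ir + hid; inn <- iz + hid
  h <- matrix(0, hid, B)
  hs <- array(0, dim = c(hid, TT, B))
  cc <- if (cache) {
    list(r = array(0, dim = c(hid, TT, B)), z = array(0, dim = c(hid, TT, B)),
         n = array(0, dim = c(hid, TT, B)),
         ghn = array(0, dim = c(hid, TT, B)),
         hprev = array(0, dim = c(hid, TT, B)))
  }
  # precompute the input projection for every step at once
  Hm <- matrix(H, nrow = D)
  GX <- par$Wx %*% Hm + par$bx             # (3*hid, T*B)
  dim(GX) <- c(3L * hid, TT, B)
  for (t in seq_len(TT)) {
    gx <- matrix(GX[, t, ], nrow = 3L * hid)
    gh <- par$Wh %*% h + par$bh
    r <- sigmoid(gx[ir, , drop = FALSE] + gh[ir, , drop = FALSE])
    z <- sigmoid(gx[iz, , drop = FALSE] + gh[iz, , drop = FALSE])
    ghn <- gh[inn, , drop = FALSE]
    n <- tanh(gx[inn, , drop = FALSE] + r * ghn)
    if (cache) {
      cc$r[, t, ] <- r; cc$z[, t, ] <- z; cc$n[, t, ] <- n
      cc$ghn[, t, ] <- ghn; cc$hprev[, t, ] <- h
    }
    h <- (1 - z) * n + z * h
    hs[, t, ] <- h
  }
  list(hs = hs, cache = cc)
}

gru_backward <- function(dHs, H, par, cache) {
  d <- dim(dHs)
  hid <- d[1]; TT <- d[2]; B <- d[3]
  D <- dim(H)[1]
  g <- list(Wx = matrix(0, 3 * hid, D), Wh = matrix(0, 3 * hid, hid),
            bx = rep(0, 3 * hid), bh = rep(0, 3 * hid))
  dX <- array(0, dim = dim(H))
  dh <- matrix(0, hid, B)
  for (t in rev(seq_len(TT))) {
    dh <- dh + matrix(dHs[, t, ], hid, B)
    r <- matrix(cache$r[, t, ], hid, B)
    z <- matrix(cache$z[, t, ], hid, B)
    n <- matrix(cache$n[, t, ], hid, B)
    ghn <- matrix(cache$ghn[, t, ], hid, B)
    hprev <- matrix(cache$hprev[, t, ], hid, B)
    dz <- dh * (hprev - n)
    dn <- dh * (1 - z)
    dh_next <- dh * z
    dn_pre <- dn * (1 - n^2)
    dr <- dn_pre * ghn
    dgx <- rbind(dr * r * (1 - r), dz * z * (1 - z), dn_pre)
    dgh <- rbind(dr * r * (1 - r), dz * z * (1 - z), dn_pre * r)
    x_t <- matrix(H[, t, ], D, B)
    g$Wx <- g$Wx + tcrossprod(dgx, x_t)
    g$Wh <- g$Wh + tcrossprod(dgh, hprev)
    g$bx <- g$bx + rowSums(dgx)
    g$bh <- g$bh + rowSums(dgh)
    dX[, t, ] <- crossprod(par$Wx, dgx)
    dh <- dh_next + crossprod(par$Wh, dgh)
  }
  list(grads = g, dX = dX)
}

# Run the (optionally bidirectional) sequence processor; Hseq (D, T, B).
sequence_forward <- function(params, config, Hseq, cache = FALSE) {
  fw <- gru_forward(Hseq, params$gru, cache)
  if (!config$bidirectional) {
    return(list(G = fw$hs, fw = fw, bw = NULL))
  }
  TT <- dim(Hseq)[2]
  rev_idx <- rev(seq_len(TT))
  bw <- gru_forward(Hseq[, rev_idx, , drop = FALSE], params$gru_rev, cache)
  hs_b <- bw$hs[, rev_idx, , drop = FALSE]
  hid <- dim(fw$hs)[1]
  G <- array(0, dim = c(2L * hid, TT, dim(Hseq)[3]))
  G[seq_len(hid), , ] <- fw$hs
  G[hid + seq_len(hid), , ] <- hs_b
  list(G = G, fw = fw, bw = bw)
}

# ---- normalisation and whole-network forward ----------------------------

normalize_inputs <- function(model, r1, r5) {
  nm <- model$norm
  r1[1L, , ] <- (r1[1L, , ] - nm$mean[["r1_rri"]]) / nm$sd[["r1_rri"]]
  r1[2L, , ] <- (r1[2L, , ] - nm$mean[["r1_rpa"]]) / nm$sd[["r1_rpa"]]
  r5[1L, , ] <- (r5[1L, , ] - nm$mean[["r5_rri"]]) / nm$sd[["r5_rri"]]
  r5[2L, , ] <- (r5[2L, , ] - nm$mean[["r5_rpa"]]) / nm$sd[["r5_rpa"]]
  list(r1 = r1, r5 = r5)
}

#' Extract per-step feature vectors
#'
#' Runs the dual-path extractor in evaluation mode on one window pair or a
#' batch of them, returning the fused, attention-weighted feature vector(s)
#' of length `feature_dim`.
#'
#' @param model an `apnea_model` (or fitted `apnea_scorer`).
#' @param r1 2x180 matrix or 2x180xM array (1-min windows).
#' @param r5 2x900 matrix or 2x900xM array (5-min windows).
#' @return a `feature_dim` x M matrix (a plain vector when M = 1).
#' @export
extract_features <- function(model, r1, r5) {
  model <- as_apnea_model(model)
  if (length(dim(r1)) == 2L) dim(r1) <- c(dim(r1), 1L)
  if (length(dim(r5)) == 2L) dim(r5) <- c(dim(r5), 1L)
  cfg <- model$config
  if (!all(dim(r1)[1:2] == c(2L, 180L)) || !all(dim(r5)[1:2] == c(2L, 900L))) {
    stop("window shapes must be 2x180 (1-min) and 2x900 (5-min)")
  }
  if (!all(is.finite(r1)) || !all(is.finite(r5))) {
    stop("window values must be finite")
  }
  nx <- normalize_inputs(model, r1, r5)
  H <- extractor_forward(model$params, model$bn_state, cfg,
                         nx$r1, nx$r5, train = FALSE)$H
  if (ncol(H) == 1L) drop(H) else H
}

#' Score a feature sequence
#'
#' Applies the sequence processor (GRU) and the final fully connected layer
#' with a logistic sigmoid to a sequence of feature vectors, yielding one
#' event score per step.
#'
#' @param model an `apnea_model` (or fitted `apnea_scorer`).
#' @param H `feature_dim` x N matrix of per-step features.
#' @param mask optional logical vector of valid steps (scores are produced
#'   for every step regardless; the mask is echoed for downstream use).
#' @return list with `scores` (in (0,1)), `logits`, and `mask`.
#' @export
score_sequence <- function(model, H, mask = NULL) {
  model <- as_apnea_model(model)
  if (is.null(dim(H)) || ncol(H) == 0L) stop("empty feature sequence")
  TT <- ncol(H)
  Hseq <- array(H, dim = c(nrow(H), TT, 1L))
  G <- sequence_forward(model$params, model$config, Hseq)$G
  Gm <- matrix(G, nrow = dim(G)[1])
  o <- as.numeric(model$params$fc2$W %*% Gm + model$params$fc2$b)
  list(scores = sigmoid(o), logits = o,
       mask = mask %||% rep(TRUE, TT))
}

# Forward one recording sequence (eval mode): chunked feature extraction,
# then the sequence processor.
forward_sequence <- function(model, s, chunk = 1024L) {
  model <- as_apnea_model(model)
  TT <- s$n
  H <- matrix(0, model$config$feature_dim, TT)
  nx <- normalize_inputs(model, s$r1, s$r5)
  for (i0 in seq(1L, TT, by = chunk)) {
    i1 <- min(TT, i0 + chunk - 1L)
    H[, i0:i1] <- extractor_forward(
      model$params, model$bn_state, model$config,
      nx$r1[, , i0:i1, drop = FALSE], nx$r5[, , i0:i1, drop = FALSE],
      train = FALSE)$H
  }
  score_sequence(model, H)
}

as_apnea_model <- function(x) {
  if (inherits(x, "apnea_scorer")) x$model else x
}

#' Predict segment scores for recording sequences
#'
#' @param object an `apnea_model`.
#' @param newdata an `apnea_dataset` (or a single sequence from one).
#' @param ... unused.
#' @return named list of per-recording numeric score vectors.
#' @export
predict.apnea_model <- function(object, newdata, ...) {
  if (!inherits(newdata, "apnea_dataset")) {
    if (!is.null(newdata$r1)) newdata <- structure(list(seq = newdata),
                                                   class = "apnea_dataset")
    else stop("newdata must be an apnea_dataset")
  }
  out <- lapply(newdata, function(s) forward_sequence(object, s)$scores)
  names(out) <- vapply(newdata, `[[`, character(1), "record_id")
  out
}

#' @export
print.apnea_model <- function(x, ...) {
  cfg <- x$config
  cat("<apnea_model>",
      if (x$trained) "(trained)" else "(untrained)", "\n")
  cat(sprintf("  deep path: %s (k=%d), shallow path: %s (k=%d)\n",
              paste(cfg$fd_channels, collapse = "-"), cfg$fd_kernel,
              paste(cfg$fs_channels, collapse = "-"), cfg$fs_kernel))
  cat(sprintf("  SE fusion (r=%d) -> fc %d; GRU hidden %d%s, dropout %.2f\n",
              cfg$se_reduction, cfg$feature_dim, cfg$gru_hidden,
              if (cfg$bidirectional) " (bidirectional)" else "",
              cfg$dropout))
  cat("  parameters:", n_parameters(x$params), "\n")
  invisible(x)
}

n_parameters <- function(p) {
  if (is.list(p)) sum(vapply(p, n_parameters, numeric(1))) else length(p)
}

# ---- parameter-tree utilities (shared with the optimiser) ---------------

tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    out <- vector("list", length(trees[[1]]))
    names(out) <- names(trees[[1]])
    for (i in seq_along(out)) {
      out[[i]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

tree_zeros_like <- function(p) tree_map(function(x) x * 0, p)
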