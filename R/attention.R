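# Cascaded hybrid (channel + spatial) attention. The channel gate squeezes
# each channel to average- and max-pooled descriptors, passes both through a
# shared two-layer MLP and sigmoids the sum ("what"); the spatial gate stacks
# the channel-wise mean and max maps, convolves them k x k and sigmoids the
# result ("where"). The gates are applied in cascade: F' = g_c(F) * F,
# M = g_s(F') * F'. Feature maps are (H, W, C, N) arrays throughout.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Attention parameters
#'
#' Holds the shared-MLP weights of the channel gate (bottleneck width
#' `channels / reduction_ratio`) and the k x k convolution of the spatial
#' gate (2 input channels -> 1 output).
#'
#' @param channels Number of feature-map channels C at the insertion point.
#' @param reduction_ratio Bottleneck reduction of the shared MLP (default 4,
#'   giving a nondegenerate hidden width at the 16-channel insertion point).
#' @param spatial_kernel Odd spatial kernel size k (default 7).
#' @param init `"zero"` (all weights and biases zero; both gates are then
#'   exactly 0.5 everywhere) or `"he"` (seeded random initialization).
#' @param seed Seed for `init = "he"`.
#' @return An object of class `"attention_params"`.
#' @export
attention_params <- function(channels, reduction_ratio = 4L,
                             spatial_kernel = 7L, init = c("zero", "he"),
                             seed = 1L) {
  init <- match.arg(init)
  k <- as.integer(spatial_kernel)
  if (k %% 2L == 0L || k < 1L) stop("spatial_kernel must be odd and >= 1")
  hidden <- max(1L, channels %/% as.integer(reduction_ratio))
  p <- list(
    W1 = matrix(0, hidden, channels), b1 = numeric(hidden),
    W2 = matrix(0, channels, hidden), b2 = numeric(channels),
    Ws = array(0, dim = c(k, k, 2L, 1L)), bs = numeric(1)
  )
  if (init == "he") {
    set.seed(seed)
    p$W1[] <- stats::rnorm(length(p$W1), 0, sqrt(2 / channels))
    p$W2[] <- stats::rnorm(length(p$W2), 0, sqrt(2 / hidden))
    p$Ws[] <- stats::rnorm(length(p$Ws), 0, sqrt(2 / (2 * k * k)))
  }
  structure(c(p, list(channels = as.integer(channels), hidden = hidden,
                      k = k)),
            class = "attention_params")
}

as_nchw <- function(F) {
  if (length(dim(F)) == 3L) array(F, dim = c(dim(F), 1L))
  else if (length(dim(F)) == 4L) F
  else stop("feature map must be (H, W, C) or (H, W, C, N)")
}

# channel-wise spatial pooling: (H,W,C,N) -> C x N
pool_spatial <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  list(avg = matrix(colMeans(m), d[3], d[4]),
       mx = matrix(apply(m, 2, max), d[3], d[4]),
       arg = apply(m, 2, which.max))
}

# per-pixel channel pooling: (H,W,C,N) -> (H,W,1,N) maps
pool_channel <- function(x) {
  d <- dim(x)
  Y <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  mx <- Y[, 1]; arg <- rep(1L, nrow(Y))
  if (d[3] > 1L) for (c in 2:d[3]) {
    upd <- Y[, c] > mx
    mx[upd] <- Y[upd, c]; arg[upd] <- c
  }
  list(avg = array(rowMeans(Y), c(d[1], d[2], 1L, d[4])),
       mx = array(mx, c(d[1], d[2], 1L, d[4])),
       arg = arg)
}

bcast_channel_gate <- function(g, H, W) {
  array(rep(as.vector(g), each = H * W), c(H, W, nrow(g), ncol(g)))
}

bcast_spatial_gate <- function(G, C) {
  d <- dim(G)
  aperm(array(as.vector(G), c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
}

mlp_fwd <- function(params, v) {
  h <- pmax(params$W1 %*% v + params$b1, 0)
  list(h = h, z = params$W2 %*% h + params$b2)
}

#' Channel attention gate
#'
#' `sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))` where the pooling collapses
#' H x W to one scalar per channel and the two branches share MLP weights.
#'
#' @param F Feature map, `(H, W, C)` or `(H, W, C, N)` array.
#' @param params An [attention_params()] dimensioned for C.
#' @return Gate values in (0, 1): a length-C vector (3D input) or C x N
#'   matrix (4D input).
#' @export
channel_gate <- function(F, params) {
  x <- as_nchw(F)
  if (dim(x)[3] != params$channels)
    stop(sprintf("feature map has %d channels, params expect %d",
                 dim(x)[3], params$channels))
  ps <- pool_spatial(x)
  g <- sigmoid(mlp_fwd(params, ps$avg)$z + mlp_fwd(params, ps$mx)$z)
  if (length(dim(F)) == 3L) as.vector(g) else g
}

#' Spatial attention gate
#'
#' `sigmoid(conv_k([mean over channels; max over channels]))` with same
#' padding, so the gate has the feature map's spatial extent.
#'
#' @inheritParams channel_gate
#' @return Gate values in (0, 1): an H x W matrix (3D input) or
#'   `(H, W, 1, N)` array (4D input).
#' @export
spatial_gate <- function(F, params) {
  x <- as_nchw(F)
  pc <- pool_channel(x)
  d <- dim(x)
  S <- array(0, c(d[1], d[2], 2L, d[4]))
  S[, , 1L, ] <- pc$avg
  S[, , 2L, ] <- pc$mx
  s <- .conv2d_fwd(S, params$Ws, params$bs, 1L, (params$k - 1L) %/% 2L)
  G <- sigmoid(s)
  if (length(dim(F)) == 3L) matrix(G, d[1], d[2]) else G
}

#' Apply the cascaded hybrid attention block
#'
#' Channel gate first (`F' = g_c(F) * F`, gate broadcast over space), then
#' spatial gate on the channel-refined map (`M = g_s(F') * F'`, gate
#' broadcast over channels). Shape is preserved. With zero-initialized
#' parameters both gates are exactly 0.5, so the block scales its input by
#' 0.25.
#'
#' @inheritParams channel_gate
#' @param spatial_on_original If `TRUE`, the spatial gate is computed from
#'   (and multiplied into) the original `F` instead of the channel-refined
#'   map — an ablation variant.
#' @param disable If `TRUE` both gates are forced to 1 (identity block).
#' @return Re-weighted feature map, same shape as `F`.
#' @export
apply_hybrid <- function(F, params, spatial_on_original = FALSE,
                         disable = FALSE) {
  if (disable) return(F)
  x <- as_nchw(F)
  out <- att_forward(x, params, spatial_on_original)$out
  if (length(dim(F)) == 3L) array(out, dim(F)) else out
}

# forward with cache for backprop
att_forward <- function(x, params, spatial_on_original = FALSE) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  ps <- pool_spatial(x)
  ma <- mlp_fwd(params, ps$avg)
  mm <- mlp_fwd(params, ps$mx)
  g <- sigmoid(ma$z + mm$z)
  gb <- bcast_channel_gate(g, H, W)
  Fp <- x * gb

  base <- if (spatial_on_original) x else Fp
  pc <- pool_channel(base)
  S <- array(0, c(H, W, 2L, N))
  S[, , 1L, ] <- pc$avg
  S[, , 2L, ] <- pc$mx
  s <- .conv2d_fwd(S, params$Ws, params$bs, 1L, (params$k - 1L) %/% 2L)
  G <- sigmoid(s)
  Gb <- bcast_spatial_gate(G, C)
  list(out = Fp * Gb,
       cache = list(x = x, ps = ps, ma = ma, mm = mm, g = g, gb = gb,
                    Fp = Fp, pc = pc, S = S, G = G, Gb = Gb,
                    spatial_on_original = spatial_on_original))
}

att_backward <- function(dout, cache, params) {
  x <- cache$x
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  HW <- H * W
  base <- if (cache$spatial_on_original) x else cache$Fp

  # spatial gate branch
  dFp <- dout * cache$Gb
  Tm <- matrix(aperm(dout * cache$Fp, c(1, 2, 4, 3)), HW * N, C)
  dG <- array(rowSums(Tm), c(H, W, 1L, N))
  ds <- dG * cache$G * (1 - cache$G)
  cb <- .conv2d_bwd(cache$S, params$Ws, ds, 1L, (params$k - 1L) %/% 2L)
  dS <- cb$dx
  davg <- array(dS[, , 1L, ], c(H, W, 1L, N))
  dmax <- array(dS[, , 2L, ], c(H, W, 1L, N))
  dbase <- bcast_spatial_gate(davg, C) / C
  # scatter the max-branch gradient to the argmax channel per pixel
  r <- seq_len(HW * N)
  hw <- (r - 1L) %% HW + 1L
  n <- (r - 1L) %/% HW
  pos <- hw + HW * (cache$pc$arg - 1L) + HW * C * n
  dbase_vec <- as.vector(dbase)
  dbase_vec[pos] <- dbase_vec[pos] + as.vector(dmax)
  dbase <- array(dbase_vec, d)

  if (cache$spatial_on_original) {
    dx_extra <- dbase
  } else {
    dFp <- dFp + dbase
    dx_extra <- 0
  }

  # channel gate branch
  dx <- dFp * cache$gb
  dg <- matrix(colSums(matrix(dFp * x, HW, C * N)), C, N)
  dz <- dg * cache$g * (1 - cache$g)

  grad_branch <- function(m, v) {
    dh <- crossprod(params$W2, dz) * (m$h > 0)
    list(dW2 = dz %*% t(m$h), db2 = rowSums(dz),
         dW1 = dh %*% t(v), db1 = rowSums(dh),
         dv = crossprod(params$W1, dh))
  }
  ga <- grad_branch(cache$ma, cache$ps$avg)
  gm <- grad_branch(cache$mm, cache$ps$mx)

  # scatter pooled-descriptor gradients back onto the feature map
  dx <- dx + bcast_channel_gate(ga$dv / HW, H, W)
  col <- seq_len(C * N)
  pos_sp <- cache$ps$arg + HW * (col - 1L)
  dx_vec <- as.vector(dx)
  dx_vec[pos_sp] <- dx_vec[pos_sp] + as.vector(gm$dv)
  dx <- array(dx_vec, d) + dx_extra

  list(dx = dx,
       grads = list(W1 = ga$dW1 + gm$dW1, b1 = ga$db1 + gm$db1,
                    W2 = ga$dW2 + gm$dW2, b2 = ga$db2 + gm$db2,
                    Ws = cb$dw, bs = cb$db))
}
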