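# The eight-weight-layer classification network: five convolutions, two
# 1024-unit fully connected layers and a final 4-way affine feeding softmax,
# with a cascaded channel/spatial attention block after the first pooling
# layer and batch normalization after the second and fifth convolutions.
# Rectifier nonlinearities follow every convolution and FC layer except the
# softmax head. All spatial sizes follow floor((n + 2p - k)/s) + 1.

#' Network specification
#'
#' The fixed layer stack: conv(11x11, 16, s4, p2) - maxpool(3, s2) -
#' attention - conv(5x5, 16, s1, p2) - batchnorm - maxpool(3, s2) -
#' conv(3x3, 24, s1, p1) x3 - batchnorm - maxpool(3, s1) - FC 1024 -
#' FC 1024 - affine 4 + softmax. Exactly 8 weight layers (5 conv + 2 FC +
#' classifier affine); batchnorm and attention gates are not weight layers.
#'
#' @param input_shape `(C, H, W)` of the network input; the native planar
#'   scintigram is `c(1, 1024, 256)`, a 2x downscale `c(1, 512, 128)`.
#' @param n_classes Number of output classes (4).
#' @param reduction_ratio,spatial_kernel Attention hyperparameters, see
#'   [attention_params()].
#' @param attention Set `FALSE` to force both attention gates to 1
#'   (ablation).
#' @param spatial_on_original Ablation flag, see [apply_hybrid()].
#' @param n_mid_convs Number of 3x3 convolutions in the middle block. The
#'   canonical stack has 3; [build_network()] refuses anything else, but
#'   [count_weight_layers()] accepts variant specs.
#' @return An object of class `"dscint_spec"`.
#' @export
dscint_spec <- function(input_shape = c(1L, 1024L, 256L), n_classes = 4L,
                        reduction_ratio = 4L, spatial_kernel = 7L,
                        attention = TRUE, spatial_on_original = FALSE,
                        n_mid_convs = 3L) {
  layers <- list(
    list(type = "conv", k = 11L, out = 16L, stride = 4L, pad = 2L,
         act = "relu"),
    list(type = "maxpool", k = 3L, stride = 2L),
    list(type = "attention"),
    list(type = "conv", k = 5L, out = 16L, stride = 1L, pad = 2L,
         act = "bn_relu", bn = "bn1"),
    list(type = "maxpool", k = 3L, stride = 2L)
  )
  for (i in seq_len(n_mid_convs)) {
    layers[[length(layers) + 1L]] <-
      list(type = "conv", k = 3L, out = 24L, stride = 1L, pad = 1L,
           act = if (i == n_mid_convs) "bn_relu" else "relu",
           bn = if (i == n_mid_convs) "bn2" else NULL)
  }
  layers <- c(layers, list(
    list(type = "maxpool", k = 3L, stride = 1L),
    list(type = "flatten"),
    list(type = "fc", out = 1024L, act = "relu"),
    list(type = "fc", out = 1024L, act = "relu"),
    list(type = "fc", out = as.integer(n_classes), act = "softmax")
  ))
  structure(list(input_shape = as.integer(input_shape), layers = layers,
                 n_classes = as.integer(n_classes),
                 reduction_ratio = as.integer(reduction_ratio),
                 spatial_kernel = as.integer(spatial_kernel),
                 attention = isTRUE(attention),
                 spatial_on_original = isTRUE(spatial_on_original),
                 n_mid_convs = as.integer(n_mid_convs)),
            class = "dscint_spec")
}

conv_out <- function(n, k, s, p) (n + 2L * p - k) %/% s + 1L

#' Derive every intermediate feature-map shape
#'
#' Propagates the input shape through the layer stack with
#' `floor((n + 2p - k)/s) + 1`. For the native 1x1024x256 input the sequence
#' is 16x255x63, 16x127x31, (attention, unchanged), 16x127x31, 16x63x15,
#' 24x63x15 (three times), 24x61x13, flatten 19032, 1024, 1024, 4.
#'
#' @param spec A [dscint_spec()].
#' @return Data frame with one row per layer: `layer`, `type`, `C`, `H`, `W`
#'   (`H = W = NA` once flattened; `C` holds the vector length).
#' @export
network_shapes <- function(spec) {
  shp <- spec$input_shape # (C, H, W)
  rows <- list(list(layer = "input", type = "input",
                    C = shp[1], H = shp[2], W = shp[3]))
  for (ly in spec$layers) {
    if (ly$type == "conv") {
      shp <- c(ly$out, conv_out(shp[2], ly$k, ly$stride, ly$pad),
               conv_out(shp[3], ly$k, ly$stride, ly$pad))
    } else if (ly$type == "maxpool") {
      shp <- c(shp[1], conv_out(shp[2], ly$k, ly$stride, 0L),
               conv_out(shp[3], ly$k, ly$stride, 0L))
    } else if (ly$type == "flatten") {
      shp <- c(prod(shp), NA_integer_, NA_integer_)
    } else if (ly$type == "fc") {
      shp <- c(ly$out, NA_integer_, NA_integer_)
    } # attention preserves shape
    if (!is.na(shp[2]) && (shp[2] < 1L || shp[3] < 1L))
      stop("input too small: a layer's output would be empty")
    rows[[length(rows) + 1L]] <- list(layer = ly$type, type = ly$type,
                                      C = shp[1], H = shp[2], W = shp[3])
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Count the network's weight layers
#'
#' Weight layers are the parameterized convolutional and fully connected
#' (including the classifier affine) layers; batchnorm stages and attention
#' gates are excluded. The canonical stack has exactly 8.
#'
#' @param x A [dscint_spec()] or built network.
#' @return Integer count.
#' @export
count_weight_layers <- function(x) {
  spec <- if (inherits(x, "dscint_network")) x$spec else x
  stopifnot(inherits(spec, "dscint_spec"))
  sum(vapply(spec$layers, function(l) l$type %in% c("conv", "fc"), logical(1)))
}

#' Build the network with seeded initialization
#'
#' He-normal weight initialization for conv/FC layers, zero biases, unit
#' batchnorm scale. Two builds with the same seed yield identical parameters.
#'
#' @param spec A canonical [dscint_spec()] (3 middle convolutions).
#' @param seed Integer RNG seed.
#' @return An object of class `"dscint_network"` in eval mode.
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "dscint_spec"))
  if (spec$n_mid_convs != 3L || count_weight_layers(spec) != 8L)
    stop("spec violates the canonical stack: expected 3 middle convolutions",
         " and 8 weight layers")
  shapes <- network_shapes(spec)
  set.seed(seed)
  params <- list()
  state <- list()
  cin <- spec$input_shape[1]
  shp <- spec$input_shape
  ci <- 1L # conv counter
  fi <- 1L
  for (ly in spec$layers) {
    if (ly$type == "conv") {
      nm <- paste0("conv", ci)
      fan_in <- ly$k * ly$k * cin
      params[[paste0(nm, ".w")]] <-
        array(stats::rnorm(ly$k * ly$k * cin * ly$out, 0, sqrt(2 / fan_in)),
              dim = c(ly$k, ly$k, cin, ly$out))
      params[[paste0(nm, ".b")]] <- numeric(ly$out)
      if (!is.null(ly$bn)) {
        params[[paste0(ly$bn, ".gamma")]] <- rep(1, ly$out)
        params[[paste0(ly$bn, ".beta")]] <- numeric(ly$out)
        state[[ly$bn]] <- list(mean = numeric(ly$out), var = rep(1, ly$out))
      }
      cin <- ly$out
      shp <- c(ly$out, conv_out(shp[2], ly$k, ly$stride, ly$pad),
               conv_out(shp[3], ly$k, ly$stride, ly$pad))
      ci <- ci + 1L
    } else if (ly$type == "maxpool") {
      shp <- c(shp[1], conv_out(shp[2], ly$k, ly$stride, 0L),
               conv_out(shp[3], ly$k, ly$stride, 0L))
    } else if (ly$type == "attention") {
      ap <- attention_params(cin, spec$reduction_ratio, spec$spatial_kernel,
                             init = "he", seed = seed + 1L)
      params[["att.W1"]] <- ap$W1; params[["att.b1"]] <- ap$b1
      params[["att.W2"]] <- ap$W2; params[["att.b2"]] <- ap$b2
      params[["att.Ws"]] <- ap$Ws; params[["att.bs"]] <- ap$bs
    } else if (ly$type == "flatten") {
      shp <- c(prod(shp), NA, NA)
    } else if (ly$type == "fc") {
      nm <- paste0("fc", fi)
      d_in <- shp[1]
      params[[paste0(nm, ".W")]] <-
        matrix(stats::rnorm(ly$out * d_in, 0, sqrt(2 / d_in)), ly$out, d_in)
      params[[paste0(nm, ".b")]] <- numeric(ly$out)
      shp <- c(ly$out, NA, NA)
      fi <- fi + 1L
    }
  }
  structure(list(spec = spec, params = params, state = state,
                 shapes = shapes, mode = "eval"),
            class = "dscint_network")
}

att_params_from_net <- function(net) {
  p <- net$params
  structure(list(W1 = p[["att.W1"]], b1 = p[["att.b1"]],
                 W2 = p[["att.W2"]], b2 = p[["att.b2"]],
                 Ws = p[["att.Ws"]], bs = p[["att.bs"]],
                 channels = ncol(p[["att.W1"]]),
                 hidden = nrow(p[["att.W1"]]),
                 k = dim(p[["att.Ws"]])[1]),
            class = "attention_params")
}

#' Numerically safe softmax
#'
#' `f(x_j) = exp(x_j) / sum_i exp(x_i)`, computed after subtracting the
#' maximum for overflow safety. Order-preserving and shift-invariant.
#'
#' @param x Finite numeric vector of logits.
#' @return Probability vector of the same length summing to 1.
#' @export
#' @examples
#' softmax(c(1, 0, 0, 0))
softmax <- function(x) {
  if (anyNA(x) || any(is.nan(x))) stop("softmax: NaN/NA input")
  e <- exp(x - max(x))
  e / sum(e)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

bn_reshape <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
}

bn_unshape <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

bn_forward <- function(x, gamma, beta, st, mode, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  m <- bn_reshape(x)
  if (mode == "train") {
    mu <- colMeans(m)
    va <- colMeans(m^2) - mu^2
    st$mean <- (1 - momentum) * st$mean + momentum * mu
    st$var <- (1 - momentum) * st$var + momentum * va
  } else {
    mu <- st$mean
    va <- st$var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(m, 2, mu), 2, inv, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = bn_unshape(y, d), state = st,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, d = d,
                    mode = mode))
}

bn_backward <- function(dout, cache) {
  d <- cache$d
  dm <- bn_reshape(dout)
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  if (cache$mode == "train") {
    M <- nrow(dm)
    dxhat <- sweep(dm, 2, cache$gamma, "*")
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
    dx <- sweep(t1 - t2, 2, cache$inv, "*")
  } else {
    dx <- sweep(sweep(dm, 2, cache$gamma, "*"), 2, cache$inv, "*")
  }
  list(dx = bn_unshape(dx, d), dgamma = dgamma, dbeta = dbeta)
}

#' Forward pass
#'
#' Runs a batch through the network. In eval mode the pass is deterministic
#' (batchnorm uses running statistics).
#'
#' @param net A built [build_network()] network.
#' @param x Input array `(H, W, 1)` for one image or `(H, W, 1, N)` for a
#'   batch, values normalized to `[0, 1]`.
#' @param mode `"eval"` or `"train"` (batchnorm statistics source).
#' @param keep_cache Keep layer caches for backpropagation.
#' @return List with `probs` (N x n_classes matrix of softmax outputs),
#'   `logits`, and optionally `cache` and updated `state`.
#' @export
network_forward <- function(net, x, mode = c("eval", "train"),
                            keep_cache = FALSE) {
  mode <- match.arg(mode)
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  ish <- net$spec$input_shape
  if (!identical(as.integer(dim(x)[c(3, 1, 2)]), ish))
    stop(sprintf("input shape (C=%d, H=%d, W=%d) does not match spec (%d, %d, %d)",
                 dim(x)[3], dim(x)[1], dim(x)[2], ish[1], ish[2], ish[3]))
  N <- dim(x)[4]
  p <- net$params
  state <- net$state
  cache <- list(x0 = x)
  ci <- 1L; fi <- 1L; li <- 1L
  for (ly in net$spec$layers) {
    key <- paste0("L", li)
    if (ly$type == "conv") {
      nm <- paste0("conv", ci)
      z <- .conv2d_fwd(x, p[[paste0(nm, ".w")]], p[[paste0(nm, ".b")]],
                       ly$stride, ly$pad)
      if (keep_cache) cache[[paste0(key, ".in")]] <- x
      if (identical(ly$act, "bn_relu")) {
        bf <- bn_forward(z, p[[paste0(ly$bn, ".gamma")]],
                         p[[paste0(ly$bn, ".beta")]], state[[ly$bn]], mode)
        state[[ly$bn]] <- bf$state
        if (keep_cache) cache[[paste0(key, ".bn")]] <- bf$cache
        z <- bf$out
      }
      a <- pmax(z, 0)
      if (keep_cache) cache[[paste0(key, ".mask")]] <- z > 0
      x <- a
      ci <- ci + 1L
    } else if (ly$type == "maxpool") {
      mp <- .maxpool_fwd(x, ly$k, ly$stride)
      if (keep_cache) cache[[paste0(key, ".idx")]] <- mp$idx
      if (keep_cache) cache[[paste0(key, ".indim")]] <- dim(x)
      x <- mp$out
    } else if (ly$type == "attention") {
      if (net$spec$attention) {
        af <- att_forward(x, att_params_from_net(net),
                          net$spec$spatial_on_original)
        if (keep_cache) cache[[paste0(key, ".att")]] <- af$cache
        x <- af$out
      }
    } else if (ly$type == "flatten") {
      if (keep_cache) cache[[paste0(key, ".indim")]] <- dim(x)
      x <- matrix(x, ncol = N)
    } else if (ly$type == "fc") {
      nm <- paste0("fc", fi)
      z <- p[[paste0(nm, ".W")]] %*% x + p[[paste0(nm, ".b")]]
      if (keep_cache) cache[[paste0(key, ".in")]] <- x
      if (identical(ly$act, "relu")) {
        if (keep_cache) cache[[paste0(key, ".mask")]] <- z > 0
        x <- pmax(z, 0)
      } else {
        x <- z # logits
      }
      fi <- fi + 1L
    }
    li <- li + 1L
  }
  probs <- t(softmax_cols(x))
  colnames(probs) <- class_labels()[seq_len(net$spec$n_classes)]
  list(probs = probs, logits = x, state = state,
       cache = if (keep_cache) cache else NULL)
}

# backward pass: dlogits (K x N) -> gradients for every parameter
network_backward <- function(net, cache, dlogits) {
  p <- net$params
  grads <- list()
  dx <- dlogits
  layers <- net$spec$layers
  ci <- sum(vapply(layers, function(l) l$type == "conv", logical(1)))
  fi <- sum(vapply(layers, function(l) l$type == "fc", logical(1)))
  for (li in rev(seq_along(layers))) {
    ly <- layers[[li]]
    key <- paste0("L", li)
    if (ly$type == "fc") {
      nm <- paste0("fc", fi)
      if (identical(ly$act, "relu")) dx <- dx * cache[[paste0(key, ".mask")]]
      xin <- cache[[paste0(key, ".in")]]
      grads[[paste0(nm, ".W")]] <- dx %*% t(xin)
      grads[[paste0(nm, ".b")]] <- rowSums(dx)
      dx <- crossprod(p[[paste0(nm, ".W")]], dx)
      fi <- fi - 1L
    } else if (ly$type == "flatten") {
      dx <- array(dx, cache[[paste0(key, ".indim")]])
    } else if (ly$type == "maxpool") {
      dx <- .maxpool_bwd(dx, cache[[paste0(key, ".idx")]],
                         cache[[paste0(key, ".indim")]])
    } else if (ly$type == "attention") {
      if (net$spec$attention) {
        ab <- att_backward(dx, cache[[paste0(key, ".att")]],
                           att_params_from_net(net))
        dx <- ab$dx
        grads[["att.W1"]] <- ab$grads$W1; grads[["att.b1"]] <- ab$grads$b1
        grads[["att.W2"]] <- ab$grads$W2; grads[["att.b2"]] <- ab$grads$b2
        grads[["att.Ws"]] <- ab$grads$Ws; grads[["att.bs"]] <- ab$grads$bs
      }
    } else if (ly$type == "conv") {
      nm <- paste0("conv", ci)
      dx <- dx * cache[[paste0(key, ".mask")]]
      if (identical(ly$act, "bn_relu")) {
        bb <- bn_backward(dx, cache[[paste0(key, ".bn")]])
        grads[[paste0(ly$bn, ".gamma")]] <- bb$dgamma
        grads[[paste0(ly$bn, ".beta")]] <- bb$dbeta
        dx <- bb$dx
      }
      cb <- .conv2d_bwd(cache[[paste0(key, ".in")]], p[[paste0(nm, ".w")]],
                        dx, ly$stride, ly$pad, need_dx = ci > 1L)
      grads[[paste0(nm, ".w")]] <- cb$dw
      grads[[paste0(nm, ".b")]] <- cb$db
      dx <- cb$dx
      ci <- ci - 1L
    }
  }
  grads
}

#' @export
print.dscint_network <- function(x, ...) {
  npar <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<dscint_network> input %s, %d weight layers, %s parameters\n",
              paste(x$spec$input_shape, collapse = "x"),
              count_weight_layers(x), format(npar, big.mark = ",")))
  invisible(x)
}
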