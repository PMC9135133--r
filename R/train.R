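# Training: mini-batch cross-entropy optimization with Adam (decoupled
# weight decay) or plain SGD. The fitting function dscint() is the package's
# front door: images in, fitted classifier out.

#' Training hyperparameters
#'
#' Defaults follow the reference protocol: learning rate 1e-3, weight decay
#' 1e-4, batch size 4, 300 epochs, adaptive-moment (Adam) optimizer,
#' categorical cross-entropy loss, no early stopping. Weight decay is applied
#' decoupled from the gradient, to weight matrices only.
#'
#' @param learning_rate Step size.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training set.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param seed RNG seed controlling initialization and batch shuffling.
#' @param verbose Print per-epoch progress.
#' @return An object of class `"dscint_control"`.
#' @export
dscint_control <- function(learning_rate = 1e-3, weight_decay = 1e-4,
                           batch_size = 4L, epochs = 300L,
                           optimizer = c("adam", "sgd"), seed = 1L,
                           verbose = FALSE) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            epochs >= 0)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 optimizer = match.arg(optimizer), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "dscint_control")
}

is_weight_matrix <- function(name) grepl("\\.(w|W|Ws)$", name)

make_optimizer <- function(params, control) {
  t_step <- 0L
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  list(
    step = function(params, grads) {
      t_step <<- t_step + 1L
      lr <- control$learning_rate
      for (nm in names(grads)) {
        wd <- if (is_weight_matrix(nm)) control$weight_decay else 0
        if (control$optimizer == "adam") {
          # fused C++ step; m and v are updated in place
          params[[nm]] <- .adam_update(params[[nm]], grads[[nm]],
                                       m[[nm]], v[[nm]], lr, 0.9, 0.999,
                                       1e-8, 1 - 0.9^t_step,
                                       1 - 0.999^t_step, wd)
        } else {
          params[[nm]] <- params[[nm]] - lr * grads[[nm]] -
            lr * wd * params[[nm]]
        }
      }
      params
    })
}

# assemble a normalized (H, W, 1, n) batch from scinti_images
images_to_batch <- function(images, idx = seq_along(images)) {
  d <- dim(images[[idx[1]]]$pixels)
  x <- array(0, c(d[1], d[2], 1L, length(idx)))
  for (i in seq_along(idx)) {
    p <- images[[idx[i]]]$pixels
    mx <- max(p)
    x[, , 1L, i] <- if (mx > 0L) p / mx else 0
  }
  x
}

image_labels <- function(images) {
  labs <- vapply(images, function(im) im$label, character(1))
  if (anyNA(labs)) stop("every image must carry a class label")
  labs
}

#' Fit the scintigram classification network
#'
#' Trains the eight-weight-layer attention CNN on a labelled set of planar
#' scintigrams by mini-batch cross-entropy optimization. All images must
#' share one grid (native 1024 x 256 or a common downscale). Deterministic
#' given `control$seed`.
#'
#' @param images List of labelled [scinti_image()]s.
#' @param control A [dscint_control()].
#' @param spec Optional [dscint_spec()]; derived from the image grid when
#'   omitted.
#' @param net Optional pre-built or pre-trained network to continue from.
#' @return An object of class `"dscint"` with components `net`, `history`
#'   (per-epoch loss and training accuracy), `control`, `classes` and
#'   `elapsed` (seconds). Methods: `print`, `summary`, `predict`, `plot`,
#'   `coef`.
#' @export
#' @examples
#' \donttest{
#' cfg <- phantom_config(n_per_class = 3, seed = 7)
#' cohort <- generate_cohort(cfg, downscale = 8L)
#' fit <- dscint(cohort$images,
#'               control = dscint_control(epochs = 1, verbose = FALSE))
#' predict(fit, cohort$images[1:2])
#' }
dscint <- function(images, control = dscint_control(), spec = NULL,
                   net = NULL) {
  if (length(images) == 0L) stop("empty training set")
  labs <- image_labels(images)
  d <- dim(images[[1]]$pixels)
  if (is.null(spec)) spec <- dscint_spec(input_shape = c(1L, d[1], d[2]))
  set.seed(control$seed)
  if (is.null(net)) net <- build_network(spec, seed = control$seed)
  y <- class_encoding(labs) # 0..3
  n <- length(images)
  K <- net$spec$n_classes

  opt <- make_optimizer(net$params, control)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  t0 <- proc.time()[["elapsed"]]
  # normalize once; batches are assembled from this cache
  d1 <- dim(images[[1]]$pixels)
  xnorm <- lapply(images, function(im) {
    mx <- max(im$pixels)
    if (mx > 0L) im$pixels / mx else matrix(0, d1[1], d1[2])
  })
  for (ep in seq_len(control$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    ep_hits <- 0L
    for (b0 in seq(1L, n, by = control$batch_size)) {
      idx <- ord[b0:min(b0 + control$batch_size - 1L, n)]
      x <- array(unlist(xnorm[idx], use.names = FALSE),
                 c(d1[1], d1[2], 1L, length(idx)))
      fw <- network_forward(net, x, mode = "train", keep_cache = TRUE)
      net$state <- fw$state
      probs <- fw$probs # nb x K
      yb <- y[idx] + 1L
      pt <- pmax(probs[cbind(seq_along(idx), yb)], 1e-12)
      ep_loss <- ep_loss - sum(log(pt))
      ep_hits <- ep_hits + sum(max.col(probs) == yb)
      onehot <- matrix(0, K, length(idx))
      onehot[cbind(yb, seq_along(idx))] <- 1
      dlogits <- (t(probs) - onehot) / length(idx)
      grads <- network_backward(net, fw$cache, dlogits)
      net$params <- opt$step(net$params, grads)
    }
    history[nrow(history) + 1L, ] <- list(ep, ep_loss / n, ep_hits / n)
    if (control$verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f",
                      ep, ep_loss / n, ep_hits / n))
  }
  structure(list(net = net, history = history, control = control,
                 classes = class_labels()[seq_len(K)],
                 n_train = n,
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "dscint")
}

#' Predict class probabilities for new scintigrams
#'
#' @param object A fitted [dscint()] model.
#' @param newdata List of [scinti_image()]s (or a single one) on the same
#'   grid the model was trained on.
#' @param type `"prob"` for the n x 4 probability matrix, `"class"` for the
#'   argmax labels.
#' @param batch_size Images per forward pass.
#' @param ... Unused.
#' @return Probability matrix or character vector of class labels.
#' @export
predict.dscint <- function(object, newdata, type = c("prob", "class"),
                           batch_size = 16L, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "scinti_image")) newdata <- list(newdata)
  probs <- network_predict(object$net, newdata, batch_size)
  if (type == "class") class_labels()[max.col(probs)] else probs
}

network_predict <- function(net, images, batch_size = 16L) {
  n <- length(images)
  out <- matrix(NA_real_, n, net$spec$n_classes,
                dimnames = list(NULL, class_labels()[seq_len(net$spec$n_classes)]))
  for (b0 in seq(1L, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    x <- images_to_batch(images, idx)
    out[idx, ] <- network_forward(net, x, mode = "eval")$probs
  }
  out
}

#' @export
print.dscint <- function(x, ...) {
  cat(sprintf("Scintigram classifier (%d weight layers, attention %s)\n",
              count_weight_layers(x$net),
              if (x$net$spec$attention) "on" else "off"))
  cat(sprintf("  trained on %d images for %d epochs (%.1f s)\n",
              x$n_train, nrow(x$history), x$elapsed))
  if (nrow(x$history) > 0)
    cat(sprintf("  final training loss %.4f, accuracy %.3f\n",
                x$history$loss[nrow(x$history)],
                x$history$accuracy[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.dscint <- function(object, ...) {
  print(object)
  print(object$net)
  if (nrow(object$history) > 0) {
    cat("training history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.dscint <- function(object, ...) object$net$params

#' @export
plot.dscint <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) {
    warning("no training history to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "training loss",
       main = "loss", ...)
  plot(h$epoch, h$accuracy, type = "l", ylim = c(0, 1), xlab = "epoch",
       ylab = "training accuracy", main = "accuracy", ...)
  invisible(x)
}

#' Save or load a model checkpoint
#'
#' The checkpoint holds the network spec, parameters and batchnorm running
#' statistics (plus history for fitted models); loading reproduces
#' evaluation results exactly.
#'
#' @param object A fitted `dscint` model or bare `dscint_network`.
#' @param path Checkpoint file path.
#' @return `load_checkpoint()`: the restored object.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, c("dscint", "dscint_network")))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
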