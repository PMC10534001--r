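# Compact convolutional image classifier trained from scratch.
#
# The network operates on scalogram images pooled to 28 x 28 x 3 (the
# 224 x 224 x 3 input contract is honoured by an 8 x 8 average-pooling
# front end, see cnn_input_tensor): three 3 x 3 valid convolutions with
# ReLU, 2 x 2 max pooling after the first two, global average pooling, and
# a softmax classification head. Implemented with im2col matrix products so
# training stays fast on a single CPU, and fully deterministic given the
# configuration seed.

# ---- tensor plumbing -------------------------------------------------------

# Linear-index matrix (positions x kernel taps) for im2col patch extraction
# on a (H, W, C) column-major tensor with a kh x kw valid convolution.
make_im2col_idx <- function(H, W, C, kh, kw) {
  oh <- H - kh + 1
  ow <- W - kw + 1
  idx <- matrix(0L, oh * ow, kh * kw * C)
  k <- 0L
  for (ch in seq_len(C)) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    k <- k + 1L
    ii <- rep(seq_len(oh), times = ow) + di - 1L
    jj <- rep(seq_len(ow), each = oh) + dj - 1L
    idx[, k] <- (ch - 1L) * H * W + (jj - 1L) * H + ii
  }
  idx
}

# 2 x 2 / stride-2 max-pool index sets: four linear-index vectors into a
# (H, W, C) tensor, one per pool-cell corner (odd trailing row/col dropped).
make_pool_idx <- function(H, W, C) {
  oh <- H %/% 2L
  ow <- W %/% 2L
  base_i <- rep(seq(1L, 2L * oh, by = 2L), times = ow)
  base_j <- rep(seq(1L, 2L * ow, by = 2L), each = oh)
  sel <- list()
  q <- 0L
  for (dj in 0:1) for (di in 0:1) {
    q <- q + 1L
    cell <- (base_j + dj - 1L) * H + base_i + di
    sel[[q]] <- as.integer(outer(cell, (seq_len(C) - 1L) * H * W, "+"))
  }
  list(sel = sel, oh = oh, ow = ow)
}

conv_forward <- function(xm, lay) {
  B <- nrow(xm)
  P <- nrow(lay$idx)
  Xcol <- xm[, as.vector(lay$idx)]
  dim(Xcol) <- c(B * P, ncol(lay$idx))   # pure relabel: layouts coincide
  Y <- Xcol %*% lay$W
  for (j in seq_along(lay$b)) Y[, j] <- Y[, j] + lay$b[j]
  dim(Y) <- c(B, P * ncol(lay$W))
  list(y = Y, Xcol = Xcol, B = B)
}

conv_backward <- function(dy, fwd, lay) {
  B <- fwd$B
  P <- nrow(lay$idx)
  Fo <- ncol(lay$W)
  dY <- dy
  dim(dY) <- c(B * P, Fo)
  dW <- crossprod(fwd$Xcol, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(lay$W)
  dxm <- matrix(0, B, lay$n_in)
  for (k in seq_len(ncol(lay$idx))) {
    cols <- lay$idx[, k]
    dxm[, cols] <- dxm[, cols] + matrix(dXcol[, k], B, P)
  }
  list(dx = dxm, dW = dW, db = db)
}

pool_forward <- function(xm, pl) {
  s <- lapply(pl$sel, function(ix) xm[, ix, drop = FALSE])
  m <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  list(y = m, s = s, m = m)
}

pool_backward <- function(dy, fwd, pl, n_in) {
  B <- nrow(dy)
  dxm <- matrix(0, B, n_in)
  taken <- matrix(FALSE, B, ncol(dy))
  for (q in 1:4) {
    w <- (fwd$s[[q]] == fwd$m) & !taken
    taken <- taken | w
    dxm[, pl$sel[[q]]] <- dxm[, pl$sel[[q]]] + dy * w
  }
  dxm
}

gap_forward <- function(xm, hw, C) {
  B <- nrow(xm)
  y <- matrix(0, B, C)
  for (ch in seq_len(C))
    y[, ch] <- rowMeans(xm[, ((ch - 1) * hw + 1):(ch * hw), drop = FALSE])
  y
}

gap_backward <- function(dy, hw, C) {
  B <- nrow(dy)
  dxm <- matrix(0, B, hw * C)
  for (ch in seq_len(C))
    dxm[, ((ch - 1) * hw + 1):(ch * hw)] <- dy[, ch] / hw
  dxm
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- model construction ----------------------------------------------------

.backbones <- new.env(parent = emptyenv())

#' Register an image-classifier backbone constructor
#'
#' Extension point mirroring the transfer-learning design: the pipeline can
#' host large pretrained backbones (e.g. GoogLeNet or EfficientNetB0
#' equivalents) supplied as plug-ins, while `tiny_test_cnn` ships built in
#' and trains from scratch at desk scale.
#'
#' @param name Backbone name.
#' @param constructor Function `(config, n_classes) -> model`.
#' @export
register_backbone <- function(name, constructor) {
  assign(name, constructor, envir = .backbones)
  invisible(name)
}

#' Training configuration for the image classifier
#'
#' @param backbone Backbone name; `"tiny_test_cnn"` is built in, others must
#'   be registered via [register_backbone()].
#' @param learning_rate Stochastic-gradient-descent learning rate
#'   (default 0.005).
#' @param momentum SGD momentum (default 0.9).
#' @param n_minibatches Number of minibatches per epoch; batch size is
#'   `ceiling(n_images / n_minibatches)` (default 10).
#' @param epochs Training epochs (default 10).
#' @param seed Integer seed controlling initialisation and batch shuffling.
#' @return Object of class `ppg_train_config`.
#' @export
train_config <- function(backbone = "tiny_test_cnn",
                         learning_rate = 0.005,
                         momentum = 0.9,
                         n_minibatches = 10,
                         epochs = 10,
                         seed = 1) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (epochs < 1) stop("epochs must be at least 1")
  structure(list(backbone = backbone, learning_rate = learning_rate,
                 momentum = momentum, n_minibatches = n_minibatches,
                 epochs = epochs, seed = seed),
            class = "ppg_train_config")
}

build_tiny_cnn <- function(config, n_classes = 2) {
  set.seed(config$seed)
  he <- function(fan_in, k_out) {
    matrix(stats::rnorm(fan_in * k_out, 0, sqrt(2 / fan_in)), fan_in, k_out)
  }
  layers <- list()
  # conv1: 28x28x3 -> 26x26x8 -> pool 13x13x8
  layers$conv1 <- list(idx = make_im2col_idx(28, 28, 3, 3, 3),
                       W = he(27, 8), b = numeric(8), n_in = 28 * 28 * 3)
  layers$pool1 <- make_pool_idx(26, 26, 8)
  # conv2: 13x13x8 -> 11x11x16 -> pool 5x5x16
  layers$conv2 <- list(idx = make_im2col_idx(13, 13, 8, 3, 3),
                       W = he(72, 16), b = numeric(16), n_in = 13 * 13 * 8)
  layers$pool2 <- make_pool_idx(11, 11, 16)
  # conv3: 5x5x16 -> 3x3x32 -> global average pool -> fc
  layers$conv3 <- list(idx = make_im2col_idx(5, 5, 16, 3, 3),
                       W = he(144, 32), b = numeric(32), n_in = 5 * 5 * 16)
  layers$fc <- list(W = he(32, n_classes), b = numeric(n_classes))
  structure(list(backbone = "tiny_test_cnn", layers = layers,
                 n_classes = n_classes, classes = NULL, config = config,
                 input_dim = c(28, 28, 3)),
            class = "ppg_cnn")
}

#' Build a trainable image classifier
#'
#' Instantiates the configured backbone with an `n_classes`-way softmax
#' output layer (the classification head always has as many output nodes as
#' there are classes). The built-in `tiny_test_cnn` trains from scratch;
#' pretrained backbones can be supplied via [register_backbone()].
#'
#' @param config A [train_config()].
#' @param n_classes Number of output classes (default 2).
#' @return A model object (class `ppg_cnn` for the built-in backbone).
#' @export
build_model <- function(config, n_classes = 2) {
  if (config$backbone == "tiny_test_cnn")
    return(build_tiny_cnn(config, n_classes))
  if (exists(config$backbone, envir = .backbones))
    return(get(config$backbone, envir = .backbones)(config, n_classes))
  stop("unknown backbone: ", config$backbone)
}

#' Convert a rendered scalogram image to a classifier input tensor
#'
#' Implements the 224 x 224 x 3 input contract of the compact backbone:
#' 8 x 8 average pooling down to 28 x 28 x 3 and rescaling to `[0, 1]`.
#'
#' @param img A `ppg_scalogram_image` (or a 224 x 224 x 3 numeric array).
#' @return Numeric vector of length `28 * 28 * 3` (column-major tensor
#'   layout).
#' @export
cnn_input_tensor <- function(img) {
  px <- if (inherits(img, "ppg_scalogram_image")) img$pixels else img
  stopifnot(length(dim(px)) == 3, dim(px)[1] %% 28 == 0)
  f <- dim(px)[1] %/% 28
  out <- array(0, c(28, 28, 3))
  for (c3 in 1:3) {
    m <- px[, , c3]
    m <- matrix(colMeans(matrix(m, f, length(m) / f)), dim(px)[1] / f,
                dim(px)[2])
    m <- t(matrix(colMeans(matrix(t(m), f, length(m) / f)), dim(px)[2] / f,
                  dim(px)[1] / f))
    out[, , c3] <- m / 255
  }
  as.vector(out)
}

cnn_forward <- function(model, xm, keep = FALSE) {
  ly <- model$layers
  xm <- (xm - 0.5) * 2          # centre [0, 1] inputs for conditioning
  c1 <- conv_forward(xm, ly$conv1)
  r1 <- pmax(c1$y, 0)
  p1 <- pool_forward(r1, ly$pool1)
  c2 <- conv_forward(p1$y, ly$conv2)
  r2 <- pmax(c2$y, 0)
  p2 <- pool_forward(r2, ly$pool2)
  c3 <- conv_forward(p2$y, ly$conv3)
  r3 <- pmax(c3$y, 0)
  g <- gap_forward(r3, 9, 32)
  z <- sweep(g %*% ly$fc$W, 2, ly$fc$b, "+")
  out <- list(probs = softmax(z))
  if (keep)
    out <- c(out, list(xm = xm, c1 = c1, r1 = r1, p1 = p1, c2 = c2,
                       r2 = r2, p2 = p2, c3 = c3, r3 = r3, g = g))
  out
}

cnn_gradients <- function(model, fwd, y_onehot) {
  ly <- model$layers
  B <- nrow(y_onehot)
  dz <- (fwd$probs - y_onehot) / B
  g <- list()
  g$fc <- list(dW = crossprod(fwd$g, dz), db = colSums(dz))
  dg <- dz %*% t(ly$fc$W)
  dr3 <- gap_backward(dg, 9, 32)
  dc3 <- dr3 * (fwd$r3 > 0)
  b3 <- conv_backward(dc3, fwd$c3, ly$conv3)
  g$conv3 <- b3[c("dW", "db")]
  dp2 <- b3$dx
  dr2 <- pool_backward(dp2, fwd$p2, ly$pool2, 11 * 11 * 16)
  dc2 <- dr2 * (fwd$r2 > 0)
  b2 <- conv_backward(dc2, fwd$c2, ly$conv2)
  g$conv2 <- b2[c("dW", "db")]
  dp1 <- b2$dx
  dr1 <- pool_backward(dp1, fwd$p1, ly$pool1, 26 * 26 * 8)
  dc1 <- dr1 * (fwd$r1 > 0)
  b1 <- conv_backward(dc1, fwd$c1, ly$conv1)
  g$conv1 <- b1[c("dW", "db")]
  g
}

#' Train the image classifier
#'
#' Minibatch stochastic gradient descent with momentum on the cross-entropy
#' loss. Images are shuffled each epoch; everything is driven by the
#' configuration seed, so a seeded rerun reproduces the final parameters and
#' loss exactly.
#'
#' @param model A model from [build_model()].
#' @param x Input tensors: matrix with one image per row (length
#'   `28 * 28 * 3` rows from [cnn_input_tensor()]).
#' @param y Class labels (character or factor), at least one image per
#'   class.
#' @param config A [train_config()].
#' @param epochs Number of epochs; defaults to `config$epochs`. `0` returns
#'   the model unchanged.
#' @return The fitted model, with a `loss_trace` data frame (epoch, loss,
#'   accuracy) attached.
#' @export
train_model <- function(model, x, y, config = model$config,
                        epochs = config$epochs) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2)
    stop("training set must contain at least one image per class")
  if (length(classes) != model$n_classes)
    stop("number of classes does not match the model output layer")
  model$classes <- classes
  if (epochs == 0) {
    model$loss_trace <- data.frame(epoch = integer(), loss = numeric(),
                                   accuracy = numeric())
    return(model)
  }
  n <- nrow(x)
  yi <- match(y, classes)
  onehot <- matrix(0, n, length(classes))
  onehot[cbind(seq_len(n), yi)] <- 1
  bs <- ceiling(n / config$n_minibatches)
  lr <- config$learning_rate
  mom <- config$momentum
  vel <- lapply(model$layers[c("conv1", "conv2", "conv3", "fc")],
                function(l) list(W = l$W * 0, b = l$b * 0))
  set.seed(config$seed + 1L)
  trace <- data.frame(epoch = seq_len(epochs), loss = NA_real_,
                      accuracy = NA_real_)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    correct <- 0
    for (b0 in seq(1, n, by = bs)) {
      ib <- ord[b0:min(b0 + bs - 1, n)]
      fwd <- cnn_forward(model, x[ib, , drop = FALSE], keep = TRUE)
      p <- fwd$probs
      losses <- c(losses, -mean(log(pmax(p[cbind(seq_along(ib),
                                                 yi[ib])], 1e-12))))
      correct <- correct + sum(max.col(p) == yi[ib])
      grads <- cnn_gradients(model, fwd, onehot[ib, , drop = FALSE])
      for (nm in names(grads)) {
        vel[[nm]]$W <- mom * vel[[nm]]$W - lr * grads[[nm]]$dW
        vel[[nm]]$b <- mom * vel[[nm]]$b - lr * grads[[nm]]$db
        model$layers[[nm]]$W <- model$layers[[nm]]$W + vel[[nm]]$W
        model$layers[[nm]]$b <- model$layers[[nm]]$b + vel[[nm]]$b
      }
    }
    trace$loss[ep] <- mean(losses)
    trace$accuracy[ep] <- correct / n
  }
  model$loss_trace <- trace
  model
}

#' Predict class scores for images
#'
#' @param object A fitted (or freshly built) `ppg_cnn`.
#' @param x Input tensor matrix (one image per row).
#' @param ... Unused.
#' @return Matrix of class scores (rows sum to 1); columns named by class
#'   when the model has been trained.
#' @export
predict.ppg_cnn <- function(object, x, ...) {
  p <- cnn_forward(object, x)$probs
  if (!is.null(object$classes)) colnames(p) <- object$classes
  p
}
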