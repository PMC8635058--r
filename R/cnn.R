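# A small convolutional network for two-class image classification,
# implemented directly on top of R matrix algebra: two strided
# convolution + ReLU blocks, a dense softmax head, cross-entropy loss and
# Adam updates. Convolutions run as im2col gathers followed by one matrix
# multiplication, so minibatches stay fast without compiled code; training
# is deterministic for a fixed seed.

# geometry of one strided convolution with zero padding
.conv_geom <- function(H, W, k, s, p) {
  Hp <- H + 2 * p; Wp <- W + 2 * p
  oh <- (Hp - k) %/% s + 1L
  ow <- (Wp - k) %/% s + 1L
  # gather indices into the padded plane for each (output position, kernel
  # offset) pair; output positions run column-major (oh fastest)
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  idx <- matrix(0L, nrow = oh * ow, ncol = k * k)
  col <- 0L
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      col <- col + 1L
      ri <- (oi - 1L) * s + ki
      rj <- (oj - 1L) * s + kj
      idx[, col] <- ri + (rj - 1L) * Hp
    }
  }
  list(H = H, W = W, k = k, s = s, p = p, Hp = Hp, Wp = Wp,
       oh = oh, ow = ow, idx = idx)
}

# x: array [N, H, W, C] -> padded matrix [N, Hp*Wp, C]
.pad_input <- function(x, g) {
  N <- dim(x)[1]; C <- dim(x)[4]
  if (g$p == 0) {
    xp <- array(x, dim = c(N, g$Hp * g$Wp, C))
    return(xp)
  }
  xp <- array(0, dim = c(N, g$Hp, g$Wp, C))
  xp[, g$p + seq_len(g$H), g$p + seq_len(g$W), ] <- x
  dim(xp) <- c(N, g$Hp * g$Wp, C)
  xp
}

# im2col: returns matrix [(N*oh*ow) x (k*k*C)], rows ordered N fastest
.im2col <- function(xp, g) {
  N <- dim(xp)[1]; C <- dim(xp)[3]
  npos <- g$oh * g$ow; kk <- g$k * g$k
  # gather: [N, npos*kk, C]
  cols <- xp[, as.vector(g$idx), , drop = FALSE]
  dim(cols) <- c(N, npos, kk, C)
  cols <- aperm(cols, c(1, 2, 3, 4))   # [N, npos, kk, C]
  dim(cols) <- c(N * npos, kk * C)
  cols
}

# scatter-add transpose of im2col: dcols [(N*npos) x (kk*C)] -> [N,H,W,C]
.col2im <- function(dcols, g, N, C) {
  npos <- g$oh * g$ow; kk <- g$k * g$k
  dim(dcols) <- c(N, npos, kk, C)
  dxp <- array(0, dim = c(N, g$Hp * g$Wp, C))
  for (j in seq_len(kk)) {
    tgt <- g$idx[, j]
    dxp[, tgt, ] <- dxp[, tgt, , drop = FALSE] +
      dcols[, , j, , drop = FALSE][, , 1, ]
  }
  dim(dxp) <- c(N, g$Hp, g$Wp, C)
  if (g$p > 0) dxp <- dxp[, g$p + seq_len(g$H), g$p + seq_len(g$W), ,
                          drop = FALSE]
  dxp
}

#' Small-CNN configuration
#'
#' Defaults give a 3-block net (two strided 2-D convolutions with ReLU and
#' a dense softmax head) sized for 64 x 64 single-channel topograms; all
#' parts are configurable. Optimisation is Adam on softmax cross-entropy
#' with early stopping on a held-out slice of the training data.
#'
#' @param input_size image side length (images are square, one channel).
#' @param filters,kernels,strides integer vectors, one entry per
#'   convolution block.
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs.
#' @param batch minibatch size.
#' @param val_frac fraction of training images held out for early stopping
#'   (taken from training subjects only).
#' @param patience epochs without validation improvement before stopping.
#' @param seed RNG seed for initialisation, shuffling and the validation
#'   split.
#' @return a `cnn_config` list.
#' @export
cnn_config <- function(input_size = 64, filters = c(8, 16),
                       kernels = c(5, 3), strides = c(2, 2), lr = 2e-3,
                       epochs = 30, batch = 32, val_frac = 0.1,
                       patience = 5, seed = 1) {
  stopifnot(length(filters) == length(kernels),
            length(filters) == length(strides))
  structure(list(input_size = input_size, filters = filters,
                 kernels = kernels, strides = strides, lr = lr,
                 epochs = epochs, batch = batch, val_frac = val_frac,
                 patience = patience, seed = seed), class = "cnn_config")
}

.cnn_init <- function(config) {
  H <- config$input_size
  geoms <- list(); params <- list(); Cin <- 1L
  for (b in seq_along(config$filters)) {
    k <- config$kernels[b]; s <- config$strides[b]; f <- config$filters[b]
    p <- (k - 1L) %/% 2L
    g <- .conv_geom(H, H, k, s, p)
    fan_in <- k * k * Cin
    params[[paste0("W", b)]] <- matrix(
      rnorm(fan_in * f, sd = sqrt(2 / fan_in)), fan_in, f)
    params[[paste0("b", b)]] <- rep(0, f)
    geoms[[b]] <- g
    H <- g$oh; Cin <- f
  }
  Dflat <- H * H * Cin
  params$Wd <- matrix(rnorm(Dflat * 2, sd = sqrt(2 / Dflat)), Dflat, 2)
  params$bd <- rep(0, 2)
  list(params = params, geoms = geoms, flat_dim = Dflat)
}

# forward pass; returns activations needed for the backward pass
.cnn_forward <- function(x, net, config) {
  N <- dim(x)[1]
  acts <- list(x0 = x)
  a <- x
  for (b in seq_along(config$filters)) {
    g <- net$geoms[[b]]
    xp <- .pad_input(a, g)
    cols <- .im2col(xp, g)
    z <- sweep(cols %*% net$params[[paste0("W", b)]], 2,
               net$params[[paste0("b", b)]], `+`)
    r <- pmax(z, 0)
    acts[[paste0("cols", b)]] <- cols
    acts[[paste0("mask", b)]] <- z > 0
    a <- array(r, dim = c(N, g$oh, g$ow, ncol(r)))
    # rows of r are ordered N fastest within output positions, matching the
    # array fill above
    acts[[paste0("a", b)]] <- a
  }
  flat <- matrix(a, nrow = N)
  logits <- sweep(flat %*% net$params$Wd, 2, net$params$bd, `+`)
  acts$flat <- flat
  acts$logits <- logits
  acts
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# backward pass; y is an N x 2 one-hot matrix
.cnn_backward <- function(acts, y, net, config) {
  N <- nrow(y)
  p <- .softmax(acts$logits)
  grads <- list()
  dlog <- (p - y) / N
  grads$Wd <- crossprod(acts$flat, dlog)
  grads$bd <- colSums(dlog)
  da <- dlog %*% t(net$params$Wd)       # [N, flat]
  nb <- length(config$filters)
  for (b in rev(seq_len(nb))) {
    g <- net$geoms[[b]]
    f <- config$filters[b]
    dz <- matrix(da, nrow = N * g$oh * g$ow, ncol = f)
    dz <- dz * acts[[paste0("mask", b)]]
    cols <- acts[[paste0("cols", b)]]
    grads[[paste0("W", b)]] <- crossprod(cols, dz)
    grads[[paste0("b", b)]] <- colSums(dz)
    if (b > 1) {
      dcols <- dz %*% t(net$params[[paste0("W", b)]])
      Cprev <- config$filters[b - 1]
      da <- .col2im(dcols, g, N, Cprev)
    }
  }
  grads
}

.adam_step <- function(net, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    net$params[[nm]] <- net$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(net = net, state = state)
}

.ce_loss <- function(logits, y) {
  p <- .softmax(logits)
  -mean(log(pmax(rowSums(p * y), 1e-12)))
}

#' Fit the small CNN
#'
#' @param images array `[N, H, W]` of single-channel inputs in `[0, 1]`.
#' @param labels per-image class labels (`"LA"`/`"HA"`); HA is class 1.
#' @param config a [cnn_config()].
#' @param val_idx optional indices of a validation slice used for early
#'   stopping; by default a seeded random `val_frac` of the input.
#' @return a `cnn_model`: parameters, config and the per-epoch training
#'   log (`epoch`, `train_loss`, `val_loss`).
#' @export
cnn_fit <- function(images, labels, config = cnn_config(), val_idx = NULL) {
  N <- dim(images)[1]
  stopifnot(dim(images)[2] == config$input_size,
            dim(images)[3] == config$input_size, length(labels) == N)
  classes <- c("LA", "HA")
  if (!all(labels %in% classes)) stop("labels must be LA or HA")
  if (length(unique(labels)) < 2)
    stop("training data contain a single class")
  set.seed(config$seed)
  if (is.null(val_idx) && config$val_frac > 0)
    val_idx <- sample.int(N, max(1, round(config$val_frac * N)))
  tr_idx <- setdiff(seq_len(N), val_idx)
  y <- cbind(LA = labels == "LA", HA = labels == "HA") * 1
  x <- array(images, dim = c(N, config$input_size, config$input_size, 1))
  net <- .cnn_init(config)
  state <- list(m = lapply(net$params, function(p) p * 0),
                v = lapply(net$params, function(p) p * 0))
  best <- list(loss = Inf, params = net$params, epoch = 0)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  step <- 0
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, length(ord), by = config$batch)) {
      sel <- ord[start:min(start + config$batch - 1, length(ord))]
      xb <- x[sel, , , , drop = FALSE]
      yb <- y[sel, , drop = FALSE]
      acts <- .cnn_forward(xb, net, config)
      ep_loss <- ep_loss + .ce_loss(acts$logits, yb)
      nb <- nb + 1
      grads <- .cnn_backward(acts, yb, net, config)
      step <- step + 1
      upd <- .adam_step(net, grads, state, config$lr, step)
      net <- upd$net; state <- upd$state
    }
    val_loss <- NA_real_
    if (length(val_idx)) {
      av <- .cnn_forward(x[val_idx, , , , drop = FALSE], net, config)
      val_loss <- .ce_loss(av$logits, y[val_idx, , drop = FALSE])
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, params = net$params, epoch = ep)
      } else if (ep - best$epoch >= config$patience) {
        log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                     val_loss = val_loss))
        break
      }
    }
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                 val_loss = val_loss))
  }
  if (is.finite(best$loss)) net$params <- best$params
  structure(list(params = net$params, geoms = net$geoms, config = config,
                 log = log, classes = classes), class = "cnn_model")
}

#' Class probabilities from a fitted CNN
#'
#' @param object a `cnn_model`.
#' @param images array `[N, H, W]`.
#' @param batch prediction batch size.
#' @param ... unused.
#' @return `N x 2` matrix of class probabilities (columns `LA`, `HA`).
#' @export
predict.cnn_model <- function(object, images, batch = 128, ...) {
  N <- dim(images)[1]
  x <- array(images, dim = c(N, dim(images)[2], dim(images)[3], 1))
  net <- list(params = object$params, geoms = object$geoms)
  out <- matrix(NA_real_, N, 2, dimnames = list(NULL, object$classes))
  for (start in seq(1, N, by = batch)) {
    sel <- start:min(start + batch - 1, N)
    acts <- .cnn_forward(x[sel, , , , drop = FALSE], net, object$config)
    out[sel, ] <- .softmax(acts$logits)
  }
  out
}
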