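# A compact convolutional network for scalogram classification, written
# with plain matrix algebra (im2col convolutions, 2x2 max pooling, dense
# head, softmax cross-entropy, Adam). Three conv-pool blocks on 32x32 RGB
# inputs give a ~23k-parameter model that trains in seconds on a CPU;
# gradients are verified against numerical differentiation in the tests.

.im2col <- function(img, k = 3L, pad = 1L) {
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  P <- array(0, c(H + 2L * pad, W + 2L * pad, C))
  P[pad + 1:H, pad + 1:W, ] <- img
  cols <- matrix(0, H * W, k * k * C)
  j <- 0L
  for (c in seq_len(C)) for (dx in seq_len(k)) for (dy in seq_len(k)) {
    j <- j + 1L
    cols[, j] <- as.vector(P[dy + 0:(H - 1L), dx + 0:(W - 1L), c])
  }
  cols
}

.col2im <- function(dcols, H, W, C, k = 3L, pad = 1L) {
  P <- array(0, c(H + 2L * pad, W + 2L * pad, C))
  j <- 0L
  for (c in seq_len(C)) for (dx in seq_len(k)) for (dy in seq_len(k)) {
    j <- j + 1L
    P[dy + 0:(H - 1L), dx + 0:(W - 1L), c] <-
      P[dy + 0:(H - 1L), dx + 0:(W - 1L), c] + matrix(dcols[, j], H, W)
  }
  P[pad + 1:H, pad + 1:W, , drop = FALSE]
}

.conv_fwd <- function(img, Wt, b, k = 3L) {
  H <- dim(img)[1]; W <- dim(img)[2]
  cols <- .im2col(img, k)
  out <- sweep(cols %*% Wt, 2, b, `+`)
  list(out = array(out, c(H, W, length(b))), cols = cols)
}

.conv_bwd <- function(dout, cache, img_dim, Wt, k = 3L) {
  H <- img_dim[1]; W <- img_dim[2]; C <- img_dim[3]
  dmat <- matrix(dout, H * W, dim(Wt)[2])
  list(dW = crossprod(cache$cols, dmat), db = colSums(dmat),
       dx = .col2im(dmat %*% t(Wt), H, W, C, k))
}

.pool_fwd <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  h2 <- H %/% 2L; w2 <- W %/% 2L
  out <- array(0, c(h2, w2, C)); arg <- array(0L, c(h2, w2, C))
  for (c in seq_len(C)) {
    xc <- x[, , c]
    blocks <- rbind(as.vector(xc[seq(1, H, 2), seq(1, W, 2)]),
                    as.vector(xc[seq(2, H, 2), seq(1, W, 2)]),
                    as.vector(xc[seq(1, H, 2), seq(2, W, 2)]),
                    as.vector(xc[seq(2, H, 2), seq(2, W, 2)]))
    am <- max.col(t(blocks), ties.method = "first")
    out[, , c] <- matrix(blocks[cbind(am, seq_len(h2 * w2))], h2, w2)
    arg[, , c] <- matrix(am, h2, w2)
  }
  list(out = out, arg = arg)
}

.pool_bwd <- function(dout, arg, H, W) {
  h2 <- dim(dout)[1]; w2 <- dim(dout)[2]; C <- dim(dout)[3]
  dx <- array(0, c(H, W, C))
  off_r <- c(0L, 1L, 0L, 1L); off_c <- c(0L, 0L, 1L, 1L)
  for (c in seq_len(C)) {
    am <- as.vector(arg[, , c])
    rr <- rep(seq(1, H, 2), times = w2) + off_r[am]
    cc <- rep(seq(1, W, 2), each = h2) + off_c[am]
    dx[, , c][cbind(rr, cc)] <- as.vector(dout[, , c])
  }
  dx
}

.cnn_init <- function(input_dim = c(32L, 32L, 3L),
                      channels = c(8L, 16L, 32L), hidden = 32L,
                      n_classes = 2L, seed = 1L) {
  .with_seed(seed, {
    he <- function(fan_in, nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)),
                                          nr, nc)
    cin <- c(input_dim[3], channels[1], channels[2])
    flat <- prod(input_dim[1:2]) / 4^length(channels) * channels[3]
    list(W1 = he(9 * cin[1], 9 * cin[1], channels[1]), b1 = numeric(channels[1]),
         W2 = he(9 * cin[2], 9 * cin[2], channels[2]), b2 = numeric(channels[2]),
         W3 = he(9 * cin[3], 9 * cin[3], channels[3]), b3 = numeric(channels[3]),
         F1 = he(flat, flat, hidden), f1 = numeric(hidden),
         F2 = he(hidden, hidden, n_classes), f2 = numeric(n_classes),
         input_dim = input_dim, channels = channels)
  })
}

.cnn_forward <- function(par, img, keep_cache = FALSE) {
  c1 <- .conv_fwd(img, par$W1, par$b1); a1 <- pmax(c1$out, 0)
  p1 <- .pool_fwd(a1)
  c2 <- .conv_fwd(p1$out, par$W2, par$b2); a2 <- pmax(c2$out, 0)
  p2 <- .pool_fwd(a2)
  c3 <- .conv_fwd(p2$out, par$W3, par$b3); a3 <- pmax(c3$out, 0)
  p3 <- .pool_fwd(a3)
  flat <- as.vector(p3$out)
  h <- pmax(drop(flat %*% par$F1) + par$f1, 0)
  logits <- drop(h %*% par$F2) + par$f2
  out <- list(logits = logits)
  if (keep_cache)
    out$cache <- list(c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2, p2 = p2,
                      c3 = c3, a3 = a3, p3 = p3, flat = flat, h = h, img = img)
  out
}

.cnn_backward <- function(par, cache, dlogits) {
  g <- list()
  g$F2 <- outer(cache$h, dlogits); g$f2 <- dlogits
  dh <- drop(par$F2 %*% dlogits) * (cache$h > 0)
  g$F1 <- outer(cache$flat, dh); g$f1 <- dh
  dflat <- drop(par$F1 %*% dh)
  dp3 <- array(dflat, dim(cache$p3$out))
  da3 <- .pool_bwd(dp3, cache$p3$arg, dim(cache$a3)[1], dim(cache$a3)[2])
  dc3 <- da3 * (cache$c3$out > 0)
  b3 <- .conv_bwd(dc3, cache$c3, dim(cache$p2$out), par$W3)
  g$W3 <- b3$dW; g$b3 <- b3$db
  da2 <- .pool_bwd(b3$dx, cache$p2$arg, dim(cache$a2)[1], dim(cache$a2)[2])
  dc2 <- da2 * (cache$c2$out > 0)
  b2 <- .conv_bwd(dc2, cache$c2, dim(cache$p1$out), par$W2)
  g$W2 <- b2$dW; g$b2 <- b2$db
  da1 <- .pool_bwd(b2$dx, cache$p1$arg, dim(cache$a1)[1], dim(cache$a1)[2])
  dc1 <- da1 * (cache$c1$out > 0)
  b1 <- .conv_bwd(dc1, cache$c1, dim(cache$img), par$W1)
  g$W1 <- b1$dW; g$b1 <- b1$db
  g
}

.softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }

.prep_image <- function(img) img / 255 - 0.5

#' Predict class probabilities with a compact CNN
#' @param model a model from [train_compact_cnn()] (or its `par` field).
#' @param images list of `H x W x 3` arrays with values in 0..255.
#' @return matrix of class probabilities, one row per image.
#' @export
predict_cnn <- function(model, images) {
  par <- if (!is.null(model$par)) model$par else model
  t(vapply(images, function(im)
    .softmax(.cnn_forward(par, .prep_image(im))$logits),
    numeric(length(par$f2))))
}

#' Train the compact convolutional scalogram classifier
#'
#' Three 3x3 conv + ReLU + 2x2 max-pool blocks (8, 16, 32 channels), a
#' 32-unit dense layer and a softmax head, optimized on cross-entropy with
#' Adam. The history records per-epoch training/validation loss and
#' accuracy. Training is deterministic under `seed`.
#'
#' @param train,val lists with fields `images` (list of `H x W x 3` arrays,
#'   0..255) and `labels` (0/1). `val` may be `NULL`.
#' @param hyper list: `lr`, `epochs`, `batch_size`, `hidden`, `channels`.
#' @param seed integer seed for initialization and batch shuffling.
#' @return list of class `koro_cnn`: `par`, `history` (data.frame),
#'   `n_params`.
#' @export
train_compact_cnn <- function(train, val = NULL,
                              hyper = list(), seed = 1L) {
  hy <- utils::modifyList(list(lr = 1e-3, epochs = 20L, batch_size = 16L,
                               hidden = 32L, channels = c(8L, 16L, 32L)),
                          hyper)
  y <- as.integer(train$labels)
  if (length(unique(y)) < 2L) stop("degenerate single-class training set")
  dimg <- dim(train$images[[1]])
  par <- .cnn_init(dimg, hy$channels, hy$hidden, 2L, seed = seed)
  mstate <- lapply(par[1:10], function(p) p * 0)
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
  imgs <- lapply(train$images, .prep_image)
  vimgs <- if (!is.null(val)) lapply(val$images, .prep_image)
  hist_rows <- vector("list", hy$epochs)
  eval_set <- function(ims, labs) {
    loss <- 0; correct <- 0
    for (i in seq_along(ims)) {
      pr <- .softmax(.cnn_forward(par, ims[[i]])$logits)
      loss <- loss - log(max(pr[labs[i] + 1L], 1e-12))
      correct <- correct + (which.max(pr) - 1L == labs[i])
    }
    c(loss / length(ims), correct / length(ims))
  }
  order_seed <- .derive_seed(seed, 77L)
  for (ep in seq_len(hy$epochs)) {
    ord <- .with_seed(.derive_seed(order_seed, ep), sample(length(imgs)))
    for (bs in split(ord, ceiling(seq_along(ord) / hy$batch_size))) {
      grads <- NULL
      for (i in bs) {
        fw <- .cnn_forward(par, imgs[[i]], keep_cache = TRUE)
        pr <- .softmax(fw$logits)
        dl <- pr; dl[y[i] + 1L] <- dl[y[i] + 1L] - 1
        g <- .cnn_backward(par, fw$cache, dl / length(bs))
        grads <- if (is.null(grads)) g
                 else mapply(`+`, grads, g, SIMPLIFY = FALSE)
      }
      step <- step + 1
      for (nm in names(mstate)) {
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * grads[[nm]]
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * grads[[nm]]^2
        mh <- mstate[[nm]] / (1 - b1^step)
        vh <- vstate[[nm]] / (1 - b2^step)
        par[[nm]] <- par[[nm]] - hy$lr * mh / (sqrt(vh) + eps)
      }
    }
    tr <- eval_set(imgs, y)
    va <- if (!is.null(val)) eval_set(vimgs, as.integer(val$labels))
          else c(NA, NA)
    hist_rows[[ep]] <- data.frame(epoch = ep, train_loss = tr[1],
                                  train_acc = tr[2], val_loss = va[1],
                                  val_acc = va[2])
  }
  n_params <- sum(vapply(par[1:10], length, 1L))
  structure(list(par = par, history = do.call(rbind, hist_rows),
                 n_params = n_params), class = "koro_cnn")
}
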