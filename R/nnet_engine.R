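# Vectorized neural-network engine (internal).
#
# Implements the two forecaster architectures and their training loop in
# plain matrix algebra: 1D valid convolution along time (im2col), pairwise
# max-pooling, dense layers, a standard LSTM with BPTT, mean-squared-error
# loss, and SGD with momentum and element-wise gradient value clipping.
# Weights live in plain named lists so they can be serialized, inspected and
# quantized tensor by tensor.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

.add_bias <- function(Z, b) Z + matrix(b, nrow(Z), length(b), byrow = TRUE)

# ---- 1D convolution (valid, along time) ------------------------------------

# A: array (N, T, C); returns list(col = (N*Tout) x (k*C) matrix, tout)
.im2col <- function(A, k) {
  d <- dim(A)
  N <- d[1]; T <- d[2]; C <- d[3]
  tout <- T - k + 1
  M <- array(0, c(N, tout, k, C))
  for (j in seq_len(k)) M[, , j, ] <- A[, j:(j + tout - 1), ]
  dim(M) <- c(N * tout, k * C)
  list(col = M, tout = tout)
}

# scatter-add the im2col gradient back to the input shape
.col2im <- function(dcol, N, T, C, k) {
  tout <- T - k + 1
  dim(dcol) <- c(N, tout, k, C)
  dA <- array(0, c(N, T, C))
  for (j in seq_len(k))
    dA[, j:(j + tout - 1), ] <- dA[, j:(j + tout - 1), ] + dcol[, , j, ]
  dA
}

.conv1d_fwd <- function(A, W, b) {
  d <- dim(A)
  ic <- .im2col(A, k = nrow(W) / d[3])
  Z <- .add_bias(ic$col %*% W, b)
  Zarr <- array(Z, c(d[1], ic$tout, ncol(W)))
  list(out = Zarr, col = ic$col)
}

.conv1d_bwd <- function(dZ, cache_col, A_dim, W) {
  F <- ncol(W)
  dZm <- matrix(dZ, ncol = F)
  dW <- crossprod(cache_col, dZm)
  db <- colSums(dZm)
  dcol <- dZm %*% t(W)
  k <- nrow(W) / A_dim[3]
  dA <- .col2im(dcol, A_dim[1], A_dim[2], A_dim[3], k)
  list(dW = dW, db = db, dA = dA)
}

# ---- pairwise max pooling over time ----------------------------------------

.pool_fwd <- function(A) {
  d <- dim(A)
  P <- d[2] %/% 2L
  A1 <- A[, seq(1, 2 * P, by = 2), , drop = FALSE]
  A2 <- A[, seq(2, 2 * P, by = 2), , drop = FALSE]
  mask <- A1 >= A2          # ties take the earlier element (deterministic)
  out <- A1
  out[!mask] <- A2[!mask]
  list(out = out, mask = mask, in_dim = d)
}

.pool_bwd <- function(dOut, cache) {
  d <- cache$in_dim
  P <- dim(dOut)[2]
  dA <- array(0, d)
  dA[, seq(1, 2 * P, by = 2), ] <- dOut * cache$mask
  dA[, seq(2, 2 * P, by = 2), ] <- dOut * !cache$mask
  dA
}

# ---- CNN -------------------------------------------------------------------

# shape arithmetic for the CNN time axis; errors if any stage degenerates
.cnn_shapes <- function(window_len, config) {
  k <- config$kernel_time
  t1 <- window_len - k + 1
  if (t1 < 1) stop("kernel_time ", k, " too large for window of ", window_len)
  p1 <- t1 %/% 2L
  if (p1 < 1) stop("time axis collapses at first pooling stage")
  t2 <- p1 - k + 1
  if (t2 < 1) stop("kernel_time ", k, " too large after pooling (length ", p1, ")")
  p2 <- t2 %/% 2L
  if (p2 < 1) stop("time axis collapses at second pooling stage")
  list(t1 = t1, p1 = p1, t2 = t2, p2 = p2,
       flat = 3L * p2 * config$filters2)
}

.cnn_init <- function(config, window_len) {
  s <- .cnn_shapes(window_len, config)
  k <- config$kernel_time
  list(W1 = .glorot(k, config$filters1), b1 = numeric(config$filters1),
       W2 = .glorot(k * config$filters1, config$filters2),
       b2 = numeric(config$filters2),
       Wd = .glorot(s$flat, config$dense_units),
       bd = numeric(config$dense_units),
       Wo = .glorot(config$dense_units, 1L), bo = numeric(1))
}

# X: array (N, 3, window_len). The 3 feature rows share the convolution
# kernels: rows are folded into the batch axis, so filters mix only
# timestamps within one feature row.
# fq: optional list of activation-range fake-quantizers (full-integer
# emulation); each entry is applied to the named inter-layer tensor.
.cnn_fwd <- function(W, X, config, keep = FALSE, fq = NULL) {
  d <- dim(X)
  N <- d[1]
  # (N, 3, T) folds to (N*3, T, 1): feature rows join the batch axis, so the
  # shared kernels mix only timestamps within one feature row
  A0 <- array(X, c(N * 3L, d[3], 1L))
  if (!is.null(fq)) A0 <- fq$input(A0)
  c1 <- .conv1d_fwd(A0, W$W1, W$b1)
  A1 <- pmax(c1$out, 0)
  if (!is.null(fq)) A1 <- fq$conv1(A1)
  p1 <- .pool_fwd(A1)
  if (!is.null(fq)) p1$out <- fq$pool1(p1$out)
  c2 <- .conv1d_fwd(p1$out, W$W2, W$b2)
  A2 <- pmax(c2$out, 0)
  if (!is.null(fq)) A2 <- fq$conv2(A2)
  p2 <- .pool_fwd(A2)
  if (!is.null(fq)) p2$out <- fq$pool2(p2$out)
  # regroup rows: (N*3, P2, F2) -> (N, 3*P2*F2)
  d2 <- dim(p2$out)
  Xf <- matrix(array(p2$out, c(N, 3L * d2[2] * d2[3])), nrow = N)
  Zd <- .add_bias(Xf %*% W$Wd, W$bd)
  Ad <- pmax(Zd, 0)
  if (!is.null(fq)) Ad <- fq$dense(Ad)
  pred <- drop(.add_bias(Ad %*% W$Wo, W$bo))
  if (!is.null(fq)) pred <- fq$output(pred)
  if (!keep) return(list(pred = pred))
  list(pred = pred, A0 = A0, c1 = c1, A1 = A1, p1 = p1, c2 = c2, A2 = A2,
       p2 = p2, Xf = Xf, Zd = Zd, Ad = Ad)
}

.cnn_bwd <- function(W, cache, dpred, config) {
  N <- length(dpred)
  dp <- matrix(dpred, ncol = 1)
  dWo <- crossprod(cache$Ad, dp)
  dbo <- sum(dp)
  dAd <- dp %*% t(W$Wo)
  dZd <- dAd * (cache$Zd > 0)
  dWd <- crossprod(cache$Xf, dZd)
  dbd <- colSums(dZd)
  dXf <- dZd %*% t(W$Wd)
  d2 <- dim(cache$p2$out)
  dP2 <- array(dXf, d2)
  dA2 <- .pool_bwd(dP2, cache$p2)
  dZ2 <- dA2 * (cache$c2$out > 0)
  g2 <- .conv1d_bwd(dZ2, cache$c2$col, dim(cache$p1$out), W$W2)
  dP1 <- .pool_bwd(g2$dA, cache$p1)
  dZ1 <- dP1 * (cache$c1$out > 0)
  g1 <- .conv1d_bwd(dZ1, cache$c1$col, dim(cache$A0), W$W1)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       Wd = dWd, bd = dbd, Wo = dWo, bo = dbo)
}

# ---- LSTM ------------------------------------------------------------------

.lstm_init <- function(config, n_features, window_len) {
  H <- config$lstm_units
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1       # unit forget-gate bias
  list(Wx = .glorot(n_features, 4 * H), Wh = .glorot(H, 4 * H), b = b,
       Wd = .glorot(H, config$dense_units), bd = numeric(config$dense_units),
       Wo = .glorot(config$dense_units, 1L), bo = numeric(1))
}

# X: array (N, F, T) — the window layout; each timestep feeds the F features.
# Gate block order: input, forget, candidate, output.
.lstm_fwd <- function(W, X, config, keep = FALSE, fq = NULL) {
  d <- dim(X)
  N <- d[1]; T <- d[3]
  H <- config$lstm_units
  if (!is.null(fq)) X <- fq$input(X)
  h <- matrix(0, N, H)
  cc <- matrix(0, N, H)
  steps <- if (keep) vector("list", T) else NULL
  ii <- 1:H; ff <- (H + 1):(2 * H); gg <- (2 * H + 1):(3 * H)
  oo <- (3 * H + 1):(4 * H)
  for (t in seq_len(T)) {
    xt <- matrix(X[, , t], nrow = N)
    A <- .add_bias(xt %*% W$Wx + h %*% W$Wh, W$b)
    i <- .sigmoid(A[, ii, drop = FALSE])
    f <- .sigmoid(A[, ff, drop = FALSE])
    g <- tanh(A[, gg, drop = FALSE])
    o <- .sigmoid(A[, oo, drop = FALSE])
    c_prev <- cc
    cc <- f * cc + i * g
    if (!is.null(fq)) cc <- fq$lstm_c(cc)
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    if (!is.null(fq)) h <- fq$lstm_h(h)
    if (keep)
      steps[[t]] <- list(xt = xt, h_prev = h_prev, c_prev = c_prev,
                         i = i, f = f, g = g, o = o, cc = cc, tc = tc)
  }
  Zd <- .add_bias(h %*% W$Wd, W$bd)
  Ad <- pmax(Zd, 0)
  if (!is.null(fq)) Ad <- fq$dense(Ad)
  pred <- drop(.add_bias(Ad %*% W$Wo, W$bo))
  if (!is.null(fq)) pred <- fq$output(pred)
  if (!keep) return(list(pred = pred))
  list(pred = pred, steps = steps, h = h, Zd = Zd, Ad = Ad)
}

.lstm_bwd <- function(W, cache, dpred, config) {
  H <- config$lstm_units
  N <- length(dpred)
  T <- length(cache$steps)
  dp <- matrix(dpred, ncol = 1)
  dWo <- crossprod(cache$Ad, dp)
  dbo <- sum(dp)
  dAd <- dp %*% t(W$Wo)
  dZd <- dAd * (cache$Zd > 0)
  dWd <- crossprod(cache$h, dZd)
  dbd <- colSums(dZd)
  dh <- dZd %*% t(W$Wd)
  dc <- matrix(0, N, H)
  dWx <- matrix(0, nrow(W$Wx), ncol(W$Wx))
  dWh <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  for (t in T:1) {
    s <- cache$steps[[t]]
    do_ <- dh * s$tc
    dc <- dc + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    df <- dc * s$c_prev
    dg <- dc * s$i
    dA <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do_ * s$o * (1 - s$o))
    dWx <- dWx + crossprod(s$xt, dA)
    dWh <- dWh + crossprod(s$h_prev, dA)
    db <- db + colSums(dA)
    dh <- dA %*% t(W$Wh)
    dc <- dc * s$f
  }
  list(Wx = dWx, Wh = dWh, b = db, Wd = dWd, bd = dbd, Wo = dWo, bo = dbo)
}

# ---- generic dispatch ------------------------------------------------------

.net_init <- function(arch, config, window_len, n_features = 3L) {
  if (arch == "cnn") .cnn_init(config, window_len)
  else .lstm_init(config, n_features, window_len)
}

.net_fwd <- function(arch, W, X, config, keep = FALSE, fq = NULL) {
  if (arch == "cnn") .cnn_fwd(W, X, config, keep = keep, fq = fq)
  else .lstm_fwd(W, X, config, keep = keep, fq = fq)
}

.net_bwd <- function(arch, W, cache, dpred, config) {
  if (arch == "cnn") .cnn_bwd(W, cache, dpred, config)
  else .lstm_bwd(W, cache, dpred, config)
}

# fused compiled forward+backward on one mini-batch -> list(loss, <grads>)
.net_grad <- function(arch, W, X, y, config) {
  if (arch == "cnn")
    .cnn_grad_cpp(W$W1, W$b1, W$W2, W$b2, W$Wd, W$bd, W$Wo, W$bo, X, y)
  else
    .lstm_grad_cpp(W$Wx, W$Wh, W$b, W$Wd, W$bd, W$Wo, W$bo, X, y)
}

# forward in chunks to bound memory; X: (N, 3, wl). The compiled kernels are
# used for plain prediction; the R path carries the activation hooks needed
# by the full-integer quantization emulation.
.net_predict <- function(arch, W, X, config, chunk = 4096L, fq = NULL,
                         use_cpp = TRUE) {
  N <- dim(X)[1]
  if (N == 0) return(numeric(0))
  out <- numeric(N)
  for (s in seq(1, N, by = chunk)) {
    e <- min(s + chunk - 1L, N)
    Xc <- X[s:e, , , drop = FALSE]
    out[s:e] <- if (is.null(fq) && use_cpp) {
      if (arch == "cnn")
        .cnn_pred_cpp(W$W1, W$b1, W$W2, W$b2, W$Wd, W$bd, W$Wo, W$bo, Xc)
      else
        .lstm_pred_cpp(W$Wx, W$Wh, W$b, W$Wd, W$bd, W$Wo, W$bo, Xc)
    } else .net_fwd(arch, W, Xc, config, fq = fq)$pred
  }
  out
}

# ---- SGD with momentum + value clipping, early stopping --------------------

.mse <- function(pred, y) mean((pred - y)^2)

.net_train <- function(arch, config, Xtr, ytr, Xval, yval, control) {
  with_seed(control$seed, {
    W <- .net_init(arch, config, window_len = dim(Xtr)[length(dim(Xtr))])
    V <- lapply(W, function(w) w * 0)
    n <- dim(Xtr)[1]
    clip <- control$clip_value
    lr <- control$learning_rate
    mom <- control$momentum
    best_val <- Inf
    best_W <- W
    best_epoch <- 0L
    wait <- 0L
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
    for (epoch in seq_len(control$max_epochs)) {
      idx <- if (isTRUE(control$shuffle)) sample.int(n) else seq_len(n)
      tr_loss <- 0
      nb <- 0L
      for (s in seq(1, n, by = control$batch_size)) {
        e <- min(s + control$batch_size - 1L, n)
        bi <- idx[s:e]
        Xb <- Xtr[bi, , , drop = FALSE]
        yb <- ytr[bi]
        G <- .net_grad(arch, W, Xb, yb, config)
        loss <- G$loss
        if (!is.finite(loss))
          stop(sprintf("non-finite training loss (%s, epoch %d, batch at %d): check input scaling / learning rate",
                       arch, epoch, s))
        for (nm in names(W)) {
          g <- G[[nm]]
          if (!is.matrix(W[[nm]])) g <- as.numeric(g)
          g <- pmin(pmax(g, -clip), clip)
          V[[nm]] <- mom * V[[nm]] - lr * g
          W[[nm]] <- W[[nm]] + V[[nm]]
        }
        tr_loss <- tr_loss + loss
        nb <- nb + 1L
      }
      val_loss <- .mse(.net_predict(arch, W, Xval, config), yval)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_loss / nb,
                                     val_loss = val_loss))
      if (val_loss < best_val) {
        best_val <- val_loss
        best_W <- W
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= control$patience) break
      }
      if (isTRUE(control$verbose))
        message(sprintf("  epoch %3d  train %.4f  val %.4f", epoch,
                        tr_loss / nb, val_loss))
    }
    list(weights = best_W, history = hist, best_val = best_val,
         best_epoch = best_epoch)
  })
}
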