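## Low-level neural-network primitives: batched 1-D convolution via
## im2col + BLAS matmul, with hand-written backward passes, softmax
## cross-entropy, and the Adam optimizer. Kept free of any architecture
## knowledge; the model wiring lives in model.R.

## Geometry of a 1-D convolution: index map from output positions to
## (padded) input positions. `idx` is k x L_out, 1-based into the padded
## signal.
conv_plan <- function(L_in, k, stride = 1L, dilation = 1L, pad = 0L) {
  span <- (k - 1L) * dilation + 1L
  Lp <- L_in + 2L * pad
  if (Lp < span) stop("input shorter than the convolution kernel span")
  L_out <- (Lp - span) %/% stride + 1L
  starts <- (seq_len(L_out) - 1L) * stride + 1L
  idx <- outer((0:(k - 1L)) * dilation, starts, "+")
  storage.mode(idx) <- "integer"
  list(k = as.integer(k), pad = as.integer(pad), L_in = as.integer(L_in),
       L_out = as.integer(L_out), idx = idx)
}

## "same" padding for an odd kernel with dilation
conv_plan_same <- function(L_in, k, dilation = 1L) {
  conv_plan(L_in, k, stride = 1L, dilation = dilation,
            pad = (k - 1L) %/% 2L * dilation)
}

## X: (C_in, L_in, B) -> Y: (C_out, L_out, B). Hot path in C++
## (src/conv.cpp); the im2col matrix stays inside C++ and is regathered in
## the backward pass from the cached layer input. conv_fw_ref/conv_bw_ref
## are pure-R reference implementations kept as the independent cross-check
## in the test suite.
conv_fw <- function(X, W, b, plan, relu = FALSE) {
  cpp_conv_fw(X, W, b, plan$idx, plan$pad, relu)
}

## relu_out: the layer's rectified output; when given, dY is masked by
## (relu_out > 0) inside the kernel (fused ReLU backward).
conv_bw <- function(dY, W, X, plan, need_dx = TRUE, relu_out = NULL) {
  cpp_conv_bw(dY, W, X, plan$idx, plan$pad, need_dx, relu_out)
}

conv_fw_ref <- function(X, W, b, plan, relu = FALSE) {
  d <- dim(X); C <- d[1]; B <- d[3]
  Lp <- plan$L_in + 2L * plan$pad
  if (plan$pad > 0L) {
    Xp <- array(0, c(C, Lp, B))
    Xp[, plan$pad + seq_len(plan$L_in), ] <- X
  } else {
    Xp <- X
  }
  k <- plan$k; Lo <- plan$L_out
  Xcol <- array(0, c(C, k, Lo, B))
  for (kk in seq_len(k)) {
    Xcol[, kk, , ] <- Xp[, plan$idx[kk, ], , drop = FALSE]
  }
  dim(Xcol) <- c(C * k, Lo * B)
  Y <- W %*% Xcol + b
  if (relu) Y[Y < 0] <- 0
  dim(Y) <- c(nrow(W), Lo, B)
  Y
}

conv_bw_ref <- function(dY, W, X, plan, need_dx = TRUE, relu_out = NULL) {
  d <- dim(X); C <- d[1]; B <- d[3]
  Co <- nrow(W); Lo <- plan$L_out
  if (!is.null(relu_out)) dY <- dY * (relu_out > 0)
  dYm <- dY; dim(dYm) <- c(Co, Lo * B)
  Lp <- plan$L_in + 2L * plan$pad
  if (plan$pad > 0L) {
    Xp <- array(0, c(C, Lp, B))
    Xp[, plan$pad + seq_len(plan$L_in), ] <- X
  } else {
    Xp <- X
  }
  Xcol <- array(0, c(C, plan$k, Lo, B))
  for (kk in seq_len(plan$k)) {
    Xcol[, kk, , ] <- Xp[, plan$idx[kk, ], , drop = FALSE]
  }
  dim(Xcol) <- c(C * plan$k, Lo * B)
  dW <- tcrossprod(dYm, Xcol)
  db <- rowSums(dYm)
  dX <- NULL
  if (need_dx) {
    dXcol <- crossprod(W, dYm)
    dim(dXcol) <- c(C, plan$k, Lo, B)
    dXp <- array(0, c(C, Lp, B))
    for (kk in seq_len(plan$k)) {
      cols <- plan$idx[kk, ]
      dXp[, cols, ] <- dXp[, cols, ] + dXcol[, kk, , ]
    }
    dX <- if (plan$pad > 0L) {
      dXp[, plan$pad + seq_len(plan$L_in), , drop = FALSE]
    } else {
      dXp
    }
  }
  list(dW = dW, db = db, dX = dX)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## column-wise stable softmax of a K x F matrix
softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

## Weighted masked cross-entropy. y: integer labels (NA = masked),
## w_class: per-class loss weights. Returns loss and dlogits.
softmax_xent <- function(logits, y, w_class) {
  p <- softmax_cols(logits)
  valid <- which(!is.na(y))
  if (!length(valid)) return(list(loss = NA_real_, dlogits = NULL, p = p))
  w <- w_class[y[valid]]
  wsum <- sum(w)
  py <- p[cbind(y[valid], valid)]
  loss <- -sum(w * log(pmax(py, 1e-12))) / wsum
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[, valid] <- p[, valid, drop = FALSE] *
    rep(w / wsum, each = nrow(p))
  dlogits[cbind(y[valid], valid)] <-
    dlogits[cbind(y[valid], valid)] - w / wsum
  list(loss = loss, dlogits = dlogits, p = p)
}

## ---------------------------------------------------------------------------
## Adam (adaptive moment estimation)
## ---------------------------------------------------------------------------

adam_init <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(opt = opt, params = params)
}
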