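## Vectorized 1-D convolution plumbing.  Batches live in (L, C, B) arrays;
## convolutions are im2col + one BLAS GEMM; backprop mirrors each step.
## Row order of every patch matrix is position-fastest-within-sample:
## row (b - 1) * P + p holds sample b, output position p.

## Patch-index cache: the linear gather indices of an im2col call depend
## only on the geometry, so they are built once per (L, C, B, w, stride)
## and reused across batches.  Very large geometries fall back to the
## slice-by-offset path instead of caching a huge index.
.im2col_cache <- new.env(parent = emptyenv())

im2col <- function(A, w, stride = 1L, pad = c(0L, 0L)) {
  d <- dim(A); L <- d[1L]; C <- d[2L]; B <- d[3L]
  if (pad[1L] > 0L || pad[2L] > 0L) {
    Ap <- array(0, dim = c(L + pad[1L] + pad[2L], C, B))
    Ap[pad[1L] + seq_len(L), , ] <- A
    A <- Ap
    L <- L + pad[1L] + pad[2L]
  }
  P <- (L - w) %/% stride + 1L
  if (as.double(P) * B * w * C > 4e7) return(im2col_slices(A, w, stride, P, C, B))
  key <- paste(L, C, B, w, stride, sep = "_")
  cc <- .im2col_cache[[key]]
  if (is.null(cc)) {
    pos <- seq(1L, by = stride, length.out = P)
    rowpart <- rep(pos, times = B) + rep((seq_len(B) - 1L) * (L * C), each = P)
    colpart <- rep(seq_len(w) - 1L, each = C) + rep((seq_len(C) - 1L) * L, times = w)
    idx <- as.vector(outer(rowpart, colpart, "+"))
    cc <- list(idx = idx, d = c(P * B, w * C))
    .im2col_cache[[key]] <- cc
  }
  X <- A[cc$idx]
  dim(X) <- cc$d
  X
}

im2col_slices <- function(A, w, stride, P, C, B) {
  pos <- seq(1L, by = stride, length.out = P)
  X <- matrix(0, nrow = P * B, ncol = w * C)
  for (o in seq_len(w)) {
    sl <- A[pos + o - 1L, , , drop = FALSE]            # (P, C, B)
    X[, ((o - 1L) * C + 1L):(o * C)] <- matrix(aperm(sl, c(1L, 3L, 2L)), P * B, C)
  }
  X
}

## Second-convolution patch extraction straight from the (P1 * B) x K1
## activation matrix: a cached linear-index gather whose out-of-window
## (padding) entries point at a zero sentinel appended to the data.
## The backward scatter reuses the same indices block by block, adding
## contributions in ascending kernel-offset order.
conv2_cache_get <- function(P1, K1, B, w, stride, pad) {
  key <- paste("c2", P1, K1, B, w, stride, pad[1L], pad[2L], sep = "_")
  cc <- .im2col_cache[[key]]
  if (!is.null(cc)) return(cc)
  Lp <- P1 + pad[1L] + pad[2L]
  P2 <- (Lp - w) %/% stride + 1L
  pos <- seq(1L, by = stride, length.out = P2)
  sentinel <- as.double(P1) * B * K1 + 1
  rowpart <- rep(pos, times = B) + rep((seq_len(B) - 1L) * P1, each = P2)
  colpart <- rep(seq_len(w) - 1L, each = K1) +
    rep((seq_len(K1) - 1L) * (P1 * B), times = w)
  idx <- outer(rowpart - pad[1L], colpart, "+")
  ## unpadded temporal coordinate of each cell, to mask the padding
  q <- outer(rep(pos, times = B) - pad[1L], rep(seq_len(w) - 1L, each = K1), "+")
  idx[q < 1L | q > P1] <- sentinel
  cc <- list(idx = as.vector(idx), d = c(P2 * B, w * K1),
             n_in = P1 * B * K1)
  .im2col_cache[[key]] <- cc
  cc
}

conv2_patches <- function(A1d, K1, B, w, stride, pad) {
  P1 <- nrow(A1d) %/% B
  if (as.double(P1) * B * w * K1 > 4e7) {
    arr1 <- aperm(array(A1d, dim = c(P1, B, K1)), c(1L, 3L, 2L))
    return(im2col(arr1, w, stride, pad))
  }
  cc <- conv2_cache_get(P1, K1, B, w, stride, pad)
  v <- c(A1d, 0)
  X <- v[cc$idx]
  dim(X) <- cc$d
  X
}

conv2_patches_bwd <- function(dX2, P1, K1, B, w, stride, pad) {
  if (as.double(P1) * B * w * K1 > 4e7) {
    dArr1 <- col2im(dX2, P1, K1, B, w, stride, pad)
    return(matrix(aperm(dArr1, c(1L, 3L, 2L)), P1 * B, K1))
  }
  cc <- conv2_cache_get(P1, K1, B, w, stride, pad)
  dvec <- numeric(cc$n_in + 1L)
  nr <- cc$d[1L]
  dX2v <- as.vector(dX2)
  for (o in seq_len(w)) {
    sl <- ((o - 1L) * K1 * nr + 1L):(o * K1 * nr)
    ib <- cc$idx[sl]                 # unique within a block except sentinel
    dvec[ib] <- dvec[ib] + dX2v[sl]
  }
  matrix(dvec[seq_len(cc$n_in)], P1 * B, K1)
}

col2im <- function(dX, L, C, B, w, stride = 1L, pad = c(0L, 0L)) {
  Lp <- L + pad[1L] + pad[2L]
  P <- (Lp - w) %/% stride + 1L
  pos <- seq(1L, by = stride, length.out = P)
  dA <- array(0, dim = c(Lp, C, B))
  for (o in seq_len(w)) {
    blk <- array(dX[, ((o - 1L) * C + 1L):(o * C)], dim = c(P, B, C))
    rows <- pos + o - 1L                               # distinct within one o
    dA[rows, , ] <- dA[rows, , , drop = FALSE] + aperm(blk, c(1L, 3L, 2L))
  }
  dA[pad[1L] + seq_len(L), , , drop = FALSE]
}

## Temporal max pooling on a (P * B) x K patch matrix.  Returns the pooled
## (P3 * B) x K matrix plus the winning global row of each pooled cell.
maxpool_fwd <- function(Y, P, B, size, stride) {
  K <- ncol(Y)
  P3 <- (P - size) %/% stride + 1L
  base <- rep((seq_len(B) - 1L) * P, each = P3) +
    rep((seq_len(P3) - 1L) * stride, times = B)        # row of window start - 1
  best <- Y[base + 1L, , drop = FALSE]
  best_row <- matrix(base + 1L, nrow = P3 * B, ncol = K)
  if (size > 1L) {
    for (r in 2L:size) {
      cand <- Y[base + r, , drop = FALSE]
      take <- cand > best
      best[take] <- cand[take]
      best_row[take] <- matrix(base + r, nrow = P3 * B, ncol = K)[take]
    }
  }
  list(out = best, argmax_row = best_row, P3 = P3)
}

maxpool_bwd <- function(dPooled, argmax_row, P, B, K) {
  dY <- numeric(P * B * K)
  lin <- as.vector(argmax_row + (col(argmax_row) - 1L) * (P * B))
  acc <- rowsum(as.vector(dPooled), group = lin)
  dY[as.integer(rownames(acc))] <- acc
  matrix(dY, nrow = P * B, ncol = K)
}

## Flatten (P3 * B) x K -> B x (P3 * K), feature order position-fastest.
flatten_fwd <- function(Pooled, P3, B, K) {
  t(matrix(aperm(array(Pooled, dim = c(P3, B, K)), c(1L, 3L, 2L)), P3 * K, B))
}

flatten_bwd <- function(dH, P3, B, K) {
  matrix(aperm(array(t(dH), dim = c(P3, K, B)), c(1L, 3L, 2L)), P3 * B, K)
}

dropout_mask <- function(n, rate) {
  if (rate <= 0) return(NULL)
  (runif(n) >= rate) / (1 - rate)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

relu <- function(x) {
  x[x < 0] <- 0
  x
}

BN_EPS <- 1e-3      # matches the common batch-norm default
BN_MOMENTUM <- 0.99

bn_fwd_train <- function(H, gamma, beta) {
  B <- nrow(H)
  mu <- colMeans(H)
  v <- colMeans(H * H) - mu * mu
  v[v < 0] <- 0
  sd <- sqrt(v + BN_EPS)
  xhat <- sweep(sweep(H, 2L, mu), 2L, sd, "/")
  list(out = sweep(xhat, 2L, gamma, "*") + rep(beta, each = B),
       xhat = xhat, sd = sd, mu = mu, var = v)
}

bn_fwd_infer <- function(H, gamma, beta, rmean, rvar) {
  B <- nrow(H)
  sd <- sqrt(rvar + BN_EPS)
  xhat <- sweep(sweep(H, 2L, rmean), 2L, sd, "/")
  sweep(xhat, 2L, gamma, "*") + rep(beta, each = B)
}

bn_bwd <- function(dY, cache, gamma) {
  B <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dH <- sweep(B * dxhat, 2L, s1) - sweep(cache$xhat, 2L, s2, "*")
  dH <- sweep(dH, 2L, B * cache$sd, "/")
  list(dH = dH, dgamma = dgamma, dbeta = dbeta)
}

glorot <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

rmsprop_step <- function(par, grads, state, lr, rho = 0.9, eps = 1e-7) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state[[nm]] <- rho * state[[nm]] + (1 - rho) * g * g
    par[[nm]] <- par[[nm]] - lr * g / (sqrt(state[[nm]]) + eps)
  }
  list(par = par, state = state)
}

branch_geometry <- function(cfg) {
  P1 <- WINDOW_LEN - cfg$conv1_size + 1L
  sp <- same_pad(P1, cfg$conv2_size, cfg$conv2_stride)
  P3 <- (sp$out - cfg$pool_size) %/% cfg$pool_stride + 1L
  list(P1 = P1, P2 = sp$out, pad = c(sp$left, sp$right), P3 = P3,
       flat = P3 * cfg$conv2_kernels)
}

## Forward pass through one branch.  `A` is (100, 4, B).  In training mode
## dropout masks are drawn from the current RNG; in inference mode dropout
## is the identity.  Returns the B x flat feature block plus, if requested,
## everything backprop needs.
branch_forward <- function(par, A, cfg, geom, train = FALSE, keep = FALSE) {
  B <- dim(A)[3L]
  X1 <- im2col(A, cfg$conv1_size)
  A1 <- relu(sweep(X1 %*% par$W1, 2L, par$b1, "+"))
  M1 <- if (train) dropout_mask(length(A1), cfg$dropout1) else NULL
  A1d <- apply_mask(A1, M1)

  X2 <- conv2_patches(A1d, cfg$conv1_kernels, B, cfg$conv2_size,
                      cfg$conv2_stride, geom$pad)
  A2 <- relu(sweep(X2 %*% par$W2, 2L, par$b2, "+"))
  M2 <- if (train) dropout_mask(length(A2), cfg$dropout2) else NULL
  A2d <- apply_mask(A2, M2)

  mp <- maxpool_fwd(A2d, geom$P2, B, cfg$pool_size, cfg$pool_stride)
  M3 <- if (train) dropout_mask(length(mp$out), cfg$dropout2) else NULL
  PooledD <- apply_mask(mp$out, M3)
  H <- flatten_fwd(PooledD, geom$P3, B, cfg$conv2_kernels)

  out <- list(H = H)
  if (keep) {
    out$cache <- list(X1 = X1, A1 = A1, M1 = M1, X2 = X2, A2 = A2, M2 = M2,
                      argmax_row = mp$argmax_row, M3 = M3, B = B)
  }
  out
}

branch_backward <- function(par, dH, cfg, geom, cache) {
  B <- cache$B
  K2 <- cfg$conv2_kernels
  dPooled <- apply_mask(flatten_bwd(dH, geom$P3, B, K2), cache$M3)
  dA2d <- maxpool_bwd(dPooled, cache$argmax_row, geom$P2, B, K2)
  dZ2 <- apply_mask(dA2d, cache$M2) * (cache$A2 > 0)
  dW2 <- crossprod(cache$X2, dZ2)
  db2 <- colSums(dZ2)
  dX2 <- tcrossprod(dZ2, par$W2)
  dA1d <- conv2_patches_bwd(dX2, geom$P1, cfg$conv1_kernels, B,
                            cfg$conv2_size, cfg$conv2_stride, geom$pad)
  dZ1 <- apply_mask(dA1d, cache$M1) * (cache$A1 > 0)
  dW1 <- crossprod(cache$X1, dZ1)
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}
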