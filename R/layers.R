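## Low-level differentiable layers.
##
## Image tensors are 4-d arrays [H, W, B, C] (batch before channel). That
## layout lets batch normalisation and the convolution input/output reshapes
## be plain `dim<-` assignments with no element permutation, which is the
## dominant cost of a pure-R implementation. Convolution weights are stored
## as matrices of shape (kh*kw*Cin) x Cout, with row ordering kernel-position
## fastest (column-major over the kernel window), then input channel, so a
## convolution is a single gather followed by one BLAS matmul. Every forward
## returns the output plus the cache its backward needs.

## Gather-index table for im2col. For each output position/batch row and each
## (kernel offset, channel) column it holds the linear index into the input
## tensor, or N+1 for positions that fall in the zero padding (the gather
## source is c(x, 0)). Tables depend only on shapes, so they are memoised.
.fh_conv_idx_cache <- new.env(parent = emptyenv())

.fh_conv_idx <- function(H, W, B, C, kh, kw, stride, pad) {
  key <- paste(H, W, B, C, kh, kw, stride, pad, sep = "_")
  hit <- .fh_conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- (H + 2L * pad - kh) %/% stride + 1L
  Wo <- (W + 2L * pad - kw) %/% stride + 1L
  oi <- rep(seq_len(Ho), times = Wo)
  oj <- rep(seq_len(Wo), each = Ho)
  N <- H * W * B * C
  K <- kh * kw
  P <- Ho * Wo
  idx <- matrix(0L, P * B, K * C)
  boff <- rep((seq_len(B) - 1L) * (H * W), each = P)
  for (dj in seq_len(kw)) {
    cc <- (oj - 1L) * stride + dj - pad
    for (di in seq_len(kh)) {
      rr <- (oi - 1L) * stride + di - pad
      base <- rr + (cc - 1L) * H
      base[rr < 1L | rr > H | cc < 1L | cc > W] <- NA_integer_
      col0 <- rep(base, times = B) + boff
      k <- di + (dj - 1L) * kh
      for (ch in seq_len(C)) {
        v <- col0 + (ch - 1L) * (H * W * B)
        v[is.na(v)] <- N + 1L
        idx[, k + (ch - 1L) * K] <- v
      }
    }
  }
  entry <- list(idx = idx, Ho = Ho, Wo = Wo, K = K)
  .fh_conv_idx_cache[[key]] <- entry
  entry
}

conv2d_forward <- function(x, W, b, stride = 1L, pad = 1L, kh = NULL) {
  d <- dim(x); B <- d[3]; C <- d[4]
  if (is.null(kh)) kh <- as.integer(sqrt(nrow(W) / C))
  ci <- .fh_conv_idx(d[1], d[2], B, C, kh, kh, as.integer(stride),
                     as.integer(pad))
  cols <- c(x, 0)[ci$idx]
  dim(cols) <- dim(ci$idx)
  outm <- cols %*% W
  outm <- outm + rep(b, each = nrow(outm))
  dim(outm) <- c(ci$Ho, ci$Wo, B, ncol(W))
  list(out = outm,
       cache = list(cols = cols, W = W, d = d, ci = ci))
}

conv2d_backward <- function(dout, cache) {
  d <- cache$d; B <- d[3]; C <- d[4]
  ci <- cache$ci
  doutm <- dout
  dim(doutm) <- c(ci$Ho * ci$Wo * B, ncol(cache$W))
  dW <- crossprod(cache$cols, doutm)
  db <- colSums(doutm)
  dcols <- tcrossprod(doutm, cache$W)
  N <- prod(d)
  dxv <- numeric(N + 1L)
  K <- ci$K
  chcols <- (seq_len(C) - 1L) * K
  for (k in seq_len(K)) {
    ## within one kernel offset every in-bounds index is distinct, so a
    ## vectorised read-add-write accumulates correctly; clashes only happen
    ## at the padding slot N+1, which is discarded below
    ik <- ci$idx[, k + chcols]
    dxv[ik] <- dxv[ik] + dcols[, k + chcols]
  }
  dx <- dxv[seq_len(N)]
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

## batch normalisation over (H, W, B) per channel; x is [H, W, B, C]
bn2d_forward <- function(x, gamma, beta, rm, rv, train, momentum = 0.1,
                         eps = 1e-5) {
  d <- dim(x); C <- d[4]
  xm <- x
  dim(xm) <- c(d[1] * d[2] * d[3], C)
  res <- bn1d_forward(xm, gamma, beta, rm, rv, train, momentum, eps)
  dim(res$out) <- d
  res$cache$d <- d
  res
}

bn2d_backward <- function(dout, cache) {
  d <- cache$d
  doutm <- dout
  dim(doutm) <- c(d[1] * d[2] * d[3], d[4])
  res <- bn1d_backward(doutm, cache)
  dim(res$dx) <- d
  res
}

## batch normalisation over rows of an N x C matrix (per feature column)
bn1d_forward <- function(x, gamma, beta, rm, rv, train, momentum = 0.1,
                         eps = 1e-5) {
  n <- nrow(x)
  if (train) {
    mu <- colMeans(x)
    ## the moment form can go fractionally negative for near-constant columns
    va <- pmax(colMeans(x^2) - mu^2, 0)
    rm_new <- (1 - momentum) * rm + momentum * mu
    rv_new <- (1 - momentum) * rv + momentum * va
  } else {
    mu <- rm; va <- rv; rm_new <- rm; rv_new <- rv
  }
  invstd <- 1 / sqrt(va + eps)
  ## fused scale/shift: out = x * (gamma * invstd) + (beta - mu * gamma * invstd)
  a <- gamma * invstd
  out <- x * rep(a, each = n) + rep(beta - mu * a, each = n)
  list(out = out,
       cache = list(x = x, mu = mu, invstd = invstd, gamma = gamma,
                    train = train),
       rm = rm_new, rv = rv_new)
}

bn1d_backward <- function(dout, cache) {
  nx <- nrow(cache$x)
  xhat <- (cache$x - rep(cache$mu, each = nx)) * rep(cache$invstd, each = nx)
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  n <- nrow(dout)
  dxh <- dout * rep(cache$gamma, each = n)
  if (cache$train) {
    dx <- (dxh - rep(colSums(dxh) / n, each = n) -
             xhat * rep(colSums(dxh * xhat) / n, each = n)) *
      rep(cache$invstd, each = n)
  } else {
    dx <- dxh * rep(cache$invstd, each = n)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_backward <- function(dout, mask) {
  dout * mask
}

linear_forward <- function(x, W, b) {
  out <- x %*% W
  out <- out + rep(b, each = nrow(out))
  list(out = out, cache = list(x = x, W = W))
}

linear_backward <- function(dout, cache) {
  list(dx = tcrossprod(dout, cache$W),
       dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

dropout_forward <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, cache = NULL))
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= p) / (1 - p)
  list(out = x * mask, cache = mask)
}

dropout_backward <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

## global average pooling [H, W, B, C] -> B x C
gap_forward <- function(x) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1] * d[2])     # (HW) x (B*C)
  matrix(colMeans(xm), d[3], d[4])        # B x C
}

gap_backward <- function(dout, d) {
  ## dout is B x C
  array(rep(as.vector(dout) / (d[1] * d[2]), each = d[1] * d[2]), d)
}
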