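# Low-level tensor ops for the network engine.
#
# Feature maps are carried in a flat "column-matrix" layout: a (H*W*N) x C
# matrix whose rows are ordered position-fastest then image, one column per
# channel, wrapped in a record `fm(m, H, W, N)`. Pooled descriptors are
# plain N x C matrices. This layout lets convolution, batch-norm and
# activation chains run without any array transposition, and keeps every
# channel as one contiguous column.
#
# Convolutions run as cached fancy-indexing (im2col with an explicit zero
# slot standing in for padding) followed by GEMM. Two accumulation modes
# exist: "fused" (one GEMM over the full K dimension, fastest, used in
# training) and "exact" (per-input-channel GEMMs summed in channel order,
# used in eval mode). The exact mode guarantees that removing a channel
# whose contribution is exactly zero leaves every downstream value
# bit-identical, which is what makes structured pruning numerically exact.

fm <- function(m, H, W, N) list(m = m, H = H, W = W, N = N)

fm_from_array <- function(x) {
  d <- dim(x)
  arr <- aperm(array(x, c(d[1] * d[2], d[3], d[4])), c(1L, 3L, 2L))
  fm(matrix(arr, d[1] * d[2] * d[4], d[3]), d[1], d[2], d[4])
}

fm_to_array <- function(f, C = ncol(f$m)) {
  arr <- array(f$m, c(f$H * f$W, f$N, C))
  array(aperm(arr, c(1L, 3L, 2L)), c(f$H, f$W, C, f$N))
}

# cache of im2col index tensors, keyed by full geometry incl. batch size
.mr_im2col_cache <- new.env(parent = emptyenv())

mr_clear_cache <- function() {
  rm(list = ls(.mr_im2col_cache), envir = .mr_im2col_cache)
}

# Index tensor of dim (Mpos, N, k^2*C) into the flat colmat vector augmented
# with one trailing zero slot (position len+1) that absorbs padding reads.
# Columns are channel-contiguous: cols (ci-1)*k^2 + 1:k^2 belong to ci.
im2col_info <- function(H, W, C, N, k, stride, pad) {
  key <- paste(H, W, C, N, k, stride, pad, sep = "_")
  hit <- .mr_im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hout <- (H + 2L * pad - k) %/% stride + 1L
  Wout <- (W + 2L * pad - k) %/% stride + 1L
  if (Hout < 1L || Wout < 1L) {
    stop("convolution output collapsed: input ", H, "x", W,
         " too small for kernel ", k, " stride ", stride)
  }
  Mpos <- Hout * Wout
  zslot <- H * W * N * C + 1L
  base_h <- (seq_len(Hout) - 1L) * stride - pad      # 0-based source row - 1
  base_w <- (seq_len(Wout) - 1L) * stride - pad
  # spatial source coordinates per (pos, tap)
  hh <- outer(rep(base_h, times = Wout), rep(seq_len(k), k), `+`)   # Mpos x k2
  ww <- outer(rep(base_w, each = Hout), rep(seq_len(k), each = k), `+`)
  valid <- hh >= 1L & hh <= H & ww >= 1L & ww <= W
  sp <- hh + H * (ww - 1L)                                          # Mpos x k2
  k2 <- k * k
  idx <- array(0L, c(Mpos, N, k2 * C))
  HW <- H * W
  HWN <- HW * N
  n_off <- HW * (seq_len(N) - 1L)
  for (ci in seq_len(C)) {
    c_off <- HWN * (ci - 1L)
    for (t in seq_len(k2)) {
      col <- (ci - 1L) * k2 + t
      v <- sp[, t] + c_off
      v[!valid[, t]] <- NA_integer_
      m <- outer(v, n_off, `+`)
      m[is.na(m)] <- zslot
      idx[, , col] <- m
    }
  }
  out <- list(idx = idx, Hout = Hout, Wout = Wout, Mpos = Mpos, k2 = k2,
              C = C, N = N, zslot = zslot, in_len = H * W * N * C)
  .mr_im2col_cache[[key]] <- out
  out
}

# patches matrix: (Mpos*N) x (k^2*C), rows ordered position-fastest per image
im2col_patches <- function(f, info) {
  xq <- c(f$m, 0)
  P <- xq[info$idx]
  dim(P) <- c(info$Mpos * info$N, info$k2 * info$C)
  P
}

conv2d_forward <- function(f, W, k, stride, pad, groups, exact = FALSE) {
  C <- ncol(f$m)
  info <- im2col_info(f$H, f$W, C, f$N, k, stride, pad)
  P <- im2col_patches(f, info)
  k2 <- info$k2
  if (groups == 1L) {
    if (exact) {
      Cout <- ncol(W)
      out <- matrix(0, nrow(P), Cout)
      for (ci in seq_len(C)) {
        cols <- (ci - 1L) * k2 + seq_len(k2)
        out <- out + P[, cols, drop = FALSE] %*% W[cols, , drop = FALSE]
      }
    } else {
      out <- P %*% W
    }
  } else {
    # depthwise: W is k^2 x C, inherently channel-ordered (exact by design)
    out <- matrix(0, nrow(P), C)
    for (ci in seq_len(C)) {
      cols <- (ci - 1L) * k2 + seq_len(k2)
      out[, ci] <- P[, cols, drop = FALSE] %*% W[, ci]
    }
  }
  list(out = fm(out, info$Hout, info$Wout, f$N), P = P, info = info)
}

conv2d_backward <- function(dmat, cache, W, groups, need_dx = TRUE) {
  info <- cache$info
  P <- cache$P
  C <- info$C
  k2 <- info$k2
  if (groups == 1L) {
    dW <- crossprod(P, dmat)
    dP <- if (need_dx) tcrossprod(dmat, W)
  } else {
    dW <- matrix(0, k2, C)
    dP <- if (need_dx) matrix(0, nrow(P), ncol(P))
    for (ci in seq_len(C)) {
      cols <- (ci - 1L) * k2 + seq_len(k2)
      dW[, ci] <- crossprod(P[, cols, drop = FALSE], dmat[, ci])
      if (need_dx) dP[, cols] <- outer(dmat[, ci], W[, ci])
    }
  }
  dx <- NULL
  if (need_dx) {
    # scatter-add back through the index tensor; the zero slot swallows the
    # padding gradient. Within one column all valid targets are distinct.
    acc <- numeric(info$in_len + 1L)
    for (j in seq_len(ncol(P))) {
      tgt <- info$idx[, , j]
      acc[tgt] <- acc[tgt] + dP[, j]
    }
    dx <- matrix(acc[-length(acc)], ncol = C)
  }
  list(dx = dx, dW = dW)
}

col_center <- function(m, v) m - rep(v, each = nrow(m))
col_scale <- function(m, v) m * rep(v, each = nrow(m))

bn_forward <- function(f, gamma, beta, running_mean, running_var, eps,
                       momentum, training) {
  xm <- f$m
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu * mu
    istd <- 1 / sqrt(v + eps)
    s <- gamma * istd
    ym <- col_center(col_scale(xm, s), mu * s - beta)
    list(out = fm(ym, f$H, f$W, f$N), mu = mu, istd = istd,
         new_mean = (1 - momentum) * running_mean + momentum * mu,
         new_var = (1 - momentum) * running_var + momentum * v)
  } else {
    g <- gamma / sqrt(running_var + eps)
    b <- beta - running_mean * g
    list(out = fm(col_center(col_scale(xm, g), -b), f$H, f$W, f$N))
  }
}

bn_backward <- function(dm, cache, gamma, x) {
  M <- nrow(dm)
  xhat <- col_scale(col_center(x, cache$mu), cache$istd)
  dgamma <- colSums(dm * xhat)
  dbeta <- colSums(dm)
  dxm <- col_scale(
    col_center(dm, dbeta / M) - col_scale(xhat, dgamma / M),
    gamma * cache$istd
  )
  list(dx = dxm, dgamma = dgamma, dbeta = dbeta)
}

act_forward <- function(x, kind) {
  switch(kind,
    relu = pmax(x, 0),
    hswish = x * pmin(pmax(x + 3, 0), 6) / 6,
    hsigmoid = pmin(pmax(x + 3, 0), 6) / 6,
    sigmoid = 1 / (1 + exp(-x)),
    stop("unknown activation: ", kind)
  )
}

act_backward <- function(dout, x, out, kind) {
  switch(kind,
    relu = dout * (x > 0),
    hswish = {
      r6 <- pmin(pmax(x + 3, 0), 6)
      inside <- (x > -3) & (x < 3)
      dout * (r6 + x * inside) / 6
    },
    hsigmoid = dout * ((x > -3) & (x < 3)) / 6,
    sigmoid = dout * out * (1 - out),
    stop("unknown activation: ", kind)
  )
}

# global average pool: fm -> N x C descriptor
gap_forward <- function(f) {
  C <- ncol(f$m)
  matrix(colMeans(matrix(f$m, f$H * f$W, f$N * C)), f$N, C)
}

gap_backward <- function(dz, f_in) {
  hw <- f_in$H * f_in$W
  C <- ncol(dz)
  g <- matrix(rep(c(dz) / hw, each = hw), hw * f_in$N, C)
  g
}

# broadcast N x C gates over the rows of an fm matrix
gate_rows <- function(g, Mpos) {
  g[rep(seq_len(nrow(g)), each = Mpos), , drop = FALSE]
}

# per-image channel sums of an fm matrix: N x C
fm_image_colsums <- function(m, Mpos, N) {
  C <- ncol(m)
  matrix(colSums(matrix(m, Mpos, N * C)), N, C)
}

linear_forward <- function(x, W, b, exact = FALSE) {
  if (exact) {
    out <- matrix(rep(b, each = nrow(x)), nrow(x), length(b))
    for (ci in seq_len(ncol(x))) {
      out <- out + outer(x[, ci], W[ci, ])
    }
    out
  } else {
    out <- x %*% W
    out + rep(b, each = nrow(out))
  }
}

conv1d_channel_forward <- function(z, w) {
  k <- length(w)
  h <- (k - 1L) %/% 2L
  N <- nrow(z); C <- ncol(z)
  zp <- cbind(matrix(0, N, h), z, matrix(0, N, h))
  out <- matrix(0, N, C)
  for (t in seq_len(k)) {
    out <- out + w[t] * zp[, t + 0:(C - 1L), drop = FALSE]
  }
  out
}

conv1d_channel_backward <- function(dout, z, w) {
  k <- length(w)
  h <- (k - 1L) %/% 2L
  N <- nrow(z); C <- ncol(z)
  zp <- cbind(matrix(0, N, h), z, matrix(0, N, h))
  dw <- numeric(k)
  dzp <- matrix(0, N, C + 2L * h)
  for (t in seq_len(k)) {
    cols <- t + 0:(C - 1L)
    dw[t] <- sum(dout * zp[, cols, drop = FALSE])
    dzp[, cols] <- dzp[, cols] + w[t] * dout
  }
  list(dz = dzp[, h + seq_len(C), drop = FALSE], dw = dw)
}
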