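# Minimal CNN engine.
#
# Feature maps are (H*W) x C matrices, spatial positions flattened
# column-major exactly as R flattens an H x W matrix. Convolutions are
# same-padded 3x3, realised as im2col gathers followed by one BLAS matrix
# multiply; 2x2/stride-2 max-pooling records flat argmax indices so SegNet
# can unpool through them. All gathers use precomputed index vectors cached
# per spatial size.

.nt_cache <- new.env(parent = emptyenv())

conv_idx <- function(H, W) {
  key <- sprintf("c%d_%d", H, W)
  hit <- .nt_cache[[key]]
  if (!is.null(hit)) return(hit)
  rows <- rep(seq_len(H), times = W)
  cols <- rep(seq_len(W), each = H)
  offs <- vector("list", 9L)
  k <- 0L
  for (dc in -1:1) {
    for (dr in -1:1) {
      k <- k + 1L
      offs[[k]] <- (cols + dc) * (H + 2L) + rows + dr + 1L
    }
  }
  out <- list(inner = cols * (H + 2L) + rows + 1L, offs = offs)
  .nt_cache[[key]] <- out
  out
}

# flat indices of the four pixels of each 2x2 block of an H x W grid,
# in block order (top-left, bottom-left, top-right, bottom-right)
pool_idx <- function(H, W) {
  key <- sprintf("p%d_%d", H, W)
  hit <- .nt_cache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- H %/% 2L; wp <- W %/% 2L
  pr <- rep(seq_len(hp), times = wp)
  pc <- rep(seq_len(wp), each = hp)
  out <- lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)),
                function(d) (2L * pc - 2L + d[2]) * H + 2L * pr - 1L + d[1])
  .nt_cache[[key]] <- out
  out
}

add_bias <- function(y, b) y + rep(b, each = nrow(y))

conv3_fwd <- function(x, H, W, Wm, b, keep = TRUE) {
  cin <- ncol(x)
  ix <- conv_idx(H, W)
  P <- matrix(0, (H + 2L) * (W + 2L), cin)
  P[ix$inner, ] <- x
  X <- matrix(0, H * W, 9L * cin)
  for (k in 1:9) {
    X[, (k - 1L) * cin + seq_len(cin)] <- P[ix$offs[[k]], , drop = FALSE]
  }
  y <- add_bias(X %*% Wm, b)
  list(y = y, X = if (keep) X else NULL)
}

conv3_bwd <- function(dy, X, Wm, H, W, cin) {
  ix <- conv_idx(H, W)
  dXc <- dy %*% t(Wm)
  dP <- matrix(0, (H + 2L) * (W + 2L), cin)
  for (k in 1:9) {
    dP[ix$offs[[k]], ] <- dP[ix$offs[[k]], ] + dXc[, (k - 1L) * cin + seq_len(cin)]
  }
  list(dx = dP[ix$inner, , drop = FALSE],
       dW = crossprod(X, dy), db = colSums(dy))
}

relu_fwd <- function(x) {
  m <- x > 0
  x[!m] <- 0
  list(y = x, m = m)
}

relu_bwd <- function(dy, m) {
  dy[!m] <- 0
  dy
}

# 2x2 stride-2 max-pool; K holds, per pooled position and channel, the flat
# input row index of the maximum (ties broken towards the earliest block
# pixel in column-major order, deterministically).
maxpool_fwd <- function(x, H, W) {
  ii <- pool_idx(H, W)
  np <- (H %/% 2L) * (W %/% 2L)
  C <- ncol(x)
  best <- x[ii[[1]], , drop = FALSE]
  K <- matrix(ii[[1]], np, C)
  for (m in 2:4) {
    cand <- x[ii[[m]], , drop = FALSE]
    sel <- cand > best
    if (any(sel)) {
      best[sel] <- cand[sel]
      Km <- matrix(ii[[m]], np, C)
      K[sel] <- Km[sel]
    }
  }
  list(y = best, K = K)
}

# place v back at the recorded argmax positions of an H x W map, zeros
# elsewhere (SegNet unpooling; also the max-pool gradient router)
unpool_scatter <- function(v, K, H, W) {
  z <- matrix(0, H * W, ncol(v))
  for (ch in seq_len(ncol(v))) z[K[, ch], ch] <- v[, ch]
  z
}

unpool_gather <- function(dz, K) {
  dv <- matrix(0, nrow(K), ncol(K))
  for (ch in seq_len(ncol(K))) dv[, ch] <- dz[K[, ch], ch]
  dv
}

# 2x2 stride-2 transposed convolution (learned upsampling); weights are
# Cin x (4*Cout), one Cout block per output sub-position.
upconv_fwd <- function(x, H, W, Wu, b) {
  cout <- length(b)
  Y4 <- x %*% Wu
  oo <- pool_idx(2L * H, 2L * W)
  out <- matrix(0, 4L * H * W, cout)
  for (m in 1:4) {
    out[oo[[m]], ] <- Y4[, (m - 1L) * cout + seq_len(cout), drop = FALSE]
  }
  add_bias(out, b)
}

upconv_bwd <- function(dout, x, Wu, cout, H, W) {
  oo <- pool_idx(2L * H, 2L * W)
  dY4 <- matrix(0, H * W, 4L * cout)
  for (m in 1:4) {
    dY4[, (m - 1L) * cout + seq_len(cout)] <- dout[oo[[m]], , drop = FALSE]
  }
  list(dx = dY4 %*% t(Wu), dW = crossprod(x, dY4), db = colSums(dout))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# He-normal initialisers (ReLU-matched fan-in scaling)
init_conv3 <- function(cin, cout) {
  list(W = matrix(stats::rnorm(9L * cin * cout, sd = sqrt(2 / (9L * cin))),
                  9L * cin, cout),
       b = numeric(cout))
}

init_upconv <- function(cin, cout) {
  list(W = matrix(stats::rnorm(cin * 4L * cout, sd = sqrt(2 / cin)),
                  cin, 4L * cout),
       b = numeric(cout))
}

init_conv1 <- function(cin, cout) {
  list(W = matrix(stats::rnorm(cin * cout, sd = sqrt(1 / cin)), cin, cout),
       b = numeric(cout))
}
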