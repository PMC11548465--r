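# Dense 2-D cross-correlation on plain arrays, shared by the dynamic
# convolution operator, the attention gates and the image-processing helpers.

# x: h x w x cin array (a matrix is treated as cin = 1);
# kernel: k x k x cin x cout; zero padding; output follows standard
# convolution arithmetic: floor((h + 2*padding - k)/stride) + 1.
conv2d <- function(x, kernel, stride = 1L, padding = 0L) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  dk <- dim(kernel)
  if (length(dk) == 2L) kernel <- array(kernel, c(dk, 1L, 1L))
  dk <- dim(kernel)
  k <- dk[1]
  if (dk[2] != k) stop_validation("only square kernels are supported")
  cin <- dk[3]; cout <- dk[4]
  if (dim(x)[3] != cin)
    stop_validation("input has ", dim(x)[3], " channels but kernel expects ", cin)
  assert_finite(kernel, "kernel")
  if (padding > 0L) {
    h <- dim(x)[1]; w <- dim(x)[2]
    xp <- array(0, c(h + 2L * padding, w + 2L * padding, cin))
    xp[padding + seq_len(h), padding + seq_len(w), ] <- x
    x <- xp
  }
  H <- dim(x)[1]; W <- dim(x)[2]
  if (H < k || W < k) stop_validation("input smaller than kernel after padding")
  ho <- (H - k) %/% stride + 1L
  wo <- (W - k) %/% stride + 1L
  ri <- seq(1L, by = stride, length.out = ho)
  ci <- seq(1L, by = stride, length.out = wo)
  out <- array(0, c(ho, wo, cout))
  for (oc in seq_len(cout)) {
    acc <- matrix(0, ho, wo)
    for (ic in seq_len(cin)) {
      xc <- x[, , ic]
      for (ki in seq_len(k)) for (kj in seq_len(k)) {
        wgt <- kernel[ki, kj, ic, oc]
        if (wgt != 0) acc <- acc + wgt * xc[ri + ki - 1L, ci + kj - 1L, drop = FALSE]
      }
    }
    out[, , oc] <- acc
  }
  out
}

# 1x1 convolution: per-pixel linear map across channels. M is cin x cout.
conv1x1 <- function(x, M) {
  d <- dim(x)
  if (d[3] != nrow(M)) stop_validation("channel mismatch in 1x1 convolution")
  array(matrix(x, d[1] * d[2], d[3]) %*% M, c(d[1], d[2], ncol(M)))
}

# Single-channel convolution with 'same' zero padding (odd kernels only),
# used for smoothing and blur.
conv_same <- function(m, kern) {
  k <- nrow(kern)
  out <- conv2d(m, array(kern, c(k, k, 1L, 1L)), stride = 1L,
                padding = (k - 1L) %/% 2L)
  out[, , 1L]
}

gaussian_kernel <- function(sigma, radius = ceiling(2.5 * sigma)) {
  g <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Separable Gaussian smoothing with zero padding at the borders; equivalent
# to conv_same with the full 2-D kernel but ~k times faster.
gauss_smooth <- function(m, sigma, radius = 2L) {
  g <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  g <- g / sum(g)
  h <- nrow(m); w <- ncol(m)
  acc <- matrix(0, h, w)
  for (k in seq_along(g)) {       # vertical pass
    o <- k - radius - 1L
    src <- max(1L, 1L + o):min(h, h + o)
    acc[src - o, ] <- acc[src - o, ] + g[k] * m[src, ]
  }
  out <- matrix(0, h, w)
  for (k in seq_along(g)) {       # horizontal pass
    o <- k - radius - 1L
    src <- max(1L, 1L + o):min(w, w + o)
    out[, src - o] <- out[, src - o] + g[k] * acc[, src]
  }
  out
}
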