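#' Omni-dimensional dynamic convolution, forward pass
#'
#' Forward-only reference of the attention-modulated dynamic convolution used
#' in the detector backbone. Each kernel in the bank is modulated elementwise
#' by four attentions in the order spatial, input-channel, output-filter,
#' whole-kernel scalar; the modulated kernels are summed and the input is
#' cross-correlated with the summed kernel:
#' \deqn{y = (\alpha_{w1}\odot\alpha_{f1}\odot\alpha_{c1}\odot\alpha_{s1}\odot W_1
#'   + \ldots + \alpha_{wn}\odot\ldots\odot W_n) * x}
#' The attention-generating sub-network is deliberately out of scope: the
#' attentions are inputs, supplied in the bank.
#'
#' @param x input feature map, an `h x w x c_in` array of finite values
#' @param bank a kernel bank from [conv_kernel_bank()]
#' @param stride positive integer stride
#' @param padding nonnegative integer zero-padding in pixels
#' @return The output feature map, `h' x w' x c_out`, with spatial dims given
#'   by standard convolution arithmetic. No bias term is applied.
#' @examples
#' x <- array(rnorm(5 * 5 * 2), c(5, 5, 2))
#' bk <- conv_kernel_bank(list(array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))))
#' dim(odconv_forward(x, bk, padding = 1))  # 5 5 4
#' @export
odconv_forward <- function(x, bank, stride = 1L, padding = 0L) {
  bank <- validate_kernel_bank(bank)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  assert_finite(x, "input feature map")
  dk <- dim(bank$kernels[[1]])
  if (dim(x)[3] != dk[3])
    stop_validation("input channels (", dim(x)[3],
                    ") do not match kernel bank c_in (", dk[3], ")")
  k <- dk[1]; cin <- dk[3]; cout <- dk[4]
  summed <- array(0, dk)
  for (i in seq_along(bank$kernels)) {
    mod <- bank$kernels[[i]] *
      array(bank$alpha_s[[i]], dk) *                        # spatial, k x k
      array(rep(bank$alpha_c[[i]], each = k * k), dk) *     # input channel
      array(rep(bank$alpha_f[[i]], each = k * k * cin), dk) # output filter
    summed <- summed + bank$alpha_w[[i]] * mod
  }
  conv2d(x, summed, stride = stride, padding = padding)
}

#' Construct and validate an attention-modulated kernel bank
#'
#' @param kernels list of `n` arrays, each `k x k x c_in x c_out`
#' @param alpha_s list of `k x k` spatial attention matrices (default all 1)
#' @param alpha_c list of length-`c_in` input-channel attention vectors
#' @param alpha_f list of length-`c_out` filter attention vectors
#' @param alpha_w numeric vector of `n` per-kernel scalars
#' @return A validated list of class `conv_kernel_bank`.
#' @export
conv_kernel_bank <- function(kernels, alpha_s = NULL, alpha_c = NULL,
                             alpha_f = NULL, alpha_w = NULL) {
  n <- length(kernels)
  if (n < 1L) stop_validation("kernel bank needs at least one kernel")
  dk <- dim(kernels[[1]])
  if (length(dk) != 4L) stop_validation("kernels must be k x k x c_in x c_out arrays")
  ones <- function(d) lapply(seq_len(n), function(i) array(1, d))
  b <- structure(list(
    kernels = kernels,
    alpha_s = alpha_s %||% ones(dk[1:2]),
    alpha_c = alpha_c %||% lapply(seq_len(n), function(i) rep(1, dk[3])),
    alpha_f = alpha_f %||% lapply(seq_len(n), function(i) rep(1, dk[4])),
    alpha_w = alpha_w %||% rep(1, n)
  ), class = "conv_kernel_bank")
  validate_kernel_bank(b)
}

validate_kernel_bank <- function(b) {
  n <- length(b$kernels)
  dk <- dim(b$kernels[[1]])
  for (i in seq_len(n)) {
    if (!identical(dim(b$kernels[[i]]), dk))
      stop_validation("kernel ", i, " has inconsistent shape")
    assert_finite(b$kernels[[i]], "kernel")
    a <- list(s = b$alpha_s[[i]], c = b$alpha_c[[i]], f = b$alpha_f[[i]],
              w = b$alpha_w[[i]])
    for (nm in names(a)) {
      if (!all(is.finite(a[[nm]])) || any(a[[nm]] < 0))
        stop_validation("alpha_", nm, "[", i, "] must be finite and nonnegative")
    }
    if (!identical(dim(b$alpha_s[[i]]), dk[1:2]) ||
        length(b$alpha_c[[i]]) != dk[3] || length(b$alpha_f[[i]]) != dk[4])
      stop_validation("attention shapes inconsistent with kernels")
  }
  if (length(b$alpha_w) != n) stop_validation("alpha_w must have one scalar per kernel")
  b
}

#' Global attention gate (channel then spatial), forward pass
#'
#' Reference forward of the global attention mechanism: a channel stage that
#' flattens the map to pixels-by-channels, applies a two-layer perceptron
#' (ReLU in between), reshapes back and gates through a sigmoid
#' (`F2 = Mc (x) F1`); then a spatial stage of two channel-mixing convolutions
#' (ReLU after the first; normalization folded to identity in this
#' inference-level reference) and a second sigmoid gate (`F3 = Ms (x) F2`).
#' Output shape equals input shape and `|output| <= |input|` elementwise since
#' both gates lie in (0, 1).
#'
#' @param f1 input feature map, `h x w x c` array
#' @param params parameter list from [gam_params()]
#' @return The gated feature map, same shape as `f1`.
#' @export
gam_forward <- function(f1, params) {
  if (is.matrix(f1)) f1 <- array(f1, c(dim(f1), 1L))
  assert_finite(f1, "input feature map")
  d <- dim(f1)
  c_in <- d[3]
  if (nrow(params$w1) != c_in)
    stop_validation("params built for ", nrow(params$w1),
                    " channels but input has ", c_in)
  # channel stage: (h*w) x c view, MLP c -> c/r -> c, full-shape sigmoid gate
  X <- matrix(f1, d[1] * d[2], c_in)
  Z <- relu(sweep(X %*% params$w1, 2L, params$b1, "+"))
  Mc <- sigmoid(sweep(Z %*% params$w2, 2L, params$b2, "+"))
  f2 <- f1 * array(Mc, d)
  # spatial stage: two same-padding convolutions, ReLU between, sigmoid gate
  k <- dim(params$conv1)[1]
  pad <- (k - 1L) %/% 2L
  s1 <- relu(conv2d(f2, params$conv1, stride = 1L, padding = pad))
  Ms <- sigmoid(conv2d(s1, params$conv2, stride = 1L, padding = pad))
  f2 * Ms
}

#' Parameters for the global attention gate
#'
#' Builds (by default randomly initialized, seeded) weights for
#' [gam_forward()]: a channel MLP `c -> c/reduction -> c` and two
#' channel-preserving spatial convolutions `c -> c/reduction -> c`.
#'
#' @param channels number of input channels `c`
#' @param reduction channel reduction ratio (default 4); must divide `channels`
#' @param kernel spatial convolution kernel size (odd, default 7)
#' @param seed RNG seed for the random initialization
#' @return A list with elements `w1, b1, w2, b2, conv1, conv2, reduction`.
#' @export
gam_params <- function(channels, reduction = 4L, kernel = 7L, seed = 1L) {
  if (channels %% reduction != 0L)
    stop_validation("reduction must divide the channel count")
  if (kernel %% 2L == 0L) stop_validation("spatial kernel must be odd")
  cr <- channels %/% reduction
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  list(
    w1 = matrix(stats::rnorm(channels * cr, sd = 0.3), channels, cr),
    b1 = stats::rnorm(cr, sd = 0.1),
    w2 = matrix(stats::rnorm(cr * channels, sd = 0.3), cr, channels),
    b2 = stats::rnorm(channels, sd = 0.1),
    conv1 = array(stats::rnorm(kernel^2 * channels * cr, sd = 0.05),
                  c(kernel, kernel, channels, cr)),
    conv2 = array(stats::rnorm(kernel^2 * cr * channels, sd = 0.05),
                  c(kernel, kernel, cr, channels)),
    reduction = reduction
  )
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Soft pooling
#'
#' Exponentially weighted pooling: per window the output is
#' \eqn{\sum_i e^{a_i} a_i / \sum_i e^{a_i}} over the window activations,
#' computed per channel and numerically stabilized by subtracting the window
#' maximum before exponentiation. The result always lies between the window
#' mean-weighted value and its maximum, retaining more signal than max pooling
#' and sharper contrast than average pooling.
#'
#' @param x input feature map, `h x w x c` array or matrix
#' @param kernel square window size, at most the spatial dims
#' @param stride positive integer stride (default `kernel`, non-overlapping)
#' @return Pooled feature map with valid-window output dims.
#' @export
softpool2d <- function(x, kernel, stride = kernel) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  assert_finite(x, "input feature map")
  d <- dim(x)
  if (kernel > d[1] || kernel > d[2])
    stop_validation("pooling kernel larger than input")
  ho <- (d[1] - kernel) %/% stride + 1L
  wo <- (d[2] - kernel) %/% stride + 1L
  out <- array(0, c(ho, wo, d[3]))
  for (ch in seq_len(d[3])) {
    xc <- x[, , ch]
    for (i in seq_len(ho)) for (j in seq_len(wo)) {
      win <- xc[(i - 1L) * stride + seq_len(kernel),
                (j - 1L) * stride + seq_len(kernel)]
      out[i, j, ch] <- softpool_window(win)
    }
  }
  out
}

softpool_window <- function(win) {
  w <- exp(win - max(win))
  sum(w * win) / sum(w)
}

# Stride-1 pooling with 'same' output size; windows are clipped at the
# borders (no padding values enter the pool). pool = "soft" or "max".
pool_same <- function(x, kernel, pool = c("soft", "max")) {
  pool <- match.arg(pool)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  r <- (kernel - 1L) %/% 2L
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    xc <- x[, , ch]
    for (i in seq_len(d[1])) {
      ri <- max(1L, i - r):min(d[1], i + r)
      for (j in seq_len(d[2])) {
        win <- xc[ri, max(1L, j - r):min(d[2], j + r)]
        out[i, j, ch] <- if (pool == "soft") softpool_window(win) else max(win)
      }
    }
  }
  out
}

#' Soft spatial pyramid pooling layer, forward pass
#'
#' Cross-stage-partial style two-branch layer (Fig.-6 style layout): branch A
#' is a 1x1 convolution of the input; branch B is a 1x1 convolution followed
#' by parallel stride-1 same-size soft pools at window sizes {3, 5, 9, 13},
#' concatenated with the un-pooled branch-B tensor and mixed by a 1x1
#' convolution; the two branches are concatenated and mixed by a final 1x1
#' convolution. Spatial dimensions are preserved. The smallest window (3) is
#' the added small-target receptive field relative to the classic {5, 9, 13}
#' pyramid.
#'
#' @param x input feature map, `h x w x c` array with spatial dims >= 13
#' @param weights weight bundle from [ssppl_weights()]
#' @param pool `"soft"` (default) or `"max"` window reduction; `"max"` gives
#'   the classic max-pool pyramid for comparison
#' @return Feature map `h x w x c_out`.
#' @export
ssppl_forward <- function(x, weights, pool = c("soft", "max")) {
  pool <- match.arg(pool)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  assert_finite(x, "input feature map")
  d <- dim(x)
  ks <- weights$kernels
  if (d[1] < max(ks) || d[2] < max(ks))
    stop_validation("input spatial dims must be at least the largest pooling kernel (",
                    max(ks), ")")
  a <- conv1x1(x, weights$cv_a)
  b <- conv1x1(x, weights$cv_b)
  pooled <- lapply(ks, function(k) pool_same(b, k, pool = pool))
  cat_b <- array(c(b, do.call(c, pooled)),
                 c(d[1], d[2], dim(b)[3] * (1L + length(ks))))
  b_mix <- conv1x1(cat_b, weights$cv_mix)
  cat_ab <- array(c(a, b_mix), c(d[1], d[2], dim(a)[3] + dim(b_mix)[3]))
  conv1x1(cat_ab, weights$cv_out)
}

#' Weight bundle for the soft spatial pyramid pooling layer
#'
#' @param c_in input channels
#' @param c_mid branch width (default `c_in`)
#' @param c_out output channels (default `c_in`)
#' @param init `"random"` (seeded Gaussian) or `"identity"`: averaging mixes
#'   that propagate a constant input unchanged (requires
#'   `c_in == c_mid == c_out`)
#' @param seed RNG seed for random init
#' @return A list with 1x1 convolution matrices `cv_a, cv_b, cv_mix, cv_out`
#'   and the pooling `kernels` vector `c(3, 5, 9, 13)`.
#' @export
ssppl_weights <- function(c_in, c_mid = c_in, c_out = c_in,
                          init = c("random", "identity"), seed = 1L) {
  init <- match.arg(init)
  ks <- c(3L, 5L, 9L, 13L)
  if (init == "identity") {
    if (c_in != c_mid || c_in != c_out)
      stop_config("identity init requires equal channel counts")
    I <- diag(c_in)
    list(cv_a = I, cv_b = I,
         cv_mix = do.call(rbind, rep(list(I / (1L + length(ks))), 1L + length(ks))),
         cv_out = rbind(I / 2, I / 2), kernels = ks)
  } else {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
    set.seed(seed)
    rnd <- function(a, b) matrix(stats::rnorm(a * b, sd = 1 / sqrt(a)), a, b)
    list(cv_a = rnd(c_in, c_mid), cv_b = rnd(c_in, c_mid),
         cv_mix = rnd(c_mid * (1L + length(ks)), c_mid),
         cv_out = rnd(2L * c_mid, c_out), kernels = ks)
  }
}
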