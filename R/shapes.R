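#' Per-level shape contract of the dense encoder
#'
#' Computes, without building the network, the (spatial side, channel count)
#' pair at every encoder level. Level 1 is the stem output (input side halved
#' by the stride-2 stem); level 2 is reached by the 3x3 stride-2 max pool;
#' levels 2..s hold the dense-block outputs, with a compressing transition
#' (1x1 conv + 2x2 average pool) between consecutive blocks. Channel counts
#' are the pre-transition widths: `in + n_layers * k` after each block,
#' `floor(theta * c)` across each transition.
#'
#' For the default configuration the sides are [112, 56, 28, 14, 7] and the
#' channels [96, 384, 768, 2112, 2208].
#'
#' @param config An [model_config()] object.
#' @return A data frame with columns `level`, `spatial_side`, `channels`.
#' @export
infer_encoder_shapes <- function(config) {
  validate_model_config(config)
  s <- config$depth_s
  sides <- config$input_side / 2^(seq_len(s))
  channels <- integer(s)
  channels[1] <- config$stem_filters
  c_in <- config$stem_filters  # max pool preserves channels
  for (b in seq_along(config$block_layers)) {
    c_out <- c_in + config$block_layers[b] * config$growth_rate_k
    channels[b + 1L] <- c_out
    c_in <- as.integer(floor(config$compression_theta * c_out))
  }
  data.frame(level = seq_len(s), spatial_side = as.integer(sides),
             channels = channels)
}

#' Atrous (dilated) discrete convolution, reference implementation
#'
#' Direct evaluation of the dilated convolution sum
#' `(F *_l k)(p) = sum_{s + l t = p} F(s) k(t)`: the kernel taps are spaced
#' `rate` positions apart, so positions are skipped relative to the standard
#' discrete convolution, which is recovered exactly at `rate = 1`. Works on
#' 1-D vectors and 2-D matrices with "same" zero padding (output extent equals
#' the signal extent, kernel centred on the dilated footprint).
#'
#' Equivalently, dilation by rate r inflates the kernel by inserting r-1 zeros
#' between consecutive taps; this identity is the basis of the package's
#' verification suite.
#'
#' @param signal Numeric vector or matrix.
#' @param kernel Numeric vector or matrix (same rank as `signal`).
#' @param rate Dilation rate (integer >= 1).
#' @return Array of the same shape as `signal`.
#' @examples
#' atrous_convolve(c(0, 0, 1, 0, 0), c(1, 2, 3), rate = 2)
#' @export
atrous_convolve <- function(signal, kernel, rate = 1L) {
  rate <- as.integer(rate)
  if (length(rate) != 1L || is.na(rate) || rate < 1L)
    stop("invalid argument: rate must be an integer >= 1")
  one_d <- is.null(dim(signal))
  if (one_d) {
    signal <- matrix(signal, nrow = 1L)
    if (!is.null(dim(kernel))) stop("kernel rank must match signal rank")
    kernel <- matrix(kernel, nrow = 1L)
  }
  if (is.null(dim(kernel))) stop("kernel rank must match signal rank")
  H <- nrow(signal); W <- ncol(signal)
  kh <- nrow(kernel); kw <- ncol(kernel)
  eff_h <- rate * (kh - 1L) + 1L
  eff_w <- rate * (kw - 1L) + 1L
  if ((kh > 1L && eff_h > H) || (kw > 1L && eff_w > W))
    stop("invalid argument: dilated kernel (", eff_h, "x", eff_w,
         ") larger than signal (", H, "x", W, ")")
  off_h <- (eff_h - 1L) %/% 2L
  off_w <- (eff_w - 1L) %/% 2L
  pad_h <- eff_h; pad_w <- eff_w
  P <- matrix(0, H + 2L * pad_h, W + 2L * pad_w)
  P[pad_h + seq_len(H), pad_w + seq_len(W)] <- signal
  out <- matrix(0, H, W)
  # y[p] = sum_t k[t] * F[p + off - rate*(t-1)]  (true convolution: the
  # kernel is reflected relative to cross-correlation)
  for (ti in seq_len(kh)) {
    for (tj in seq_len(kw)) {
      kv <- kernel[ti, tj]
      if (kv == 0) next
      rows <- pad_h + seq_len(H) + off_h - rate * (ti - 1L)
      cols <- pad_w + seq_len(W) + off_w - rate * (tj - 1L)
      out <- out + kv * P[rows, cols, drop = FALSE]
    }
  }
  if (one_d) as.vector(out) else out
}

#' Inflate a kernel with zeros between taps
#'
#' Helper for reasoning about dilation: a rate-r atrous convolution equals a
#' standard convolution with the kernel inflated by r-1 zeros between
#' consecutive values.
#'
#' @inheritParams atrous_convolve
#' @return The zero-inflated kernel (same rank as the input).
#' @export
inflate_kernel <- function(kernel, rate) {
  rate <- as.integer(rate)
  stopifnot(rate >= 1L)
  one_d <- is.null(dim(kernel))
  if (one_d) kernel <- matrix(kernel, nrow = 1L)
  kh <- nrow(kernel); kw <- ncol(kernel)
  out <- matrix(0, rate * (kh - 1L) + 1L, rate * (kw - 1L) + 1L)
  out[seq(1L, by = rate, length.out = kh), seq(1L, by = rate, length.out = kw)] <- kernel
  if (one_d) as.vector(out) else out
}
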