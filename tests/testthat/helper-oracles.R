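# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals they check.

# Dilated true convolution by direct summation over s + l*t = p, "same"
# zero padding with the kernel centred on its dilated footprint.
oracle_atrous_1d <- function(f, k, rate) {
  n <- length(f); m <- length(k)
  eff <- rate * (m - 1) + 1
  off <- (eff - 1) %/% 2
  out <- numeric(n)
  for (p in seq_len(n)) {
    acc <- 0
    for (t in seq_len(m)) {
      s <- p + off - rate * (t - 1)
      if (s >= 1 && s <= n) acc <- acc + f[s] * k[t]
    }
    out[p] <- acc
  }
  out
}

oracle_atrous_2d <- function(f, k, rate) {
  H <- nrow(f); W <- ncol(f)
  kh <- nrow(k); kw <- ncol(k)
  offh <- (rate * (kh - 1)) %/% 2
  offw <- (rate * (kw - 1)) %/% 2
  out <- matrix(0, H, W)
  for (p in seq_len(H)) for (q in seq_len(W)) {
    acc <- 0
    for (ti in seq_len(kh)) for (tj in seq_len(kw)) {
      si <- p + offh - rate * (ti - 1)
      sj <- q + offw - rate * (tj - 1)
      if (si >= 1 && si <= H && sj >= 1 && sj <= W)
        acc <- acc + f[si, sj] * k[ti, tj]
    }
    out[p, q] <- acc
  }
  out
}

# Exhaustive double-loop pixel tally of segmentation metrics.
oracle_metrics <- function(pred, truth) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1
    else if (pred[i, j] == 1 && truth[i, j] == 0) fp <- fp + 1
    else if (pred[i, j] == 0 && truth[i, j] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA,
       iou = if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA,
       dice = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA)
}

# Tiny architecture for gradient checks and structural tests: 32px input,
# one layer per dense block, narrow everything.
micro_config <- function(...) {
  args <- utils::modifyList(
    list(input_side = 32L, stem_filters = 4L, growth_rate_k = 2L,
         block_layers = c(1L, 1L, 1L, 1L), bottleneck_factor = 2L,
         decoder_base_filters = 2L, decoder_max_filters = 16L,
         deep_supervision_filters = 2L),
    list(...))
  do.call(reduced_model_config, args)
}

# Access to package internals for white-box tests.
adu_ns <- asNamespace("adenseunet")

random_mask <- function(side, p = 0.4) {
  matrix(as.integer(stats::runif(side * side) < p), side, side)
}
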