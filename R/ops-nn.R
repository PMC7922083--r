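# Differentiable network operations on tape nodes.
# Array convention: activations are (H, W, C) arrays; conv weights are
# (kh, kw, Cin, Cout); biases length Cout.

op_conv2d <- function(x, w, b, stride = 1L, pad = 0L, dil = 1L) {
  xd <- dim(x$val); wd <- dim(w$val)
  stopifnot(length(xd) == 3L, length(wd) == 4L, xd[3] == wd[3])
  y <- nn_conv2d_fwd(x$val, as.integer(xd), w$val, as.integer(wd), b$val,
                     as.integer(stride), as.integer(pad), as.integer(dil))
  xv <- x$val; wv <- w$val
  nd(y, parents = list(x, w, b), backfn = function(g) {
    r <- nn_conv2d_bwd(xv, as.integer(xd), wv, as.integer(wd), g,
                       as.integer(stride), as.integer(pad), as.integer(dil),
                       TRUE)
    list(r$gx, r$gw, r$gb)
  })
}

op_convt2 <- function(x, w, b) {
  xd <- dim(x$val); wd <- dim(w$val)
  stopifnot(wd[1] == 2L, wd[2] == 2L, xd[3] == wd[3])
  y <- nn_convt2_fwd(x$val, as.integer(xd), w$val, as.integer(wd), b$val)
  xv <- x$val; wv <- w$val
  nd(y, parents = list(x, w, b), backfn = function(g) {
    r <- nn_convt2_bwd(xv, as.integer(xd), wv, as.integer(wd), g, TRUE)
    list(r$gx, r$gw, r$gb)
  })
}

op_maxpool3 <- function(x) {
  xd <- dim(x$val)
  r <- nn_maxpool3_fwd(x$val, as.integer(xd))
  arg <- r$arg
  nd(r$y, parents = list(x), backfn = function(g) {
    list(nn_maxpool3_bwd(arg, g, as.integer(xd)))
  })
}

op_avgpool2 <- function(x) {
  xd <- dim(x$val)
  y <- nn_avgpool2_fwd(x$val, as.integer(xd))
  nd(y, parents = list(x), backfn = function(g) {
    list(nn_avgpool2_bwd(g, as.integer(xd)))
  })
}

op_up2_bilinear <- function(x) {
  xd <- dim(x$val)
  y <- nn_up2_bilinear_fwd(x$val, as.integer(xd))
  nd(y, parents = list(x), backfn = function(g) {
    list(nn_up2_bilinear_bwd(g, as.integer(xd)))
  })
}

op_relu <- function(x) {
  mask <- x$val > 0
  nd(x$val * mask, parents = list(x), backfn = function(g) list(g * mask))
}

op_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$val))
  nd(y, parents = list(x), backfn = function(g) list(g * y * (1 - y)))
}

op_add <- function(a, b) {
  nd(a$val + b$val, parents = list(a, b), backfn = function(g) list(g, g))
}

# Channel-wise concatenation of (H, W, C_i) arrays.
op_concat <- function(xs) {
  if (length(xs) == 1L) return(xs[[1]])
  dims <- lapply(xs, function(x) dim(x$val))
  H <- dims[[1]][1]; W <- dims[[1]][2]
  for (d in dims) {
    if (d[1] != H || d[2] != W)
      stop("concat: spatial dimensions differ (", d[1], "x", d[2], " vs ", H, "x", W, ")")
  }
  chans <- vapply(dims, function(d) d[3], numeric(1))
  val <- array(unlist(lapply(xs, function(x) x$val), use.names = FALSE),
               dim = c(H, W, sum(chans)))
  ends <- cumsum(chans); starts <- c(1, head(ends, -1) + 1)
  nd(val, parents = xs, backfn = function(g) {
    lapply(seq_along(xs), function(i) {
      gi <- g[, , starts[i]:ends[i], drop = FALSE]
      dim(gi) <- c(H, W, chans[i])
      gi
    })
  })
}

# Multiply a (H, W, 1) coefficient map into every channel of x.
op_gate_mul <- function(coef, x) {
  xd <- dim(x$val)
  npix <- xd[1] * xd[2]
  cv <- as.vector(coef$val)
  stopifnot(length(cv) == npix)
  crep <- rep(cv, xd[3])
  xv <- x$val
  nd(x$val * crep, parents = list(coef, x), backfn = function(g) {
    m <- matrix(g * xv, npix, xd[3])
    gc <- array(rowSums(m), dim = c(xd[1], xd[2], 1L))
    list(gc, g * crep)
  })
}

# Mean of a list of same-shaped nodes (deep-supervision averaging).
op_mean_of <- function(xs) {
  n <- length(xs)
  if (n == 1L) return(xs[[1]])
  val <- xs[[1]]$val
  for (i in 2:n) val <- val + xs[[i]]$val
  val <- val / n
  nd(val, parents = xs, backfn = function(g) {
    gi <- g / n
    rep(list(gi), n)
  })
}

# Batch normalisation over the spatial positions of one activation map.
# In training mode batch statistics are used and running estimates updated
# in-place in `state` (an environment with running_mean / running_var).
op_batchnorm <- function(x, gamma, beta, state, training, eps = 1e-5,
                        momentum = 0.1) {
  xd <- dim(x$val)
  npix <- xd[1] * xd[2]; C <- xd[3]
  M <- x$val; dim(M) <- c(npix, C)
  bycol <- function(v) rep(v, each = npix)  # per-channel broadcast
  if (training) {
    mu <- colMeans(M)
    xc <- M - bycol(mu)
    v <- colMeans(xc * xc)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * v
  } else {
    mu <- state$running_mean
    v <- state$running_var
    xc <- M - bycol(mu)
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * bycol(istd)
  Y <- xhat * bycol(gamma$val) + bycol(beta$val)
  dim(Y) <- xd
  nd(Y, parents = list(x, gamma, beta), backfn = function(g) {
    G <- g; dim(G) <- c(npix, C)
    gbeta <- colSums(G)
    ggamma <- colSums(G * xhat)
    dxhat <- G * bycol(gamma$val)
    if (training) {
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      GX <- (dxhat - bycol(s1 / npix) - xhat * bycol(s2 / npix)) * bycol(istd)
    } else {
      GX <- dxhat * bycol(istd)
    }
    dim(GX) <- xd
    list(GX, ggamma, gbeta)
  })
}

# ---- losses -----------------------------------------------------------------
# Each returns a scalar node whose parents include the prediction node.

# Numerically stable BCE on pre-sigmoid logits; `truth` is a {0,1} array.
loss_bce_logits <- function(logits, truth, reduction = "mean") {
  z <- logits$val
  t <- as.numeric(truth)
  # log(1 + exp(-|z|)) + max(z, 0) - z*y  (stable softplus form)
  ell <- pmax(z, 0) - z * t + log1p(exp(-abs(z)))
  n <- length(z)
  total <- sum(ell)
  scale <- if (reduction == "mean") 1 / n else 1
  p <- 1 / (1 + exp(-z))
  nd(total * scale, parents = list(logits),
     backfn = function(g) list(array(g * scale * (p - t), dim = dim(z))))
}

# Soft Dice loss on probabilities: 1 - (2*sum(p*y)+s)/(sum(p)+sum(y)+s).
loss_soft_dice <- function(prob, truth, smooth = 1) {
  p <- prob$val; t <- as.numeric(truth)
  inter <- sum(p * t); ps <- sum(p); ts <- sum(t)
  num <- 2 * inter + smooth; den <- ps + ts + smooth
  nd(1 - num / den, parents = list(prob), backfn = function(g) {
    list(array(g * (num / den^2 - 2 * t / den), dim = dim(p)))
  })
}

# Soft Jaccard (IoU) loss on probabilities.
loss_soft_jaccard <- function(prob, truth, smooth = 1) {
  p <- prob$val; t <- as.numeric(truth)
  inter <- sum(p * t); uni <- sum(p) + sum(t) - inter
  num <- inter + smooth; den <- uni + smooth
  nd(1 - num / den, parents = list(prob), backfn = function(g) {
    # d/dp_i of num/den with inter' = t_i, uni' = 1 - t_i
    list(array(g * ((num * (1 - t) - den * t) / den^2), dim = dim(p)))
  })
}

loss_mse <- function(prob, truth) {
  p <- prob$val; t <- as.numeric(truth)
  n <- length(p)
  nd(mean((p - t)^2), parents = list(prob), backfn = function(g) {
    list(array(g * 2 * (p - t) / n, dim = dim(p)))
  })
}
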