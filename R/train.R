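#' Training protocol configuration
#'
#' The published protocol: Adam, batch size 10, up to 100 epochs, initial
#' learning rate 0.01 divided by 10 whenever the validation loss fails to
#' improve for more than `plateau_patience` epochs, early stopping on the
#' validation set, binary cross-entropy as the default loss (Dice, Jaccard
#' and mean-square losses selectable).
#'
#' @param batch_size Images per optimizer step.
#' @param epochs Maximum number of epochs.
#' @param initial_lr Starting learning rate.
#' @param plateau_factor Multiplier applied to the learning rate on plateau.
#' @param plateau_patience Epochs without validation improvement before the
#'   learning rate drops (min-delta 1e-4).
#' @param early_stop_patience Epochs without validation improvement before
#'   training halts.
#' @param optimizer Only `"adam"` is implemented.
#' @param loss One of `"bce"`, `"dice"`, `"jaccard"`, `"mse"`.
#' @param max_steps Optional cap on total optimizer steps (useful for smoke
#'   tests; `Inf` to disable).
#' @param val_every Run validation every `val_every` epochs (plateau/early
#'   stop bookkeeping advances only on validation epochs).
#' @param target_val_dice Optional Dice level on the validation set at which
#'   training stops early (`NA` to disable); used by overfitting smoke runs.
#' @param seed Integer seed for shuffling and any stochastic layers.
#' @param checkpoint_dir Optional directory for the best-validation
#'   checkpoint.
#' @return An object of class `adu_train_config`.
#' @export
train_config <- function(batch_size = 10L,
                         epochs = 100L,
                         initial_lr = 0.01,
                         plateau_factor = 0.1,
                         plateau_patience = 5L,
                         early_stop_patience = 15L,
                         optimizer = c("adam"),
                         loss = c("bce", "dice", "jaccard", "mse"),
                         max_steps = Inf,
                         val_every = 1L,
                         target_val_dice = NA_real_,
                         seed = 1L,
                         checkpoint_dir = NULL) {
  stopifnot(batch_size >= 1L, epochs >= 1L, initial_lr > 0,
            plateau_factor > 0, plateau_factor < 1,
            plateau_patience >= 1L, early_stop_patience >= 1L)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 initial_lr = as.numeric(initial_lr),
                 plateau_factor = as.numeric(plateau_factor),
                 plateau_patience = as.integer(plateau_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 optimizer = match.arg(optimizer),
                 loss = match.arg(loss),
                 max_steps = max_steps,
                 val_every = as.integer(val_every),
                 target_val_dice = as.numeric(target_val_dice),
                 seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir),
            class = "adu_train_config")
}

adam_make <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(params, function(p) 0)
  st$v <- lapply(params, function(p) 0)
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

adam_step <- function(st, params, lr, grad_scale = 1) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  bc1 <- 1 - b1^st$t; bc2 <- 1 - b2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    g <- g * grad_scale
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
    st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g * g
    p$val <- p$val - lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + st$eps)
  }
  invisible(NULL)
}

training_loss_node <- function(out, mask, loss) {
  switch(loss,
         bce = loss_bce_logits(out$logits, mask, reduction = "mean"),
         dice = loss_soft_dice(out$prob, mask),
         jaccard = loss_soft_jaccard(out$prob, mask),
         mse = loss_mse(out$prob, mask))
}

#' Train an A-DenseUNet
#'
#' Full training loop: mini-batch Adam on the selected loss, per-epoch
#' validation, reduce-on-plateau learning-rate schedule, early stopping, and
#' retention of the best-validation parameters. Gradients are averaged over
#' each mini-batch; batch normalisation uses per-image batch statistics
#' during training and running estimates at validation time.
#'
#' @param model An [a_denseunet()] network (modified in place and returned
#'   inside the fit object).
#' @param train_samples,val_samples Lists of `segmentation_sample`s whose
#'   images match the model's input side.
#' @param config An [train_config()].
#' @param verbose Print one line per epoch.
#' @return An object of class `adenseunet_fit` with elements `model`,
#'   `history` (data frame: epoch, loss, lr, val_loss, val_dice, val_iou),
#'   `best_epoch`, `config`.
#' @export
fit_adenseunet <- function(model, train_samples, val_samples = NULL,
                           config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "adenseunet"), inherits(config, "adu_train_config"))
  if (length(train_samples) == 0) stop("invalid argument: empty training set")
  has_val <- length(val_samples) > 0
  params <- model$params
  opt <- adam_make(params)
  lr <- config$initial_lr
  best_val <- Inf; best_epoch <- 0L; since_best <- 0L
  best_params <- NULL
  hist <- list()
  steps <- 0L
  min_delta <- 1e-4

  run_seeded(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(train_samples))
      epoch_losses <- c()
      i <- 1L
      while (i <= length(ord) && steps < config$max_steps) {
        batch <- ord[i:min(i + config$batch_size - 1L, length(ord))]
        i <- i + config$batch_size
        zero_grads(params)
        batch_loss <- 0
        for (b in batch) {
          s <- train_samples[[b]]
          tape_start()
          out <- forward_adenseunet(model, s$image, training = TRUE)
          ln <- training_loss_node(out, s$mask, config$loss)
          if (!is.finite(ln$val))
            stop("training aborted: non-finite loss at epoch ", epoch,
                 " (lr ", lr, ")")
          batch_loss <- batch_loss + ln$val
          backward(ln)
          tape_stop()
        }
        adam_step(opt, params, lr, grad_scale = 1 / length(batch))
        steps <- steps + 1L
        epoch_losses <- c(epoch_losses, batch_loss / length(batch))
      }

      last_epoch <- epoch == config$epochs || steps >= config$max_steps
      do_val <- has_val && (epoch %% config$val_every == 0L || last_epoch)
      val <- if (do_val) {
        evaluate_model(model, val_samples, loss = config$loss)
      } else {
        list(loss = if (has_val) NA_real_ else mean(epoch_losses),
             dice = NA_real_, iou = NA_real_)
      }
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  loss = mean(epoch_losses), lr = lr,
                                  val_loss = val$loss, val_dice = val$dice,
                                  val_iou = val$iou)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  lr %.2e  val_loss %.4f  val_dice %.4f",
                        epoch, mean(epoch_losses), lr, val$loss, val$dice))

      if (do_val || !has_val) {
        monitored <- if (has_val) val$loss else mean(epoch_losses)
        if (monitored < best_val - min_delta) {
          best_val <- monitored; best_epoch <- epoch; since_best <- 0L
          best_params <- lapply(params, function(p) p$val)
        } else {
          since_best <- since_best + 1L
          if (since_best %% (config$plateau_patience + 1L) == 0L)
            lr <- lr * config$plateau_factor
        }
        if (is.finite(config$target_val_dice) && isTRUE(val$dice >= config$target_val_dice)) {
          # target reached: keep the current weights, not an earlier checkpoint
          best_params <- lapply(params, function(p) p$val)
          best_epoch <- epoch
          break
        }
        if (since_best >= config$early_stop_patience) break
      }
      if (steps >= config$max_steps) break
    }
  })

  if (!is.null(best_params)) {
    for (i in seq_along(params)) params[[i]]$val <- best_params[[i]]
  }
  history <- do.call(rbind, hist)
  if (!is.null(config$checkpoint_dir)) {
    dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(model, file.path(config$checkpoint_dir, "best.rds"))
  }
  structure(list(model = model, history = history, best_epoch = best_epoch,
                 config = config),
            class = "adenseunet_fit")
}

#' Desk-scale overfitting smoke run
#'
#' Trains the reduced network on a handful of synthetic phantoms until it
#' memorises them: 8 phantom samples at 96x96, the [reduced_model_config()]
#' architecture, Adam at 1e-3 with mini-batches of 4, and at most `max_steps`
#' optimizer steps (training stops as soon as the training-set Dice reaches
#' `target_dice`). A healthy implementation overfits this task quickly, so
#' the run is a fast end-to-end check that forward pass, gradients and the
#' optimizer cooperate.
#'
#' @param seed Integer seed controlling phantoms, weights and shuffling.
#' @param max_steps Optimizer-step budget.
#' @param target_dice Training-set Dice at which the run stops early.
#' @param n_samples Number of phantom samples to memorise.
#' @return List with `dice` (final training-set Dice), `initial_loss`,
#'   `final_loss`, `steps` (epochs run times steps per epoch, capped), and
#'   the `fit` object.
#' @export
overfit_smoke <- function(seed = 0L, max_steps = 300L, target_dice = 0.93,
                          n_samples = 8L) {
  pc <- phantom_config(side = 96L, seed = as.integer(seed))
  samples <- lapply(seq_len(n_samples) - 1L, function(i) phantom_sample(pc, i))
  net <- a_denseunet(reduced_model_config(seed = as.integer(seed) + 1000L))
  initial <- evaluate_model(net, samples)
  tc <- train_config(batch_size = 4L, epochs = as.integer(ceiling(max_steps / 2)),
                     initial_lr = 1e-3, max_steps = max_steps,
                     val_every = 5L, target_val_dice = target_dice,
                     plateau_patience = 20L, early_stop_patience = 1000L,
                     seed = as.integer(seed) + 1L)
  fit <- fit_adenseunet(net, samples, samples, tc)
  final <- evaluate_model(fit$model, samples)
  list(dice = final$dice, initial_loss = initial$loss, final_loss = final$loss,
       epochs = nrow(fit$history), fit = fit)
}

#' Evaluate a model on a sample set
#'
#' Deterministic inference (running batch-norm statistics), 0.5 thresholding,
#' confusion-count metrics, plus the mean of the configured loss.
#'
#' @param model An `adenseunet` or `adenseunet_fit`.
#' @param samples List of `segmentation_sample`s.
#' @param threshold Binarisation threshold.
#' @param aggregation Metric aggregation mode, see [evaluate_dataset()].
#' @param loss Loss reported alongside the metrics.
#' @return A `metrics_report` with an additional `loss` element.
#' @export
evaluate_model <- function(model, samples, threshold = 0.5,
                           aggregation = "per-image-mean", loss = "bce") {
  if (inherits(model, "adenseunet_fit")) model <- model$model
  if (length(samples) == 0) stop("invalid argument: empty evaluation set")
  preds <- vector("list", length(samples))
  losses <- numeric(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    out <- forward_adenseunet(model, s$image, training = FALSE)
    p <- out$prob$val; dim(p) <- dim(p)[1:2]
    preds[[i]] <- p
    losses[i] <- switch(loss,
                        bce = bce_loss(p, s$mask, "mean"),
                        dice = 1 - dice(confusion_soft(p, s$mask)),
                        jaccard = 1 - iou(confusion_soft(p, s$mask)),
                        mse = mean((p - s$mask)^2))
  }
  rep <- evaluate_dataset(preds, lapply(samples, `[[`, "mask"),
                          threshold = threshold, aggregation = aggregation)
  rep$loss <- mean(losses)
  rep
}

# Soft counts for reporting dice/jaccard losses on probabilities.
confusion_soft <- function(p, y) {
  tp <- sum(p * y)
  list(tp = tp, fp = sum(p) - tp, fn = sum(y) - tp, tn = 0)
}

#' @export
print.adenseunet_fit <- function(x, ...) {
  h <- x$history
  cat("fitted A-DenseUNet\n")
  cat(sprintf("  epochs run: %d (best validation at epoch %d)\n",
              nrow(h), x$best_epoch))
  cat(sprintf("  final: loss %.4f, lr %.2e", h$loss[nrow(h)], h$lr[nrow(h)]))
  if (is.finite(h$val_dice[nrow(h)]))
    cat(sprintf(", val Dice %.4f, val IoU %.4f",
                h$val_dice[nrow(h)], h$val_iou[nrow(h)]))
  cat("\n")
  invisible(x)
}

#' @export
summary.adenseunet_fit <- function(object, ...) {
  print(object)
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object$history)
}

#' @export
predict.adenseunet_fit <- function(object, image, ...) {
  predict(object$model, image, ...)
}

#' Plot training history
#'
#' Loss and validation Dice per epoch, with learning-rate drops marked.
#'
#' @param x An `adenseunet_fit`.
#' @param ... Passed to `matplot`.
#' @export
plot.adenseunet_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$loss, h$val_loss), type = "l", lty = 1,
                    col = c("steelblue", "firebrick"), xlab = "epoch",
                    ylab = "loss", ...)
  drops <- which(diff(h$lr) < 0) + 1L
  if (length(drops)) graphics::abline(v = h$epoch[drops], lty = 3, col = "grey50")
  graphics::legend("topright", c("train loss", "validation loss"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(h)
}

#' Save / load model parameters
#'
#' Checkpoints hold the configuration, every parameter array and the batch
#' normalisation running statistics; reloading reproduces inference
#' bit-for-bit.
#'
#' @param model An `adenseunet` (or fit object).
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "adenseunet_fit")) model <- model$model
  vals <- lapply(model$params, function(p) p$val)
  bns <- collect_bn_states(model)
  saveRDS(list(config = unclass(model$config), params = vals,
               bn = lapply(bns, function(st) list(m = st$running_mean,
                                                  v = st$running_var))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns a rebuilt `adenseunet`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- ck$config; class(cfg) <- "adu_model_config"
  model <- a_denseunet(cfg)
  stopifnot(length(model$params) == length(ck$params))
  for (i in seq_along(model$params)) model$params[[i]]$val <- ck$params[[i]]
  bns <- collect_bn_states(model)
  stopifnot(length(bns) == length(ck$bn))
  for (i in seq_along(bns)) {
    bns[[i]]$running_mean <- ck$bn[[i]]$m
    bns[[i]]$running_var <- ck$bn[[i]]$v
  }
  model
}

# All batch-norm state environments of a model, in deterministic order.
collect_bn_states <- function(model) {
  found <- list()
  walk <- function(x) {
    if (is.environment(x) && !is.null(x$running_mean) && is.null(x$val)) {
      found[[length(found) + 1L]] <<- x
    } else if (is.list(x) && !is.environment(x)) {
      for (el in x) walk(el)
    }
  }
  walk(list(model$stem, model$blocks, model$trans, model$dec, model$ds,
            model$head_conv))
  found
}
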