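# Minimal reverse-mode differentiation tape.
#
# A "node" is an environment with fields:
#   val     - numeric array (H x W x C) or scalar
#   grad    - accumulated gradient (NULL until backward reaches it)
#   parents - list of parent nodes (only in grad mode)
#   backfn  - function(grad) -> list of parent gradients (NULL entries allowed)
# Trainable parameters are plain environments with the same val/grad fields,
# so they participate in backward() like any other leaf.

.adu <- new.env(parent = emptyenv())
.adu$grad_enabled <- FALSE
.adu$tape <- NULL
.adu$tape_len <- 0L

grad_enabled <- function() .adu$grad_enabled

#' @keywords internal
tape_start <- function() {
  .adu$grad_enabled <- TRUE
  .adu$tape <- vector("list", 4096L)
  .adu$tape_len <- 0L
  invisible(NULL)
}

#' @keywords internal
tape_stop <- function() {
  .adu$grad_enabled <- FALSE
  .adu$tape <- NULL
  .adu$tape_len <- 0L
  invisible(NULL)
}

tape_push <- function(node) {
  n <- .adu$tape_len + 1L
  if (n > length(.adu$tape)) .adu$tape <- c(.adu$tape, vector("list", length(.adu$tape)))
  .adu$tape[[n]] <- node
  .adu$tape_len <- n
  invisible(NULL)
}

# Create a node. In eval mode parents/backfn are dropped and nothing is taped,
# so intermediates are garbage-collected as soon as the forward pass moves on.
nd <- function(val, parents = NULL, backfn = NULL) {
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  if (.adu$grad_enabled && !is.null(backfn)) {
    node$parents <- parents
    node$backfn <- backfn
    tape_push(node)
  }
  node
}

# Leaf with a constant value (no gradient tracked).
nd_const <- function(val) nd(val)

new_param <- function(val) {
  p <- new.env(parent = emptyenv())
  p$val <- val
  p$grad <- NULL
  p$trainable <- TRUE
  class(p) <- "adu_param"
  p
}

accumulate_grad <- function(node, g) {
  if (is.null(g)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Run reverse-mode accumulation from `root` (a scalar node) through the tape.
# Parameter gradients end up in each param's $grad; they are NOT zeroed here,
# so successive backward() calls accumulate (used for mini-batch sums).
backward <- function(root) {
  if (!.adu$grad_enabled) stop("backward() requires an active tape")
  root$grad <- 1
  tape <- .adu$tape
  for (i in seq(.adu$tape_len, 1L)) {
    node <- tape[[i]]
    if (is.null(node$grad) || is.null(node$backfn)) next
    gs <- node$backfn(node$grad)
    for (j in seq_along(gs)) accumulate_grad(node$parents[[j]], gs[[j]])
    # free intermediate gradients/values early
    if (is.null(attr(node, "keep_grad"))) node$grad <- NULL
  }
  # reset tape for the next forward pass within the same grad section
  .adu$tape <- vector("list", 4096L)
  .adu$tape_len <- 0L
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Flatten a nested list-of-(lists|params) into a flat named list of params.
flatten_params <- function(x, prefix = "") {
  if (inherits(x, "adu_param")) {
    out <- list(x)
    names(out) <- prefix
    return(out)
  }
  if (!is.list(x)) return(list())
  out <- list()
  nms <- names(x)
  for (i in seq_along(x)) {
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
    out <- c(out, flatten_params(x[[i]], paste0(prefix, if (nzchar(prefix)) "." else "", nm)))
  }
  out
}
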