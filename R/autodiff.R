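# Lightweight reverse-mode automatic differentiation over dense arrays.
#
# Feature maps are plain R arrays with dim [H, W, C, N]. A tensor is an
# environment carrying the value (`v`), an accumulated gradient (`g`), and a
# requires-grad flag (`rg`). Operations that touch at least one grad-requiring
# tensor push a node (the output tensor itself, holding its parents and a
# backward closure) onto a global tape; nn_backward() walks the tape in
# reverse creation order. Parameters are off-tape leaves whose gradients
# persist until zeroed by the optimizer.

.tape <- new.env(parent = emptyenv())
.tape$nodes <- vector("list", 512L)
.tape$n <- 0L
.tape$active <- TRUE

#' @noRd
nn_tensor <- function(value, requires_grad = FALSE) {
  t <- new.env(parent = emptyenv())
  t$v <- value
  t$g <- NULL
  t$rg <- requires_grad
  class(t) <- "nn_tensor"
  t
}

is_tensor <- function(x) inherits(x, "nn_tensor")

#' @noRd
tape_reset <- function() {
  if (.tape$n > 0L) {
    # drop references so closures/values can be collected
    .tape$nodes[seq_len(.tape$n)] <- list(NULL)
  }
  .tape$n <- 0L
  invisible()
}

# Run expr without recording (inference / plain numeric evaluation).
no_grad <- function(expr) {
  old <- .tape$active
  .tape$active <- FALSE
  on.exit(.tape$active <- old)
  expr
}

# Create the output tensor of an op. `bw` maps the output gradient to a list
# of parent gradients (NULL entries for parents that need none).
record <- function(value, parents, bw) {
  rg <- FALSE
  for (p in parents) if (isTRUE(p$rg)) { rg <- TRUE; break }
  out <- nn_tensor(value, rg)
  if (.tape$active && rg) {
    out$parents <- parents
    out$bw <- bw
    n <- .tape$n + 1L
    if (n > length(.tape$nodes))
      .tape$nodes <- c(.tape$nodes, vector("list", length(.tape$nodes)))
    .tape$nodes[[n]] <- out
    .tape$n <- n
  }
  out
}

#' @noRd
nn_backward <- function(loss) {
  stopifnot(is_tensor(loss), length(loss$v) == 1L)
  loss$g <- 1
  if (.tape$n == 0L) return(invisible())
  for (i in seq(.tape$n, 1L)) {
    node <- .tape$nodes[[i]]
    if (is.null(node) || is.null(node$g)) next
    grads <- node$bw(node$g)
    ps <- node$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      gj <- grads[[j]]
      if (is.null(gj) || !isTRUE(p$rg)) next
      p$g <- if (is.null(p$g)) gj else p$g + gj
    }
    node$g <- NULL
  }
  invisible()
}

# Coerce numeric input to a [H,W,C,N] tensor (no grad).
as_tensor4 <- function(x) {
  if (is_tensor(x)) return(x)
  x <- as_array4(x)
  nn_tensor(x)
}

# Promote matrix / 3-d array to [H,W,C,N].
as_array4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or array, got a plain vector")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected 2-4 dimensions, got ", length(d))
  x
}
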