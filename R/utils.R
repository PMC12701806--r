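# Internal numerical helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Row-wise numerically stable log-softmax of a matrix of logits.
log_softmax <- function(z) {
  m <- apply(z, 1L, max)
  zs <- z - m
  zs - log(rowSums(exp(zs)))
}

softmax_rows <- function(z) {
  p <- exp(log_softmax(z))
  p / rowSums(p)
}

# One-hot encode integer class labels (1..C) into an N x C matrix.
one_hot <- function(labels, C) {
  Y <- matrix(0, length(labels), C)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

# Derive a child seed from a base seed; kept within 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 10007 * as.double(offset)) %% 2147483647L)
}
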