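# Linear operators used by the wavelet transforms.
#
# Every 1-D filtering step (symmetric-extension convolution at level 1,
# circular decimated filtering at deeper levels) is linear in the input
# column, so it is materialised once per (filter, length) as a dense
# matrix and applied by BLAS matrix multiplication.  Operators are cached
# in a package-local environment; a 5-level decomposition of a stack of
# equally sized slices therefore pays the construction cost only once.

.op_cache <- new.env(parent = emptyenv())

# Map arbitrary integer indices onto 1..n by half-point symmetric
# reflection with edge repetition (... 2 1 | 1 2 ... n-1 n | n n-1 ...).
reflect_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j >= n, 2L * n - 1L - j, j) + 1L
}

# Undecimated centred convolution with symmetric boundary extension:
# y[i] = sum_k h[k] x_ext[i + c - k], c = centre tap index.
op_sym_conv <- function(h, n) {
  ctr <- (length(h) + 1L) %/% 2L
  M <- matrix(0, n, n)
  rows <- seq_len(n)
  for (k in seq_along(h)) {
    cols <- reflect_index(rows + ctr - k, n)
    idx <- cbind(rows, cols)
    M[idx] <- M[idx] + h[k]
  }
  M
}

# Circular convolution with decimation by two:
# y[i] = sum_k h[k] x[(2i + d - k) mod n], i = 0..n/2-1 (0-based),
# with d = length(h)/2 so coefficients stay roughly centred under
# features of the input.  For a conjugate-quadrature pair the stacked
# low/high operator is exactly orthogonal, so the inverse is the
# transpose.
op_circ_down <- function(h, n) {
  stopifnot(n %% 2L == 0L)
  d <- length(h) %/% 2L
  M <- matrix(0, n %/% 2L, n)
  rows <- seq_len(n %/% 2L)
  for (k in seq_along(h)) {
    cols <- (2L * (rows - 1L) + d - (k - 1L)) %% n + 1L
    idx <- cbind(rows, cols)
    M[idx] <- M[idx] + h[k]
  }
  M
}

# Retrieve (building if needed) a cached operator.
get_op <- function(kind, h, n, key) {
  id <- paste(kind, key, n, sep = "|")
  op <- .op_cache[[id]]
  if (is.null(op)) {
    op <- switch(kind,
      sym  = op_sym_conv(h, n),
      down = op_circ_down(h, n),
      stop("unknown operator kind: ", kind))
    .op_cache[[id]] <- op
  }
  op
}

# Apply a column operator M to the rows dimension, and the row operator
# N to the columns dimension: result = M %*% X %*% t(N).
apply_sep <- function(X, M, N) M %*% X %*% t(N)

# Clear cached operators (exposed for tests / memory control).
#' Drop cached filter-bank operator matrices
#'
#' The transform caches one dense matrix per (filter, signal length)
#' combination.  Call this to release that memory, e.g. after processing
#' a batch of unusually large images.
#' @return Invisibly, the number of operators dropped.
#' @export
clear_op_cache <- function() {
  n <- length(ls(.op_cache))
  rm(list = ls(.op_cache), envir = .op_cache)
  invisible(n)
}
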