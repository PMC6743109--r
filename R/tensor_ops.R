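# Framework-independent reference implementations of the forward-pass
# primitives: 2-D convolution (cross-correlation, no kernel flip), zero
# padding, max pooling, ReLU and softmax.  Written as direct, readable
# loops over small grids; the trained network's vectorized layers are
# checked against these in the test suite.

#' Rectified linear unit
#'
#' @param x numeric vector/matrix.
#' @return elementwise max(x, 0), dimensions preserved.
#' @export
relu <- function(x) pmax(x, 0)

activation_fun <- function(name) {
  switch(match.arg(name, c("identity", "relu", "sigmoid")),
         identity = identity,
         relu = relu,
         sigmoid = function(x) 1 / (1 + exp(-x)))
}

#' 2-D convolution (sliding weighted sum)
#'
#' Implements convolution as cross-correlation: the kernel is slid over
#' the input without flipping and each output cell is the weighted sum of
#' the covered block, plus bias, through the activation.  With `"valid"`
#' padding an r-by-c input and a K-by-K kernel give an (r-K+1)-by-(c-K+1)
#' map; `"same"` zero-pads by (K-1)/2 so the shape is preserved (odd K).
#'
#' @param input numeric matrix.
#' @param kernel numeric `K x K` matrix.
#' @param bias scalar added to every weighted sum.
#' @param padding `"valid"` or `"same"`.
#' @param activation `"identity"`, `"relu"` or `"sigmoid"`.
#' @return the feature-map matrix.
#' @export
conv2d <- function(input, kernel, bias = 0, padding = c("valid", "same"),
                   activation = "identity") {
  padding <- match.arg(padding)
  stopifnot(is.matrix(input), is.matrix(kernel),
            nrow(kernel) == ncol(kernel))
  K <- nrow(kernel)
  if (padding == "same") {
    if (K %% 2 == 0) stop("same padding needs an odd kernel size")
    input <- zero_pad(input, (K - 1) / 2)
  }
  ro <- nrow(input) - K + 1
  co <- ncol(input) - K + 1
  if (ro < 1 || co < 1) stop("kernel larger than (padded) input")
  f <- activation_fun(activation)
  out <- matrix(0, ro, co)
  for (i in seq_len(ro)) {
    for (j in seq_len(co)) {
      out[i, j] <- sum(input[i:(i + K - 1), j:(j + K - 1)] * kernel) + bias
    }
  }
  f(out)
}

#' Surround a grid with a zero border
#'
#' @param input numeric matrix.
#' @param margin rings of zeros to add on every side (>= 0).
#' @return `(r + 2 margin) x (c + 2 margin)` matrix with `input` centered.
#' @export
zero_pad <- function(input, margin = 1) {
  stopifnot(is.matrix(input), margin >= 0)
  margin <- as.integer(margin)
  if (margin == 0) return(input)
  out <- matrix(0, nrow(input) + 2 * margin, ncol(input) + 2 * margin)
  out[margin + seq_len(nrow(input)), margin + seq_len(ncol(input))] <- input
  out
}

#' Max pooling
#'
#' Tiles the grid with `window x window` blocks at the given stride and
#' takes the maximum of each block.  Edge blocks may be partial (ceiling
#' tiling), so an r-by-r input with window 2, stride 2 yields ceil(r/2)
#' cells per side; an 8 x 8 grid pools to 4 x 4.
#'
#' @param input numeric matrix.
#' @param window block edge length.
#' @param stride step between block origins.
#' @return pooled matrix.
#' @export
max_pool <- function(input, window = 2, stride = 2) {
  stopifnot(is.matrix(input), window >= 1, stride >= 1)
  if (window > nrow(input) || window > ncol(input)) {
    stop("pooling window larger than input")
  }
  ri <- seq(1, nrow(input), by = stride)
  ci <- seq(1, ncol(input), by = stride)
  out <- matrix(0, length(ri), length(ci))
  for (a in seq_along(ri)) {
    for (b in seq_along(ci)) {
      rows <- ri[a]:min(ri[a] + window - 1, nrow(input))
      cols <- ci[b]:min(ci[b] + window - 1, ncol(input))
      out[a, b] <- max(input[rows, cols])
    }
  }
  out
}

#' Softmax
#'
#' Exponential normalization with the max-shift trick for numerical
#' stability: `softmax(z) = exp(z - max z) / sum exp(z - max z)`.
#'
#' @param z numeric vector of finite scores.
#' @return probability vector (positive, sums to 1).
#' @export
softmax <- function(z) {
  stopifnot(all(is.finite(z)))
  e <- exp(z - max(z))
  e / sum(e)
}
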