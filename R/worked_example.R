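# A fully worked numeric example of the forward-pass arithmetic on a real
# 3-mer frequency matrix: one 8 x 8 input (a 64-entry 3-mer frequency
# vector laid out row-major), one fixed 3 x 3 kernel, and the chain
# valid convolution -> zero padding -> 2x2/2 max pooling.  Every stage is
# computed by the reference tensor ops, so the chain doubles as an
# executable self-test of the arithmetic.

#' The worked example's 8 x 8 k-mer frequency matrix
#'
#' A 3-mer (64-entry) frequency vector of one lncRNA sequence arranged
#' row-major on an 8 x 8 grid.
#'
#' @return an 8 x 8 numeric matrix.
#' @export
example_frequency_matrix <- function() {
  matrix(c(
    0.0059, 0.0102, 0.0117, 0.0190, 0.0059, 0.0029, 0.0059, 0.0102,
    0.0088, 0.0073, 0.0220, 0.0059, 0.0220, 0.0146, 0.0234, 0.0146,
    0.0044, 0.0044, 0.0088, 0.0088, 0.0073, 0.0102, 0.0176, 0.0161,
    0.0132, 0.0176, 0.0322, 0.0117, 0.0117, 0.0220, 0.0249, 0.0146,
    0.0161, 0.0044, 0.0102, 0.0337, 0.0088, 0.0264, 0.0293, 0.0264,
    0.0278, 0.0439, 0.0366, 0.0190, 0.0044, 0.0132, 0.0190, 0.0102,
    0.0205, 0.0073, 0.0117, 0.0176, 0.0044, 0.0117, 0.0220, 0.0190,
    0.0161, 0.0220, 0.0366, 0.0102, 0.0146, 0.0073, 0.0176, 0.0161),
    nrow = 8, byrow = TRUE)
}

#' The worked example's 3 x 3 convolution kernel
#'
#' @return a 3 x 3 0/1 matrix.
#' @export
example_kernel <- function() {
  matrix(c(1, 0, 1,
           0, 1, 0,
           1, 0, 0), nrow = 3, byrow = TRUE)
}

#' Run the worked forward-pass chain
#'
#' Computes, with the reference ops, the 6 x 6 feature map (valid
#' cross-correlation, bias 0, identity activation), its zero-padded 8 x 8
#' form, and the 4 x 4 max-pooled result (window 2, stride 2).  The first
#' feature-map cell is 0.0293.
#'
#' @return list with `input`, `kernel`, `feature_map` (6 x 6), `padded`
#'   (8 x 8) and `pooled` (4 x 4).
#' @export
worked_example <- function() {
  M <- example_frequency_matrix()
  K <- example_kernel()
  fm <- conv2d(M, K, bias = 0, padding = "valid", activation = "identity")
  padded <- zero_pad(fm, 1)
  pooled <- max_pool(padded, window = 2, stride = 2)
  list(input = M, kernel = K, feature_map = fm, padded = padded,
       pooled = pooled)
}
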