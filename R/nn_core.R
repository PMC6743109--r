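# Internal neural-network engine: batched im2col convolution, ceil-tiled
# 2x2 max pooling, dense layers, inverted dropout, softmax cross-entropy
# and the Adadelta update rule.
#
# Batches are arrays of dim (H, W, C, N).  A convolution layer is compiled
# once into a "geometry": the gather index taking the (padded) batch into
# im2col columns, and its sparse transpose used to scatter-add gradients
# back (col2im).  Both directions then reduce to dense BLAS matrix
# products, which is what makes training fast in plain R.  im2col column
# order: within a window, row offset fastest, then column offset, then
# input channel; windows ordered column-major over the output grid.  A
# kernel row of the weight matrix therefore reshapes to the K x K matrix
# used by the reference conv2d via matrix(w, K, K) per channel.

conv_geometry <- function(Hin, Win, Cin, K, Fout, padding) {
  margin <- if (padding == "same") {
    if (K %% 2 == 0) stop("same padding needs an odd kernel size")
    (K - 1L) %/% 2L
  } else 0L
  Hp <- Hin + 2L * margin
  Wp <- Win + 2L * margin
  Ho <- Hp - K + 1L
  Wo <- Wp - K + 1L
  if (Ho < 1L || Wo < 1L) {
    stop("input ", Hin, " x ", Win, " too small for a ", K, " x ", K,
         " kernel with ", padding, " padding")
  }
  og <- expand.grid(di = seq_len(K), dj = seq_len(K), ch = seq_len(Cin))
  off <- og$di + (og$dj - 1L) * Hp + (og$ch - 1L) * Hp * Wp
  pg <- expand.grid(io = seq_len(Ho), jo = seq_len(Wo))
  start <- (pg$io - 1L) + (pg$jo - 1L) * Hp
  idx <- rep(off, times = length(start)) + rep(start, each = length(off))
  scatter <- Matrix::sparseMatrix(
    i = seq_along(idx), j = idx, x = 1,
    dims = c(length(idx), Hp * Wp * Cin))
  list(Hin = Hin, Win = Win, Cin = Cin, K = K, Fout = Fout,
       margin = margin, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo,
       KKC = K * K * Cin, P = Ho * Wo, idx = idx, scatter = scatter)
}

pad_batch <- function(X, margin) {
  if (margin == 0L) return(X)
  d <- dim(X)
  Xp <- array(0, c(d[1] + 2L * margin, d[2] + 2L * margin, d[3], d[4]))
  Xp[margin + seq_len(d[1]), margin + seq_len(d[2]), , ] <- X
  Xp
}

conv_forward <- function(geom, W, b, X, relu_act = TRUE) {
  N <- dim(X)[4]
  Xp <- pad_batch(X, geom$margin)
  Xflat <- matrix(Xp, nrow = geom$Hp * geom$Wp * geom$Cin, ncol = N)
  cols <- Xflat[geom$idx, , drop = FALSE]
  dim(cols) <- c(geom$KKC, geom$P * N)
  Z <- W %*% cols + b
  A <- if (relu_act) pmax(Z, 0) else Z
  out <- aperm(array(A, c(geom$Fout, geom$P, N)), c(2, 1, 3))
  dim(out) <- c(geom$Ho, geom$Wo, geom$Fout, N)
  list(out = out, cols = cols, Z = Z, N = N)
}

conv_backward <- function(geom, W, cache, d_out, relu_act = TRUE) {
  N <- cache$N
  dim(d_out) <- c(geom$P, geom$Fout, N)
  dA <- aperm(d_out, c(2, 1, 3))
  dim(dA) <- c(geom$Fout, geom$P * N)
  dZ <- if (relu_act) dA * (cache$Z > 0) else dA
  dW <- dZ %*% t(cache$cols)
  db <- rowSums(dZ)
  dcols <- crossprod(W, dZ)
  dim(dcols) <- c(geom$KKC * geom$P, N)
  dXp <- as.matrix(Matrix::crossprod(geom$scatter, dcols))
  dXp <- array(dXp, c(geom$Hp, geom$Wp, geom$Cin, N))
  m <- geom$margin
  dX <- if (m > 0L) {
    dXp[m + seq_len(geom$Hin), m + seq_len(geom$Win), , , drop = FALSE]
  } else dXp
  list(dX = dX, dW = dW, db = db)
}

# 2x2 stride-2 max pooling with ceiling tiling: edge windows may be
# partial, so odd dimensions pool to ceil(d/2).  Implemented by -Inf
# padding to even dimensions and a 4-way pmax over strided slices.
pool_forward <- function(X) {
  d <- dim(X)
  Ho <- ceiling(d[1] / 2); Wo <- ceiling(d[2] / 2)
  Xe <- array(-Inf, c(2 * Ho, 2 * Wo, d[3], d[4]))
  Xe[seq_len(d[1]), seq_len(d[2]), , ] <- X
  ro <- seq(1, 2 * Ho, by = 2); re <- ro + 1
  co <- seq(1, 2 * Wo, by = 2); ce <- co + 1
  s1 <- Xe[ro, co, , , drop = FALSE]; s2 <- Xe[re, co, , , drop = FALSE]
  s3 <- Xe[ro, ce, , , drop = FALSE]; s4 <- Xe[re, ce, , , drop = FALSE]
  out <- pmax(s1, s2, s3, s4)
  m1 <- s1 == out
  m2 <- (s2 == out) & !m1
  m3 <- (s3 == out) & !(m1 | m2)
  m4 <- (s4 == out) & !(m1 | m2 | m3)
  list(out = out, masks = list(m1, m2, m3, m4), in_dim = d,
       even_dim = dim(Xe))
}

pool_backward <- function(cache, d_out) {
  dXe <- array(0, cache$even_dim)
  Ho2 <- cache$even_dim[1]; Wo2 <- cache$even_dim[2]
  ro <- seq(1, Ho2, by = 2); re <- ro + 1
  co <- seq(1, Wo2, by = 2); ce <- co + 1
  dXe[ro, co, , ] <- d_out * cache$masks[[1]]
  dXe[re, co, , ] <- d_out * cache$masks[[2]]
  dXe[ro, ce, , ] <- d_out * cache$masks[[3]]
  dXe[re, ce, , ] <- d_out * cache$masks[[4]]
  d <- cache$in_dim
  dXe[seq_len(d[1]), seq_len(d[2]), , , drop = FALSE]
}

# Inverted dropout: scaling at train time keeps inference dropout-free.
dropout_forward <- function(X, rate, train) {
  if (!train || rate <= 0) return(list(out = X, mask = NULL))
  mask <- array((stats::runif(length(X)) >= rate) / (1 - rate), dim(X))
  list(out = X * mask, mask = mask)
}

# Softmax cross-entropy on a score matrix Z (n_classes x N) against integer
# labels in 0..n_classes-1; returns mean loss and dZ (already /N).
softmax_xent <- function(Z, y) {
  N <- ncol(Z)
  Zs <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Zs)
  P <- sweep(E, 2, colSums(E), "/")
  picked <- P[cbind(y + 1L, seq_len(N))]
  loss <- -mean(log(pmax(picked, 1e-300)))
  Y <- matrix(0, nrow(Z), N)
  Y[cbind(y + 1L, seq_len(N))] <- 1
  list(loss = loss, probs = P, dZ = (P - Y) / N)
}

glorot_uniform <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

adadelta_state <- function(params) {
  lapply(params, function(p) list(Eg = p * 0, Ed = p * 0))
}

adadelta_update <- function(param, grad, state, lr, rho, eps) {
  state$Eg <- rho * state$Eg + (1 - rho) * grad^2
  step <- -sqrt(state$Ed + eps) / sqrt(state$Eg + eps) * grad
  state$Ed <- rho * state$Ed + (1 - rho) * step^2
  list(param = param + lr * step, state = state)
}
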