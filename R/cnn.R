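# The two-convolutional-layer classifier on k-mer frequency matrices:
# conv(32, 3x3, same, ReLU) -> conv(64, 3x3, valid, ReLU) -> max-pool 2x2
# -> dropout 0.25 -> flatten -> dense(128, ReLU) -> dropout 0.5 ->
# dense(2) -> softmax, trained with Adadelta on cross-entropy.
#
# Class encoding throughout: lncRNA = 0 (the positive class), mRNA = 1.

#' Configuration of the convolutional classifier
#'
#' Defaults follow the published architecture: 32 then 64 3x3 kernels,
#' ReLU activations, one 2x2 stride-2 max-pooling layer, dropout 0.25
#' before and 0.5 after the 128-unit dense layer, softmax output, Adadelta
#' on cross-entropy.  The first convolution uses zero same-padding; the
#' second defaults to valid padding so an 8x8 input passes through 6x6
#' feature maps to a 3x3 pooled grid (set `conv2_padding = "same"` for the
#' alternative all-same reading of the architecture).
#'
#' @param input_shape `c(rows, cols)` of the frequency matrices.
#' @param conv1_filters,conv2_filters kernel counts of the two layers.
#' @param kernel_size edge length of the (square) kernels.
#' @param conv2_padding `"valid"` or `"same"` for the second layer.
#' @param dropout1,dropout2 dropout rates before/after the dense layer.
#' @param dense_units width of the fully connected layer.
#' @param n_classes number of output classes.
#' @param epochs,batch_size training schedule.
#' @param lr,rho,eps Adadelta hyperparameters (standard defaults).
#' @param seed single integer driving every source of randomness
#'   (initialization, shuffling, dropout).
#' @return list of class `"cnn_config"`.
#' @export
cnn_config <- function(input_shape,
                       conv1_filters = 32L, conv2_filters = 64L,
                       kernel_size = 3L, conv2_padding = c("valid", "same"),
                       dropout1 = 0.25, dropout2 = 0.5,
                       dense_units = 128L, n_classes = 2L,
                       epochs = 200L, batch_size = 128L,
                       lr = 1.0, rho = 0.95, eps = 1e-6, seed = 1L) {
  conv2_padding <- match.arg(conv2_padding)
  stopifnot(length(input_shape) == 2, all(input_shape >= 1),
            dropout1 >= 0, dropout1 < 1, dropout2 >= 0, dropout2 < 1)
  structure(
    list(input_shape = as.integer(input_shape),
         conv1_filters = as.integer(conv1_filters),
         conv2_filters = as.integer(conv2_filters),
         kernel_size = as.integer(kernel_size),
         conv2_padding = conv2_padding,
         dropout1 = dropout1, dropout2 = dropout2,
         dense_units = as.integer(dense_units),
         n_classes = as.integer(n_classes),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lr = lr, rho = rho, eps = eps, seed = as.integer(seed)),
    class = "cnn_config")
}

#' Build an untrained classifier
#'
#' Compiles the layer geometry for the configured input shape and draws
#' Glorot-uniform initial weights from the config seed, so two builds with
#' the same config are bitwise identical.
#'
#' @param config a [cnn_config].
#' @return object of class `"cnn_model"` with elements `config`, `geom`,
#'   `params`, `n_parameters`, `history` (empty) and `vocab` (`NULL` until
#'   training attaches one).
#' @export
build_cnn <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  K <- config$kernel_size
  g1 <- conv_geometry(config$input_shape[1], config$input_shape[2], 1L,
                      K, config$conv1_filters, "same")
  g2 <- conv_geometry(g1$Ho, g1$Wo, config$conv1_filters,
                      K, config$conv2_filters, config$conv2_padding)
  pool_dim <- c(ceiling(g2$Ho / 2), ceiling(g2$Wo / 2), config$conv2_filters)
  flat <- prod(pool_dim)
  set.seed(config$seed)
  params <- list(
    W1 = glorot_uniform(config$conv1_filters, g1$KKC,
                        g1$KKC, config$conv1_filters * K * K),
    b1 = numeric(config$conv1_filters),
    W2 = glorot_uniform(config$conv2_filters, g2$KKC,
                        g2$KKC, config$conv2_filters * K * K),
    b2 = numeric(config$conv2_filters),
    Wd = glorot_uniform(config$dense_units, flat, flat, config$dense_units),
    bd = numeric(config$dense_units),
    Wo = glorot_uniform(config$n_classes, config$dense_units,
                        config$dense_units, config$n_classes),
    bo = numeric(config$n_classes))
  structure(
    list(config = config, geom = list(conv1 = g1, conv2 = g2,
                                      pool_dim = pool_dim, flat = flat),
         params = params,
         n_parameters = sum(vapply(params, length, integer(1))),
         history = data.frame(), vocab = NULL, trained = FALSE),
    class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cfg <- x$config
  cat("cnn_model: input ", cfg$input_shape[1], "x", cfg$input_shape[2],
      " -> conv(", cfg$conv1_filters, ", same) -> conv(", cfg$conv2_filters,
      ", ", cfg$conv2_padding, ") -> pool -> dense(", cfg$dense_units,
      ") -> ", cfg$n_classes, " classes; ", x$n_parameters, " parameters; ",
      if (x$trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

# Full forward pass; X is (H, W, 1, N).  With train = TRUE, dropout masks
# are drawn from the current RNG stream and caches for backprop are kept.
cnn_net_forward <- function(model, X, train = FALSE) {
  p <- model$params; g <- model$geom
  c1 <- conv_forward(g$conv1, p$W1, p$b1, X, relu_act = TRUE)
  c2 <- conv_forward(g$conv2, p$W2, p$b2, c1$out, relu_act = TRUE)
  pl <- pool_forward(c2$out)
  d1 <- dropout_forward(pl$out, model$config$dropout1, train)
  N <- dim(X)[4]
  flat <- matrix(d1$out, nrow = g$flat, ncol = N)
  Zd <- p$Wd %*% flat + p$bd
  Ad <- pmax(Zd, 0)
  d2 <- dropout_forward(Ad, model$config$dropout2, train)
  Zo <- p$Wo %*% d2$out + p$bo
  list(Zo = Zo, c1 = c1, c2 = c2, pl = pl, d1 = d1, flat = flat,
       Zd = Zd, d2 = d2, N = N)
}

cnn_net_backward <- function(model, fw, dZo) {
  p <- model$params; g <- model$geom
  grads <- list()
  grads$Wo <- dZo %*% t(fw$d2$out)
  grads$bo <- rowSums(dZo)
  dAd <- crossprod(p$Wo, dZo)
  if (!is.null(fw$d2$mask)) dAd <- dAd * fw$d2$mask
  dZd <- dAd * (fw$Zd > 0)
  grads$Wd <- dZd %*% t(fw$flat)
  grads$bd <- rowSums(dZd)
  dflat <- crossprod(p$Wd, dZd)
  dP <- array(dflat, dim(fw$pl$out))
  if (!is.null(fw$d1$mask)) dP <- dP * fw$d1$mask
  dC2 <- pool_backward(fw$pl, dP)
  bk2 <- conv_backward(g$conv2, p$W2, fw$c2, dC2, relu_act = TRUE)
  grads$W2 <- bk2$dW; grads$b2 <- bk2$db
  bk1 <- conv_backward(g$conv1, p$W1, fw$c1, bk2$dX, relu_act = TRUE)
  grads$W1 <- bk1$dW; grads$b1 <- bk1$db
  grads[names(model$params)]
}

as_feature_array <- function(model, features) {
  shape <- model$config$input_shape
  if (is.array(features) && length(dim(features)) == 4) {
    if (!all(dim(features)[1:2] == shape)) {
      stop("feature array is ", dim(features)[1], "x", dim(features)[2],
           " but the model expects ", shape[1], "x", shape[2])
    }
    return(features)
  }
  if (is.matrix(features) && all(dim(features) == shape)) {
    return(array(features, c(shape, 1L, 1L)))
  }
  if (is.matrix(features)) return(to_matrix_array(features, shape))
  if (is.list(features)) {
    X <- array(0, c(shape, 1L, length(features)))
    for (i in seq_along(features)) {
      stopifnot(all(dim(features[[i]]) == shape))
      X[, , 1L, i] <- features[[i]]
    }
    return(X)
  }
  stop("unsupported feature container")
}

#' Train the classifier
#'
#' Minibatch Adadelta on softmax cross-entropy.  Labels must contain both
#' classes.  All randomness (shuffling, dropout) continues the RNG stream
#' seeded by the config, so training is reproducible end to end.
#'
#' @param model an untrained (or previously trained) [build_cnn] model.
#' @param features frequency matrices: a 4-D array `(rows, cols, 1, n)`, a
#'   feature matrix from [frequency_table] (rows are laid out via
#'   [to_matrix]), or a list of matrices.
#' @param labels integer labels, lncRNA = 0 / mRNA = 1.
#' @param epochs,batch_size override the config schedule.
#' @param vocab optional [kmer_vocabulary] recorded for prediction-time
#'   compatibility checks.
#' @param verbose print one line per epoch.
#' @return the trained `"cnn_model"`, with `history` (epoch, loss,
#'   accuracy).
#' @export
train_cnn <- function(model, features, labels,
                      epochs = model$config$epochs,
                      batch_size = model$config$batch_size,
                      vocab = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"))
  if (is.matrix(features) && is.null(vocab)) vocab <- attr(features, "vocab")
  X <- as_feature_array(model, features)
  y <- as.integer(labels)
  N <- dim(X)[4]
  stopifnot(length(y) == N)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  if (!all(y %in% 0:(model$config$n_classes - 1L))) stop("labels out of range")
  cfg <- model$config
  if (!model$trained) set.seed(cfg$seed)  # resuming keeps the stream
  opt <- adadelta_state(model$params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0; ep_correct <- 0
    for (b0 in seq(1, N, by = batch_size)) {
      take <- ord[b0:min(b0 + batch_size - 1, N)]
      Xb <- X[, , , take, drop = FALSE]
      yb <- y[take]
      fw <- cnn_net_forward(model, Xb, train = TRUE)
      sm <- softmax_xent(fw$Zo, yb)
      ep_loss <- ep_loss + sm$loss * length(take)
      ep_correct <- ep_correct + sum(max.col(t(sm$probs)) - 1L == yb)
      grads <- cnn_net_backward(model, fw, sm$dZ)
      for (nm in names(model$params)) {
        up <- adadelta_update(model$params[[nm]], grads[[nm]], opt[[nm]],
                              cfg$lr, cfg$rho, cfg$eps)
        model$params[[nm]] <- up$param
        opt[[nm]] <- up$state
      }
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss = ep_loss / N, accuracy = ep_correct / N))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.4f",
                      ep, ep_loss / N, ep_correct / N))
    }
  }
  model$history <- rbind(model$history, history)
  model$vocab <- vocab %||% model$vocab
  model$trained <- TRUE
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict class probabilities and labels
#'
#' Inference is dropout-free and deterministic.  When `newdata` is a
#' feature matrix carrying a vocabulary, it is checked against the one the
#' model was trained with.
#'
#' @param object a trained `"cnn_model"`.
#' @param newdata features as in [train_cnn].
#' @param type `"prob"` for the probability matrix, `"class"` for hard
#'   labels, `"report"` for a per-sequence data.frame.
#' @param ... unused.
#' @return per `type`: an `n x 2` matrix with columns `lncRNA`/`mRNA`, an
#'   integer label vector, or a data.frame with `p_lncRNA`, `p_mRNA`,
#'   `pre_label` and `class`.
#' @export
predict.cnn_model <- function(object, newdata,
                              type = c("prob", "class", "report"), ...) {
  type <- match.arg(type)
  if (!object$trained) warning("predicting from an untrained model")
  check_vocab_compat(object, newdata)
  X <- as_feature_array(object, newdata)
  N <- dim(X)[4]
  probs <- matrix(0, N, object$config$n_classes)
  for (b0 in seq(1, N, by = 512)) {
    take <- b0:min(b0 + 511, N)
    fw <- cnn_net_forward(object, X[, , , take, drop = FALSE], train = FALSE)
    Zs <- sweep(fw$Zo, 2, apply(fw$Zo, 2, max))
    E <- exp(Zs)
    probs[take, ] <- t(sweep(E, 2, colSums(E), "/"))
  }
  colnames(probs) <- c("lncRNA", "mRNA")[seq_len(ncol(probs))]
  label <- max.col(probs) - 1L
  switch(type,
         prob = probs,
         class = label,
         report = data.frame(p_lncRNA = probs[, 1], p_mRNA = probs[, 2],
                             pre_label = label, class = label_name(label)))
}

check_vocab_compat <- function(model, newdata) {
  nd_vocab <- attr(newdata, "vocab")
  if (is.null(model$vocab) || is.null(nd_vocab)) return(invisible(TRUE))
  if (!identical(model$vocab$kmers, nd_vocab$kmers)) {
    stop("feature vocabulary does not match the model's; the model was ",
         "trained on ", model$vocab$size, " k-mers (k = ",
         paste(model$vocab$ks, collapse = ","), ")")
  }
  invisible(TRUE)
}

#' Classify sequences end to end
#'
#' Featurizes records with the model's stored vocabulary and predicts,
#' reproducing the single-sequence workflow (frequency vector -> matrix ->
#' forward pass -> `pre_label`).
#'
#' @param model a trained `"cnn_model"` with a stored vocabulary.
#' @param records a [seq_records] table.
#' @return data.frame with `id`, `p_lncRNA`, `p_mRNA`, `pre_label`,
#'   `class`.
#' @export
predict_sequences <- function(model, records) {
  if (is.null(model$vocab)) stop("model carries no vocabulary; train with one")
  feats <- frequency_table(records, vocab = model$vocab)
  out <- predict(model, feats, type = "report")
  cbind(id = records$id, out)
}

#' Stratified train/test split
#'
#' @param labels integer label vector.
#' @param test_prop held-out proportion (default 0.2, the 8000/2000
#'   train/test design).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
train_test_split <- function(labels, test_prop = 0.2, seed = 1L) {
  stopifnot(test_prop > 0, test_prop < 1)
  set.seed(seed)
  test <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    test <- c(test, sample(idx, max(1L, round(length(idx) * test_prop))))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Featurizes once, then trains a fresh model per fold (same config, fold-
#' specific seeds derived from the config seed) and evaluates on the
#' held-out fold.
#'
#' @param records labeled [seq_records] (both classes in every fold).
#' @param ks window lengths used for featurization.
#' @param config a [cnn_config]; its `input_shape` must match
#'   [matrix_shape_for] of the vocabulary size.
#' @param folds number of folds (>= 2).
#' @param epochs override of the per-fold training length.
#' @return list with `reports` (one [eval_report] per fold), `mean_accuracy`
#'   and `fold_assignment`.
#' @export
crossvalidate_cnn <- function(records, ks = c(1, 2, 3), config, folds = 10L,
                              epochs = config$epochs) {
  if (folds < 2) stop("folds must be >= 2")
  if (nrow(records) < folds) stop("fewer records than folds")
  y <- records$label
  if (any(is.na(y))) stop("all records must be labeled")
  set.seed(config$seed)
  fold_of <- integer(nrow(records))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  vocab <- kmer_vocabulary(ks)
  feats <- frequency_table(records, vocab = vocab)
  X <- to_matrix_array(feats, config$input_shape)
  reports <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) {
      stop("fold ", f, " does not contain both classes")
    }
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    mod <- build_cnn(cfg_f)
    mod <- train_cnn(mod, X[, , , tr, drop = FALSE], y[tr],
                     epochs = epochs, vocab = vocab)
    probs <- predict(mod, X[, , , te, drop = FALSE], type = "prob")
    reports[[f]] <- eval_report(y[te], max.col(probs) - 1L,
                                scores = probs[, 1],
                                model_name = sprintf("CNN fold %d", f))
  }
  list(reports = reports,
       mean_accuracy = mean(vapply(reports, function(r) r$accuracy, numeric(1))),
       fold_assignment = fold_of)
}

#' Persist a trained model to a directory
#'
#' Writes `config.json`, `vocabulary.txt` (when present), `history.csv`
#' and `weights.rds`.
#'
#' @param model a `"cnn_model"`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_cnn <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(model$config[names(model$config)],
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(model$vocab)) {
    write_vocabulary(model$vocab, file.path(dir, "vocabulary.txt"))
  }
  utils::write.csv(model$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' Load a model saved by [save_cnn]
#'
#' @param dir directory written by [save_cnn].
#' @return a `"cnn_model"` ready for prediction.
#' @export
load_cnn <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  config <- cnn_config(
    input_shape = cfg$input_shape, conv1_filters = cfg$conv1_filters,
    conv2_filters = cfg$conv2_filters, kernel_size = cfg$kernel_size,
    conv2_padding = cfg$conv2_padding, dropout1 = cfg$dropout1,
    dropout2 = cfg$dropout2, dense_units = cfg$dense_units,
    n_classes = cfg$n_classes, epochs = cfg$epochs,
    batch_size = cfg$batch_size, lr = cfg$lr, rho = cfg$rho,
    eps = cfg$eps, seed = cfg$seed)
  model <- build_cnn(config)
  model$params <- readRDS(file.path(dir, "weights.rds"))
  hist_path <- file.path(dir, "history.csv")
  if (file.exists(hist_path)) model$history <- utils::read.csv(hist_path)
  vocab_path <- file.path(dir, "vocabulary.txt")
  if (file.exists(vocab_path)) model$vocab <- read_vocabulary(vocab_path)
  model$trained <- TRUE
  model
}
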