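test_that("layer geometry matches the published architecture", {
  cfg <- cnn_config(c(8, 8))
  m <- build_cnn(cfg)
  # same-padded conv keeps 8x8, valid conv gives 6x6, pooling halves to 3x3
  expect_equal(c(m$geom$conv1$Ho, m$geom$conv1$Wo), c(8, 8))
  expect_equal(c(m$geom$conv2$Ho, m$geom$conv2$Wo), c(6, 6))
  expect_equal(m$geom$pool_dim, c(3, 3, 64))
  expect_equal(m$geom$flat, 3 * 3 * 64)

  # the 84-feature layout builds without error
  m2 <- build_cnn(cnn_config(c(7, 12)))
  expect_equal(m2$geom$pool_dim, c(3, 5, 64))

  expect_error(build_cnn(cnn_config(c(2, 2))), "too small")
  expect_error(cnn_config(c(8, 8), dropout1 = 1), "dropout1")
})

test_that("initialization is a deterministic function of the seed", {
  cfg <- cnn_config(c(7, 12), seed = 99L)
  expect_identical(build_cnn(cfg)$params, build_cnn(cfg)$params)
  cfg2 <- cnn_config(c(7, 12), seed = 100L)
  expect_false(identical(build_cnn(cfg)$params, build_cnn(cfg2)$params))
})

test_that("analytic gradients match finite differences", {
  cfg <- cnn_config(c(5, 6), conv1_filters = 2L, conv2_filters = 3L,
                    dense_units = 4L, dropout1 = 0, dropout2 = 0,
                    seed = 42L)
  m <- build_cnn(cfg)
  set.seed(7)
  X <- array(rnorm(5 * 6 * 4), c(5, 6, 1, 4))
  y <- c(0L, 1L, 0L, 1L)
  fw <- kmerCNN:::cnn_net_forward(m, X, train = FALSE)
  sm <- kmerCNN:::softmax_xent(fw$Zo, y)
  gr <- kmerCNN:::cnn_net_backward(m, fw, sm$dZ)
  eps <- 1e-6
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(6, length(p)))) {
      m2 <- m
      m2$params[[nm]][i] <- p[i] + eps
      up <- kmerCNN:::softmax_xent(kmerCNN:::cnn_net_forward(m2, X)$Zo, y)$loss
      m2$params[[nm]][i] <- p[i] - eps
      dn <- kmerCNN:::softmax_xent(kmerCNN:::cnn_net_forward(m2, X)$Zo, y)$loss
      num <- (up - dn) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("the first network layer agrees with the reference conv2d", {
  # layer-equivalence oracle: extract each conv1 kernel and rerun it
  # through the loop-based reference implementation
  cfg <- cnn_config(c(8, 8), seed = 12L)
  m <- build_cnn(cfg)
  M <- example_frequency_matrix()
  fw <- kmerCNN:::cnn_net_forward(m, array(M, c(8, 8, 1, 1)))
  for (f in c(1L, 17L, 32L)) {
    kern <- matrix(m$params$W1[f, ], 3, 3)
    ref <- conv2d(M, kern, bias = m$params$b1[f], padding = "same",
                  activation = "relu")
    expect_equal(fw$c1$out[, , f, 1], ref, tolerance = 1e-12)
  }
})

test_that("training learns a separable synthetic contrast reproducibly", {
  rec <- simulate_corpus(50, length_range = list(lncRNA = c(500, 900),
                                                 mRNA = c(500, 900)),
                         seed = 5)
  vocab <- kmer_vocabulary(1:3)
  feats <- frequency_table(rec, vocab = vocab)
  cfg <- cnn_config(c(7, 12), epochs = 30L, batch_size = 16L, seed = 2L)
  m <- train_cnn(build_cnn(cfg), feats, rec$label, vocab = vocab)
  expect_true(m$trained)
  expect_equal(nrow(m$history), 30)
  expect_true(all(is.finite(m$history$loss)))
  expect_gte(utils::tail(m$history$accuracy, 1), 0.9)

  # identical seed, identical everything
  m2 <- train_cnn(build_cnn(cfg), feats, rec$label, vocab = vocab)
  expect_identical(m$params, m2$params)
  expect_identical(m$history, m2$history)

  # inference is deterministic (dropout off) and probabilities are proper
  p1 <- predict(m, feats, type = "prob")
  p2 <- predict(m, feats, type = "prob")
  expect_identical(p1, p2)
  expect_equal(rowSums(p1), rep(1, nrow(feats)), tolerance = 1e-12)

  rep <- predict(m, feats, type = "report")
  expect_equal(rep$class, label_name(rep$pre_label))

  expect_error(train_cnn(build_cnn(cfg), feats, rep(0L, nrow(feats))),
               "single class")
})

test_that("persistence round-trips predictions exactly", {
  rec <- small_corpus(20, seed = 8)
  vocab <- kmer_vocabulary(1:3)
  feats <- frequency_table(rec, vocab = vocab)
  cfg <- cnn_config(c(7, 12), epochs = 2L, batch_size = 16L, seed = 3L)
  m <- train_cnn(build_cnn(cfg), feats, rec$label, vocab = vocab)
  dir <- withr::local_tempdir()
  save_cnn(m, dir)
  expect_true(all(file.exists(file.path(
    dir, c("config.json", "weights.rds", "vocabulary.txt", "history.csv")))))
  m2 <- load_cnn(dir)
  expect_identical(predict(m, feats), predict(m2, feats))
  expect_equal(m2$vocab$kmers, vocab$kmers)

  # a model trained on one vocabulary refuses features from another
  wrong <- frequency_table(rec, ks = 2)
  expect_error(predict(m2, wrong), "vocabulary does not match")

  out <- predict_sequences(m2, rec[1:3, ])
  expect_equal(out$id, rec$id[1:3])
  expect_true(all(out$pre_label %in% 0:1))
})

test_that("stratified splitting and cross-validation are seed-deterministic", {
  labels <- rep(c(0L, 1L), each = 50)
  sp <- train_test_split(labels, test_prop = 0.2, seed = 4L)
  expect_length(sp$test, 20)
  expect_equal(sum(labels[sp$test] == 0), 10)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, train_test_split(labels, test_prop = 0.2, seed = 4L))

  rec <- small_corpus(20, seed = 6)
  cfg <- cnn_config(c(7, 12), epochs = 2L, batch_size = 16L, seed = 7L)
  cv <- crossvalidate_cnn(rec, ks = 1:3, config = cfg, folds = 2L)
  expect_length(cv$reports, 2)
  expect_s3_class(cv$reports[[1]], "eval_report")
  expect_true(is.finite(cv$mean_accuracy))
  cv2 <- crossvalidate_cnn(rec, ks = 1:3, config = cfg, folds = 2L)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_equal(cv$mean_accuracy, cv2$mean_accuracy)
  expect_error(crossvalidate_cnn(rec[1:3, ], ks = 1, config = cfg,
                                 folds = 5L), "fewer records")
})
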