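# Classical baselines on the flattened frequency vectors: random forest,
# (ridge-regularized) logistic regression, decision tree and RBF SVM.
# All four consume exactly the same feature extraction as the network; the
# classifier is the only difference.

BASELINE_FAMILIES <- c("RF", "LR", "DT", "SVM")

#' Baseline specification
#'
#' @param family one of `"RF"`, `"LR"`, `"DT"`, `"SVM"`.
#' @param params named list of hyperparameter overrides passed to the
#'   underlying fitter; defaults are the standard library defaults.
#' @param seed RNG seed for the stochastic fitters.
#' @return list of class `"baseline_spec"`.
#' @export
baseline_spec <- function(family, params = list(), seed = 1L) {
  if (!family %in% BASELINE_FAMILIES) {
    stop("unknown baseline family '", family, "'; use one of ",
         paste(BASELINE_FAMILIES, collapse = ", "))
  }
  structure(list(family = family, params = params, seed = as.integer(seed)),
            class = "baseline_spec")
}

#' Train one baseline on frequency vectors
#'
#' @param spec a [baseline_spec].
#' @param features numeric matrix, one row per sequence (e.g. from
#'   [frequency_table]).
#' @param labels integer labels, lncRNA = 0 / mRNA = 1; both classes must
#'   be present.
#' @return object of class `"baseline_model"` wrapping the fitted model.
#' @export
train_baseline <- function(spec, features, labels) {
  stopifnot(inherits(spec, "baseline_spec"))
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  stopifnot(nrow(features) == length(y))
  x <- unname(as.matrix(features))
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  set.seed(spec$seed)
  yf <- factor(y, levels = c(0, 1))
  fit <- switch(
    spec$family,
    RF = do.call(randomForest::randomForest,
                 c(list(x = x, y = yf), spec$params)),
    # L2-regularized logistic regression (lambda = 1/n matches the common
    # C = 1 default of other stacks); plain ML logistic regression
    # separates perfectly on clean synthetic corpora.
    LR = do.call(glmnet::glmnet,
                 c(list(x = x, y = yf, family = "binomial", alpha = 0,
                        lambda = 1 / length(y)), spec$params)),
    DT = do.call(rpart::rpart,
                 c(list(formula = y ~ ., data = data.frame(y = yf, x),
                        method = "class"), spec$params)),
    SVM = do.call(e1071::svm,
                  c(list(x = x, y = yf, probability = TRUE), spec$params)))
  structure(list(spec = spec, fit = fit, n_features = ncol(x)),
            class = "baseline_model")
}

#' Predict from a trained baseline
#'
#' @param object a `"baseline_model"`.
#' @param newdata feature matrix with the same columns as in training.
#' @param type `"prob"` for an `n x 2` matrix (`lncRNA`, `mRNA`) or
#'   `"class"` for hard labels.
#' @param ... unused.
#' @return per `type`.
#' @export
predict.baseline_model <- function(object, newdata,
                                   type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- unname(as.matrix(newdata))
  if (ncol(x) != object$n_features) {
    stop("expected ", object$n_features, " features, got ", ncol(x))
  }
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  p1 <- switch(  # probability of class "1" (mRNA)
    object$spec$family,
    RF = stats::predict(object$fit, x, type = "prob")[, "1"],
    LR = as.numeric(stats::predict(object$fit, x, type = "response")),
    DT = stats::predict(object$fit, data.frame(x), type = "prob")[, "1"],
    SVM = {
      pr <- stats::predict(object$fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    })
  probs <- cbind(lncRNA = 1 - p1, mRNA = p1)
  if (type == "prob") probs else as.integer(probs[, "mRNA"] > 0.5)
}

#' Train and evaluate every baseline plus the network on a shared split
#'
#' Convenience wrapper used by the comparison workflow: all four baseline
#' families are fitted on `features[train, ]` and evaluated on
#' `features[test, ]`.
#'
#' @param features feature matrix from [frequency_table].
#' @param labels integer labels.
#' @param train,test integer row indices (e.g. from [train_test_split]).
#' @param seed seed shared by the stochastic fitters.
#' @return list of [eval_report]s, one per family.
#' @export
evaluate_baselines <- function(features, labels, train, test, seed = 1L) {
  lapply(BASELINE_FAMILIES, function(fam) {
    fit <- train_baseline(baseline_spec(fam, seed = seed),
                          features[train, , drop = FALSE], labels[train])
    probs <- predict(fit, features[test, , drop = FALSE])
    eval_report(labels[test], as.integer(probs[, "mRNA"] > 0.5),
                scores = probs[, "lncRNA"], model_name = fam)
  })
}

#' Ranked model-comparison table
#'
#' @param reports list of [eval_report]s sharing one test set (same size
#'   and true labels).
#' @return data.frame with columns `model`, `accuracy`, `precision`,
#'   `recall`, `f1`, `auc`, sorted by accuracy (ties by model name).
#' @export
compare_models <- function(reports) {
  stopifnot(length(reports) >= 1)
  truths <- lapply(reports, function(r) r$truth)
  if (length(unique(vapply(truths, function(t) paste(t, collapse = ""),
                           character(1)))) != 1) {
    stop("reports do not share a test set")
  }
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(model = r$model_name, accuracy = r$accuracy,
               precision = r$precision, recall = r$recall,
               f1 = r$f1, auc = r$auc)
  }))
  df <- df[order(-df$accuracy, df$model), ]
  rownames(df) <- NULL
  df
}

#' Write a comparison table as TSV and Markdown
#'
#' @param table data.frame from [compare_models].
#' @param path output path; `path` gets the TSV and `paste0(path, ".md")`
#'   the Markdown rendering.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))
  md <- c(
    "| model | accuracy | P | R | F1 | AUC |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %s | %s | %s |", table$model,
            fmt(table$accuracy), fmt(table$precision), fmt(table$recall),
            fmt(table$f1), fmt(table$auc)))
  writeLines(md, paste0(path, ".md"))
  invisible(path)
}
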