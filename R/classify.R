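#' Classifier specification
#'
#' The six classifiers of the motor-imagery chain with their fixed
#' hyperparameters: random forest with 100 trees (`"rf"`), k-nearest
#' neighbors with k = 5 (`"knn"`), linear-kernel SVM trained one-versus-rest
#' (`"svm"`), Gaussian naive Bayes (`"nb"`), L2-regularized logistic
#' regression (`"lr"`), and a decision tree with maximum depth 10 (`"dt"`).
#'
#' @param algorithm one of `"rf"`, `"knn"`, `"svm"`, `"nb"`, `"lr"`, `"dt"`.
#' @param seed integer seed for stochastic fits.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(algorithm = c("rf", "knn", "svm", "nb", "lr", "dt"),
                       seed = 1L) {
  algorithm <- match.arg(algorithm)
  hp <- switch(algorithm,
               rf = list(ntree = 100),
               knn = list(k = 5),
               svm = list(kernel = "linear", strategy = "ovr"),
               nb = list(distribution = "gaussian"),
               lr = list(penalty = "l2"),
               dt = list(max_depth = 10))
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Stratified train/test split
#'
#' Splits rows into disjoint, exhaustive train and test sets, preserving
#' class proportions to within one sample per class, reproducibly for a
#' fixed seed. The standard protocol is 80% training, 20% testing.
#'
#' @param x feature matrix (rows = samples).
#' @param y class labels.
#' @param train_fraction fraction of each class assigned to training.
#' @param seed integer seed.
#' @return list with `train` and `test`, each `list(x, y, idx)`.
#' @export
split_dataset <- function(x, y, train_fraction = 0.8, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(y),
            train_fraction > 0, train_fraction < 1)
  y <- as.character(y)
  counts <- table(y)
  if (any(counts < 2)) {
    stop("class '", names(counts)[which(counts < 2)[1]],
         "' has fewer than 2 samples; cannot split")
  }
  train_idx <- with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      idx <- which(y == cl)
      n_tr <- min(max(round(train_fraction * length(idx)), 1L),
                  length(idx) - 1L)
      sample(idx, n_tr)
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(y), train_idx)
  list(train = list(x = x[train_idx, , drop = FALSE], y = y[train_idx],
                    idx = train_idx),
       test = list(x = x[test_idx, , drop = FALSE], y = y[test_idx],
                   idx = test_idx))
}

#' Train a classifier
#'
#' Fits the classifier named by the [model_spec()] on a feature matrix. Rows with
#' non-finite features must be excluded beforehand (flagged epochs are never
#' imputed). The SVM is trained one binary machine per class against the
#' rest; prediction takes the argmax of the decision scores, ties broken by
#' training-class frequency then by fixed class order.
#'
#' @param x numeric feature matrix, rows = samples.
#' @param y class labels (2 or more classes).
#' @param spec a [model_spec()].
#' @return object of class `bci_model`.
#' @export
train_model <- function(x, y, spec = model_spec("lr")) {
  stopifnot(is.matrix(x), nrow(x) == length(y), nrow(x) > 0)
  if (!all(is.finite(x))) stop("training features must be finite")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- factor(y)
  if (nlevels(y) < 2) stop("training data contains a single class")
  lv <- levels(y)
  fit <- with_seed(spec$seed, switch(
    spec$algorithm,
    rf = randomForest::randomForest(x = x, y = y, ntree = 100),
    knn = list(x = x, y = y, k = 5),
    svm = lapply(lv, function(cl) {
      yb <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
      e1071::svm(x = x, y = yb, kernel = "linear", scale = FALSE)
    }),
    nb = e1071::naiveBayes(x = x, y = y),
    lr = glmnet::glmnet(
      x = x, y = y,
      family = if (nlevels(y) == 2) "binomial" else "multinomial",
      alpha = 0, lambda = 1 / length(y), standardize = FALSE),
    dt = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(maxdepth = 10))
    },
    stop("unknown algorithm: ", spec$algorithm)))
  structure(list(spec = spec, fit = fit, levels = lv,
                 class_freq = as.numeric(table(y)[lv]),
                 layout = colnames(x)),
            class = "bci_model")
}

#' @export
print.bci_model <- function(x, ...) {
  cat(sprintf("<bci_model> %s, %d classes (%s)\n", x$spec$algorithm,
              length(x$levels), paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Predict labels and per-class scores
#'
#' Scores are posterior probabilities (rf, nb, dt, lr after the logistic
#' link), decision values (svm), or k-NN vote shares (the winning class's
#' share; the remainder is spread over the other classes, which leaves the
#' argmax unchanged). For the SVM, the predicted class is the argmax of the
#' one-versus-rest decision values with deterministic tie-breaking.
#'
#' @param object a `bci_model`.
#' @param x feature matrix with the training layout.
#' @param ... unused.
#' @return list with `labels` (factor) and `scores` (samples x classes
#'   matrix, columns named by class).
#' @export
predict.bci_model <- function(object, x, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (ncol(x) != length(object$layout)) {
    stop("feature length ", ncol(x), " does not match training layout (",
         length(object$layout), ")")
  }
  lv <- object$levels
  scores <- switch(
    object$spec$algorithm,
    rf = predict(object$fit, x, type = "prob")[, lv, drop = FALSE],
    knn = {
      pr <- with_seed(object$spec$seed,
                      class::knn(object$fit$x, x, object$fit$y,
                                 k = object$fit$k, prob = TRUE))
      share <- attr(pr, "prob")
      m <- matrix((1 - share) / max(length(lv) - 1, 1), nrow(x), length(lv),
                  dimnames = list(NULL, lv))
      m[cbind(seq_len(nrow(x)), match(as.character(pr), lv))] <- share
      m
    },
    svm = {
      m <- vapply(object$fit, function(f) {
        dv <- attr(predict(f, x, decision.values = TRUE), "decision.values")
        # decision value signed toward the first level ("pos")
        if (colnames(dv)[1] == "pos/neg") dv[, 1] else -dv[, 1]
      }, numeric(nrow(x)))
      m <- matrix(m, nrow = nrow(x), dimnames = list(NULL, lv))
      m
    },
    nb = predict(object$fit, x, type = "raw")[, lv, drop = FALSE],
    lr = {
      p <- predict(object$fit, newx = x, type = "response")
      if (length(lv) == 2) {
        cbind(1 - p[, 1], p[, 1])
      } else {
        p[, , 1]
      }
    },
    dt = {
      df <- as.data.frame(x)
      colnames(df) <- object$layout
      predict(object$fit, df, type = "prob")[, lv, drop = FALSE]
    })
  scores <- matrix(as.numeric(scores), nrow = nrow(x),
                   dimnames = list(NULL, lv))
  # argmax with deterministic tie-break: class frequency, then fixed order
  pick <- apply(scores, 1, function(s) {
    cand <- which(s == max(s))
    if (length(cand) > 1) {
      cand <- cand[order(-object$class_freq[cand], cand)]
    }
    cand[1]
  })
  list(labels = factor(lv[pick], levels = lv), scores = scores)
}

#' Classification metrics from predictions
#'
#' Builds the confusion matrix (rows = truth, columns = predicted) and the
#' accuracy plus macro-averaged precision, recall and F1 over the classes.
#' Per-class precision/recall with an empty denominator counts as 0.
#'
#' @param predicted predicted labels.
#' @param truth true labels.
#' @param levels optional class order.
#' @return object of class `eval_report`: `accuracy`, `precision`, `recall`,
#'   `f1` (macro), `per_class` data.frame and `confusion` matrix.
#' @export
classification_metrics <- function(predicted, truth, levels = NULL) {
  lv <- levels %||% sort(unique(c(as.character(truth), as.character(predicted))))
  truth <- factor(truth, levels = lv)
  predicted <- factor(predicted, levels = lv)
  conf <- table(truth = truth, predicted = predicted)
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  rec <- ifelse(rowSums(conf) > 0, tp / rowSums(conf), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(accuracy = sum(tp) / sum(conf),
                 precision = mean(prec), recall = mean(rec), f1 = mean(f1),
                 per_class = data.frame(class = lv, precision = as.numeric(prec),
                                        recall = as.numeric(rec),
                                        f1 = as.numeric(f1),
                                        support = as.numeric(rowSums(conf))),
                 confusion = unclass(conf)),
            class = "eval_report")
}

#' Evaluate a trained model on held-out data
#'
#' @param model a `bci_model`.
#' @param x test feature matrix.
#' @param y test labels.
#' @return an `eval_report` (see [classification_metrics()]).
#' @export
evaluate_model <- function(model, x, y) {
  stopifnot(nrow(x) > 0, nrow(x) == length(y))
  pred <- predict(model, x)
  classification_metrics(pred$labels, factor(y, levels = model$levels),
                         levels = model$levels)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro precision %.4f recall %.4f F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `eval_report`.
#' @param path optional output file.
#' @return JSON string (invisibly if written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(accuracy = report$accuracy, precision = report$precision,
              recall = report$recall, f1 = report$f1,
              per_class = report$per_class,
              confusion = as.matrix(report$confusion))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
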