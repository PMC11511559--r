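make_clusters <- function(n_per_class = 25, sigma = 0.1, dist = 5,
                          seed = 51) {
  set.seed(seed)
  centers <- dist * rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  x <- do.call(rbind, lapply(1:4, function(k) {
    cbind(rnorm(n_per_class, centers[k, 1], sigma),
          rnorm(n_per_class, centers[k, 2], sigma))
  }))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = rep(c("A", "B", "C", "D"), each = n_per_class))
}

test_that("stratified split preserves class proportions and partitions", {
  d <- make_clusters(25)
  sp <- split_dataset(d$x, d$y, 0.8, seed = 1)
  expect_equal(as.numeric(table(sp$train$y)), rep(20, 4))
  expect_equal(as.numeric(table(sp$test$y)), rep(5, 4))
  expect_length(intersect(sp$train$idx, sp$test$idx), 0)
  expect_setequal(c(sp$train$idx, sp$test$idx), seq_len(100))

  sp2 <- split_dataset(d$x, d$y, 0.8, seed = 1)
  expect_identical(sp$train$idx, sp2$train$idx)
  sp3 <- split_dataset(d$x, d$y, 0.8, seed = 2)
  expect_false(identical(sp$train$idx, sp3$train$idx))

  expect_error(split_dataset(d$x[1:26, ], c(rep("A", 25), "B"), 0.8, 1),
               "'B'")
})

test_that("all six classifiers separate well-separated Gaussian clusters", {
  d <- make_clusters(50, sigma = 0.1, dist = 5)
  sp <- split_dataset(d$x, d$y, 0.8, seed = 2)
  for (alg in c("rf", "knn", "svm", "nb", "lr", "dt")) {
    model <- train_model(sp$train$x, sp$train$y, model_spec(alg, seed = 3))
    rep_ <- evaluate_model(model, sp$test$x, sp$test$y)
    expect_gte(rep_$accuracy, 0.99)
  }
})

test_that("label-permuted training yields chance-level accuracy", {
  d <- make_clusters(100, sigma = 0.1, dist = 5, seed = 52)
  set.seed(53)
  y_perm <- sample(d$y)
  sp <- split_dataset(d$x, y_perm, 0.8, seed = 4)
  model <- train_model(sp$train$x, sp$train$y, model_spec("lr", seed = 4))
  rep_ <- evaluate_model(model, sp$test$x, sp$test$y)
  expect_gt(rep_$accuracy, 0.25 - 0.1)
  expect_lt(rep_$accuracy, 0.25 + 0.1)
})

test_that("degenerate training inputs error", {
  d <- make_clusters(10)
  one <- d$y == "A"
  expect_error(train_model(d$x[one, ], d$y[one], model_spec("lr")),
               "single class")
  xb <- d$x; xb[1, 1] <- NA
  expect_error(train_model(xb, d$y, model_spec("lr")), "finite")
})

test_that("metrics match the counting oracle on known prediction sets", {
  lv <- c("A", "B", "C", "D")
  truth <- rep(lv, each = 5)
  r <- classification_metrics(truth, truth, lv)
  expect_equal(r$accuracy, 1)
  expect_true(all(diag(r$confusion) == 5))
  expect_equal(sum(r$confusion) - sum(diag(r$confusion)), 0)

  allA <- rep("A", 20)
  r2 <- classification_metrics(allA, truth, lv)
  expect_equal(r2$accuracy, 0.25)
  expect_equal(r2$per_class$recall, c(1, 0, 0, 0))
  expect_equal(r2$per_class$precision[1], 0.25)

  set.seed(54)
  for (i in 1:20) {
    pred <- sample(lv, 40, replace = TRUE)
    tr <- sample(lv, 40, replace = TRUE)
    got <- classification_metrics(pred, tr, lv)
    want <- oracle_metrics(pred, tr, lv)
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(got$f1, want$f1)
    expect_equal(unclass(got$confusion), want$confusion,
                 ignore_attr = TRUE)
  }
})

test_that("confusion row sums equal per-class test counts", {
  d <- make_clusters(30, sigma = 2, dist = 3, seed = 55)
  sp <- split_dataset(d$x, d$y, 0.8, seed = 5)
  model <- train_model(sp$train$x, sp$train$y, model_spec("dt", seed = 5))
  rep_ <- evaluate_model(model, sp$test$x, sp$test$y)
  expect_equal(as.numeric(rowSums(rep_$confusion)),
               as.numeric(table(factor(sp$test$y, levels = model$levels))))
  expect_equal(rep_$accuracy,
               sum(diag(rep_$confusion)) / sum(rep_$confusion))
})

test_that("prediction rejects layout mismatches and reports scores", {
  d <- make_clusters(20, seed = 56)
  sp <- split_dataset(d$x, d$y, 0.8, seed = 6)
  model <- train_model(sp$train$x, sp$train$y, model_spec("svm", seed = 6))
  expect_error(predict(model, sp$test$x[, 1, drop = FALSE]), "layout")
  pred <- predict(model, sp$test$x)
  expect_equal(dim(pred$scores), c(nrow(sp$test$x), 4L))
  expect_equal(colnames(pred$scores), model$levels)
  # argmax of scores agrees with the reported labels
  expect_equal(as.character(pred$labels),
               model$levels[apply(pred$scores, 1, which.max)])
})

test_that("evaluation report serializes to JSON", {
  d <- make_clusters(10, seed = 57)
  sp <- split_dataset(d$x, d$y, 0.8, seed = 7)
  model <- train_model(sp$train$x, sp$train$y, model_spec("nb"))
  rep_ <- evaluate_model(model, sp$test$x, sp$test$y)
  js <- jsonlite::fromJSON(report_to_json(rep_))
  expect_equal(js$accuracy, rep_$accuracy)
  expect_equal(dim(js$confusion), c(4L, 4L))
})
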