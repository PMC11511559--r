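# Independent brute-force oracles, written as literal transcriptions of the
# defining formulas (plain double loops, no shared code with the package
# internals).

oracle_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    total <- 0
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt)) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) cnt <- cnt + 1
      }
      total <- total + log(cnt / nt)
    }
    total / nt
  }
  phi(m) - phi(m + 1)
}

oracle_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (B == 0) return(NaN)
  if (A == 0) return(Inf)
  -log(A / B)
}

oracle_perm_entropy <- function(x, m, delay) {
  nw <- length(x) - (m - 1) * delay
  pats <- character(nw)
  for (t in seq_len(nw)) {
    w <- x[t + (0:(m - 1)) * delay]
    # ties by temporal order of appearance = stable ordering
    pats[t] <- paste(order(w), collapse = ",")
  }
  p <- table(pats) / nw
  -sum(p * log(p))
}

oracle_moments <- function(x) {
  n <- length(x)
  xb <- sum(x) / n
  sig <- sqrt(sum((x - xb)^2) / n)
  list(skewness = sum(((x - xb) / sig)^3) / n,
       kurtosis = sum(((x - xb) / sig)^4) / n - 3,
       variance = sum((x - xb)^2) / (n - 1),
       sd = sqrt(sum((x - xb)^2) / (n - 1)))
}

# Confusion-matrix metrics by direct tallying.
oracle_metrics <- function(predicted, truth, lv) {
  conf <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(truth)) {
    conf[truth[i], predicted[i]] <- conf[truth[i], predicted[i]] + 1
  }
  prec <- rec <- f1 <- numeric(length(lv))
  for (k in seq_along(lv)) {
    tp <- conf[k, k]
    prec[k] <- if (sum(conf[, k]) > 0) tp / sum(conf[, k]) else 0
    rec[k] <- if (sum(conf[k, ]) > 0) tp / sum(conf[k, ]) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  list(accuracy = sum(diag(conf)) / sum(conf), precision = mean(prec),
       recall = mean(rec), f1 = mean(f1), confusion = conf)
}

random_epoch <- function(nc = 4, n = 500, fs = 250, label = "REST",
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  new_epoch(matrix(rnorm(nc * n), nc, n),
            fs = fs, label = label,
            channel_labels = paste0("ch", seq_len(nc)))
}
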