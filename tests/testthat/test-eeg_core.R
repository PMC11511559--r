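test_that("delimited format round-trips data, fs and labels", {
  set.seed(11)
  rec <- new_recording(matrix(rnorm(3 * 40), 3, 40), fs = 250,
                       channel_labels = c("C3", "Cz", "C4"),
                       events = events_table(sample = c(0L, 10L),
                                             kind = "MI_CUE",
                                             mi_class = c("LEFT", "REST")))
  path <- tempfile(fileext = ".tsv")
  write_recording(rec, path, "delimited")
  back <- read_recording(path, "delimited")
  expect_equal(back$fs, 250)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_equal(back$data, rec$data, tolerance = 1e-8)
  expect_equal(back$events$mi_class, c("LEFT", "REST"))
})

test_that("delimited reader echoes a small file and rejects malformed ones", {
  path <- tempfile()
  writeLines(c("#fs=100", "#labels=A,B",
               "1\t2\t3\t4", "5\t6\t7\t8"), path)
  rec <- read_recording(path, "delimited")
  expect_equal(dim(rec$data), c(2L, 4L))
  expect_equal(rec$fs, 100)
  expect_equal(unname(rec$data[2, 3]), 7)

  writeLines(c("#fs=100", "#labels=A,B,C",
               "1\t2", "3\t4"), path)
  expect_error(read_recording(path, "delimited"), "format error")

  writeLines(c("#fs=100", "#labels=A,B",
               "1\tx", "3\t4"), path)
  expect_error(read_recording(path, "delimited"), "non-numeric")
})

test_that("EDF round-trip preserves the signal to 16-bit precision", {
  set.seed(12)
  data <- matrix(rnorm(2 * 500, sd = 40), 2, 500)
  rec <- new_recording(data, fs = 100, channel_labels = c("Fz", "Pz"))
  path <- tempfile(fileext = ".edf")
  write_recording(rec, path, "edf")
  back <- read_recording(path, "edf")
  expect_identical(back$channel_labels, c("Fz", "Pz"))
  expect_equal(back$fs, 100)
  # quantization error bounded by the physical range / 2^16
  tol <- (max(data) - min(data)) / 65535
  expect_lt(max(abs(back$data[, 1:500] - data)), 2 * tol)
})

test_that("epoch length follows the floor rule across sampling rates", {
  for (fs in c(100, 240, 250, 1000)) {
    rec <- new_recording(matrix(0, 1, 2 * fs), fs, "Cz",
                         events_table(sample = 0L, kind = "MI_CUE",
                                      mi_class = "REST"))
    eps <- extract_epochs(rec, "MI_CUE", 0, 0.667)
    expect_equal(ncol(eps[[1]]$data), floor(0.667 * fs),
                 info = paste("fs =", fs))
  }
})

test_that("out-of-bounds epochs are dropped and counted", {
  fs <- 240
  rec <- new_recording(matrix(rnorm(2 * 300), 2, 300), fs, c("A", "B"),
                       events_table(sample = c(0L, 290L),
                                    kind = "INTENSIFICATION",
                                    rc_id = 1L, is_target = TRUE,
                                    char_index = 0L))
  eps <- extract_epochs(rec, "INTENSIFICATION", 0, 0.667)
  expect_length(eps, 1)
  expect_equal(attr(eps, "n_dropped"), 1L)
})

test_that("cue epochs inherit labels in event order", {
  rec <- new_recording(matrix(rnorm(1 * 300), 1, 300), 100, "Cz",
                       events_table(sample = c(0L, 100L, 200L),
                                    kind = "MI_CUE",
                                    mi_class = c("LEFT", "BOTH", "RIGHT")))
  eps <- extract_epochs(rec, "MI_CUE", 0, 1)
  expect_equal(vapply(eps, function(e) e$label, ""),
               c("LEFT", "BOTH", "RIGHT"))
  expect_length(extract_epochs(rec, "INTENSIFICATION", 0, 1), 0)
})

test_that("cleaning removes incomplete recordings and is idempotent", {
  ok <- new_recording(matrix(0, 2, 10), 100, c("Cz", "C3"))
  missing_ch <- new_recording(matrix(0, 1, 10), 100, "C3")
  with_nan <- new_recording(matrix(c(NaN, rep(0, 19)), 2, 10), 100,
                            c("Cz", "C3"))
  out <- clean_recordings(list(ok, missing_ch, with_nan), "Cz")
  expect_length(out, 1)
  expect_equal(attr(out, "removals")$index, c(2L, 3L))

  again <- clean_recordings(out, "Cz")
  expect_length(again, 1)
  expect_equal(again[[1]]$data, ok$data)

  all_ok <- clean_recordings(list(ok, ok), "Cz")
  expect_length(all_ok, 2)
  expect_equal(nrow(attr(all_ok, "removals")), 0)
})

test_that("recording invariants are enforced at construction", {
  expect_error(new_recording(matrix(0, 2, 5), 100, c("A", "A")), "unique")
  expect_error(new_recording(matrix(0, 2, 5), -1, c("A", "B")), "positive")
  expect_error(new_recording(matrix(0, 1, 5), 100, "A",
                             events_table(sample = 9L, kind = "MI_CUE",
                                          mi_class = "REST")),
               "within the recording")
  expect_error(new_recording(matrix(0, 1, 20), 100, "A",
                             events_table(sample = 0L, kind = "MI_CUE")),
               "mi_class")
})
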