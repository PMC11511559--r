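#' Run the full motor-imagery decoding chain
#'
#' End to end: epoch the recording at the cue events, apply the spatial
#' filters (CAR then small Laplacian by default), compute the per-channel
#' feature bank, drop flagged epochs, split 80/20 stratified, z-score on the
#' training statistics, train the requested classifier and evaluate on the
#' held-out 20%.
#'
#' @param recording a `bci_recording` with MI_CUE events.
#' @param montage electrode montage for the Laplacian (default: built-in
#'   10-10 sized to the recording).
#' @param trial_s epoch length in seconds.
#' @param spec a [model_spec()].
#' @param feature_cfg a [feature_config()].
#' @param car,laplacian,weighted spatial-filter settings (see
#'   [apply_spatial()]).
#' @param train_fraction train split fraction.
#' @param seed split seed.
#' @return list with `report` (an `eval_report`), `model`, `normalizer`,
#'   and `n_flagged`.
#' @export
run_mi_chain <- function(recording, montage = NULL, trial_s = 3.0,
                         spec = model_spec("lr"),
                         feature_cfg = feature_config(),
                         car = TRUE, laplacian = "small", weighted = FALSE,
                         train_fraction = 0.8, seed = 1L) {
  if (is.null(montage)) montage <- montage_1010(nrow(recording$data))
  epochs <- extract_epochs(recording, "MI_CUE", 0, trial_s)
  epochs <- lapply(epochs, apply_spatial, montage = montage, car = car,
                   laplacian = laplacian, weighted = weighted)
  feats <- featurize_epochs(epochs, feature_cfg)
  keep <- !feats$flagged
  x <- feats$x[keep, , drop = FALSE]
  y <- feats$labels[keep]
  sp <- split_dataset(x, y, train_fraction, seed)
  norm <- fit_normalizer(sp$train$x)
  model <- train_model(apply_normalizer(sp$train$x, norm), sp$train$y, spec)
  report <- evaluate_model(model, apply_normalizer(sp$test$x, norm),
                           sp$test$y)
  list(report = report, model = model, normalizer = norm,
       n_flagged = sum(!keep))
}

#' Run the full P300 speller chain
#'
#' Trains the phase-1 target/nontarget classifier on one session and decodes
#' another: both sessions are preprocessed with the standard chain (0-667 ms
#' epochs, Chebyshev type-I 0.1-10 Hz order 8, decimation by the upper
#' cutoff, channel-major assembly), then each character of the test session
#' is decoded by row/column score summation.
#'
#' @param train_rec training-session `bci_recording`.
#' @param test_rec test-session `bci_recording`.
#' @param spec phase-1 classifier spec (default random forest).
#' @param layout a [speller_layout()].
#' @param repetitions decode with only the first r repetitions (default all).
#' @return list with `decoded` (string), `model`, and the test `prep`.
#' @export
run_p300_chain <- function(train_rec, test_rec, spec = model_spec("rf"),
                           layout = speller_layout(), repetitions = NULL) {
  train_prep <- p300_preprocess(train_rec)
  model <- p300_train(train_prep, spec)
  test_prep <- p300_preprocess(test_rec)
  decoded <- p300_decode_session(model, test_prep, layout, repetitions)
  list(decoded = decoded, model = model, prep = test_prep)
}
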