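#' 6x6 speller layout
#'
#' The standard matrix-speller grid: 36 symbols (A-Z, 1-9, underscore) in six
#' rows and six columns. Intensification ids 1-6 denote columns 1-6 and ids
#' 7-12 denote rows 1-6, so every symbol is covered by exactly one row id and
#' one column id.
#'
#' @param symbols 36 unique single characters, filled row-major.
#' @return object of class `speller_layout`.
#' @export
speller_layout <- function(symbols = c(LETTERS, as.character(1:9), "_")) {
  stopifnot(length(symbols) == 36, !anyDuplicated(symbols))
  structure(list(matrix = matrix(symbols, 6, 6, byrow = TRUE)),
            class = "speller_layout")
}

#' Row/column ids of a symbol
#'
#' @param layout a [speller_layout()].
#' @param symbol a single character present in the layout.
#' @return integer vector `c(row_id, col_id)` with row ids in 7-12 and
#'   column ids in 1-6.
#' @export
symbol_rc <- function(layout, symbol) {
  pos <- which(layout$matrix == symbol, arr.ind = TRUE)
  if (nrow(pos) == 0) stop("symbol not in layout: ", symbol)
  c(row_id = unname(pos[1, "row"]) + 6L, col_id = unname(pos[1, "col"]))
}

#' Symbol at a row/column id pair
#'
#' @param layout a [speller_layout()].
#' @param row_id id in 7-12.
#' @param col_id id in 1-6.
#' @return the symbol character.
#' @export
symbol_at <- function(layout, row_id, col_id) {
  stopifnot(row_id %in% 7:12, col_id %in% 1:6)
  layout$matrix[row_id - 6L, col_id]
}

#' Post-stimulus epoching for the speller
#'
#' Extracts one epoch per intensification over the window 0 to 667 ms after
#' the stimulus (160 samples at 240 Hz), labeled target/nontarget.
#'
#' @param rec a `bci_recording` with INTENSIFICATION events.
#' @param window_s window end in seconds (default 0.667).
#' @return list of `bci_epoch` (see [extract_epochs()]).
#' @export
p300_epoch <- function(rec, window_s = 0.667) {
  extract_epochs(rec, "INTENSIFICATION", 0, window_s)
}

# Chebyshev type-I bandpass in zero-pole-gain form, paired into
# second-order sections. Design path mirrors signal::cheby1 (analog
# prototype -> sftrans -> bilinear) but keeps zpk to stay numerically
# stable at narrow low-frequency bands where the expanded transfer
# function has poles outside the unit circle.
design_cheby1_sos <- function(fs, order = 8, band = c(0.1, 10), ripple = 0.5) {
  stopifnot(fs > 2 * band[2])
  W <- band / (fs / 2)
  T <- 2
  Wp <- 2 / T * tan(pi * W / T)
  eps <- sqrt(10^(ripple / 10) - 1)
  v0 <- asinh(1 / eps) / order
  pole <- exp(1i * pi * seq(-(order - 1), order - 1, by = 2) / (2 * order))
  pole <- -sinh(v0) * Re(pole) + 1i * cosh(v0) * Im(pole)
  gain <- prod(-pole)
  if (order %% 2 == 0) gain <- gain / 10^(ripple / 20)
  zpg <- signal::Zpg(zero = numeric(0), pole = pole, gain = gain)
  zpg <- signal::sftrans(zpg, W = Wp, stop = FALSE)
  zpg <- signal::bilinear(zpg, T = T)
  if (max(Mod(zpg$pole)) >= 1) {
    stop("unstable filter design at fs = ", fs,
         "; adjust the band or sampling rate")
  }
  zpk_to_sos(zpg)
}

# Pair conjugate poles (closest to the unit circle first) with their nearest
# zeros; overall gain folded into the first section.
zpk_to_sos <- function(zpg) {
  p <- zpg$pole
  z <- zpg$zero
  used <- rep(FALSE, length(p))
  pairs <- list()
  for (i in order(-Mod(p))) {
    if (used[i]) next
    used[i] <- TRUE
    j <- which(!used & abs(p - Conj(p[i])) < 1e-8)[1]
    if (is.na(j)) stop("unpaired complex pole in SOS conversion")
    used[j] <- TRUE
    pairs[[length(pairs) + 1]] <- c(p[i], p[j])
  }
  zused <- rep(FALSE, length(z))
  sos <- matrix(0, length(pairs), 6)
  for (k in seq_along(pairs)) {
    pp <- pairs[[k]]
    zz <- complex(2)
    for (t in 1:2) {
      d <- Mod(z - pp[t])
      d[zused] <- Inf
      j <- which.min(d)
      zused[j] <- TRUE
      zz[t] <- z[j]
    }
    sos[k, ] <- c(Re(c(1, -(zz[1] + zz[2]), zz[1] * zz[2])),
                  Re(c(1, -(pp[1] + pp[2]), pp[1] * pp[2])))
  }
  sos[1, 1:3] <- sos[1, 1:3] * Re(zpg$gain)
  sos
}

#' Chebyshev type-I band-pass filtering
#'
#' Filters every channel of the epoch with an order-8 Chebyshev type-I
#' band-pass (0.1-10 Hz by default, 0.5 dB passband ripple), applied
#' causally (forward only, matching an online-capable chain) as a cascade of
#' second-order sections for numerical stability. Shape and sampling rate
#' are preserved.
#'
#' @param epoch a `bci_epoch`.
#' @param order filter order.
#' @param band `c(lo, hi)` cutoff frequencies in Hz.
#' @param ripple passband ripple in dB.
#' @return filtered `bci_epoch`.
#' @export
bandpass_cheby1 <- function(epoch, order = 8, band = c(0.1, 10),
                            ripple = 0.5) {
  stopifnot(inherits(epoch, "bci_epoch"))
  sos <- design_cheby1_sos(epoch$fs, order, band, ripple)
  for (i in seq_len(nrow(epoch$data))) {
    epoch$data[i, ] <- .sosfilt_cpp(sos, epoch$data[i, ])
  }
  epoch
}

#' Decimate a band-limited epoch
#'
#' Keeps every k-th sample starting at index 0, with `k = floor(fs / (2 *
#' f_high))` derived from the band-pass upper cutoff; the preceding
#' Chebyshev filter provides the anti-aliasing, so no extra filtering is
#' applied here. A 160-sample epoch at 240 Hz with a 10 Hz cutoff gives
#' k = 12 and 14 retained samples.
#'
#' @param epoch a `bci_epoch` already band-limited below `f_high`.
#' @param f_high upper cutoff in Hz.
#' @return decimated `bci_epoch` with `fs / k` sampling rate and
#'   `ceil(n / k)` samples.
#' @export
decimate_epoch <- function(epoch, f_high = 10) {
  stopifnot(inherits(epoch, "bci_epoch"))
  k <- as.integer(floor(epoch$fs / (2 * f_high)))
  if (k < 1) stop("decimation factor < 1 at fs = ", epoch$fs)
  idx <- seq(1L, ncol(epoch$data), by = k)
  epoch$data <- epoch$data[, idx, drop = FALSE]
  epoch$fs <- epoch$fs / k
  epoch
}

#' Assemble the post-stimulus feature vector
#'
#' Channel-major concatenation of the decimated epoch: all samples of
#' channel 1, then channel 2, and so on. 64 channels of 14 samples give the
#' reference 896-dimensional vector.
#'
#' @param epoch a decimated `bci_epoch`.
#' @return numeric vector with attributes `label`, `rc_id`, `char_index`.
#' @export
assemble_vector <- function(epoch) {
  v <- as.vector(t(epoch$data))
  attr(v, "label") <- epoch$label
  attr(v, "rc_id") <- epoch$rc_id
  attr(v, "char_index") <- epoch$char_index
  v
}

#' Preprocess a speller session into post-stimulus vectors
#'
#' Runs the full per-intensification chain (epoch 0-667 ms, Chebyshev
#' band-pass, decimation, channel-major assembly) over every
#' INTENSIFICATION event, streaming one epoch at a time.
#'
#' @param rec a `bci_recording` with INTENSIFICATION events.
#' @param window_s post-stimulus window in seconds.
#' @param order,band,ripple band-pass parameters (see [bandpass_cheby1()]).
#' @return list: `x` (vectors x dims matrix), `label`, `rc_id`,
#'   `char_index`, `repetition` (1-based count of each rc_id within its
#'   character).
#' @export
p300_preprocess <- function(rec, window_s = 0.667, order = 8,
                            band = c(0.1, 10), ripple = 0.5) {
  ev <- rec$events[rec$events$kind == "INTENSIFICATION", , drop = FALSE]
  if (nrow(ev) == 0) stop("recording has no INTENSIFICATION events")
  sos <- design_cheby1_sos(rec$fs, order, band, ripple)
  n_ep <- as.integer(floor(window_s * rec$fs))
  k <- as.integer(floor(rec$fs / (2 * band[2])))
  keep <- seq(1L, n_ep, by = k)
  dim_out <- nrow(rec$data) * length(keep)
  ok <- ev$sample + n_ep <= ncol(rec$data)
  ev <- ev[ok, , drop = FALSE]
  x <- matrix(0, nrow(ev), dim_out)
  for (e in seq_len(nrow(ev))) {
    sl <- (ev$sample[e] + 1L):(ev$sample[e] + n_ep)
    seg <- rec$data[, sl, drop = FALSE]
    for (i in seq_len(nrow(seg))) {
      seg[i, ] <- .sosfilt_cpp(sos, seg[i, ])
    }
    x[e, ] <- as.vector(t(seg[, keep, drop = FALSE]))
  }
  rep_idx <- stats::ave(seq_len(nrow(ev)),
                        ev$char_index, ev$rc_id, FUN = seq_along)
  list(x = x,
       label = ifelse(ev$is_target, "target", "nontarget"),
       rc_id = ev$rc_id, char_index = ev$char_index,
       repetition = as.integer(rep_idx),
       n_dropped = sum(!ok))
}

#' Train the phase-1 (P300 / non-P300) classifier
#'
#' Binary classification of post-stimulus vectors; the default classifier is
#' a random forest, with the full classifier menu of [model_spec()]
#' available.
#'
#' @param prep output of [p300_preprocess()] for a training session.
#' @param spec a [model_spec()].
#' @return a `bci_model` whose positive class is `"target"`.
#' @export
p300_train <- function(prep, spec = model_spec("rf")) {
  train_model(prep$x, prep$label, spec)
}

#' Score post-stimulus vectors for P300 likelihood
#'
#' Returns a monotone score (higher = more P300-like): the model's score for
#' the `"target"` class.
#'
#' @param model a binary `bci_model` from [p300_train()].
#' @param x matrix of post-stimulus vectors.
#' @return numeric score vector.
#' @export
score_p300 <- function(model, x) {
  predict(model, x)$scores[, "target"]
}

#' Decode one symbol from intensification scores
#'
#' Phase 2 of the speller: sums the scores of each of the 12 row/column ids
#' over repetitions, picks the best row id (7-12) and the best column id
#' (1-6), and returns the symbol at their intersection. Ties are broken by
#' the lowest rc_id.
#'
#' @param rc_id intensification ids (must cover all of 1-12).
#' @param score one score per intensification.
#' @param layout a [speller_layout()].
#' @return single decoded symbol.
#' @export
decode_symbol <- function(rc_id, score, layout = speller_layout()) {
  if (!all(1:12 %in% rc_id)) {
    stop("scores must cover all 12 row/column ids; missing: ",
         paste(setdiff(1:12, rc_id), collapse = ","))
  }
  tot <- vapply(1:12, function(id) sum(score[rc_id == id]), 0)
  col_id <- which.max(tot[1:6])              # ties: which.max takes lowest
  row_id <- 6L + which.max(tot[7:12])
  symbol_at(layout, row_id, col_id)
}

#' Decode a whole session into text
#'
#' Scores every post-stimulus vector with the phase-1 model and decodes each
#' character by row/column score summation, optionally truncating to the
#' first `repetitions` repetitions of each id.
#'
#' @param model phase-1 `bci_model`.
#' @param prep output of [p300_preprocess()].
#' @param layout a [speller_layout()].
#' @param repetitions use only the first r repetitions (default all).
#' @return decoded string, one symbol per character index.
#' @export
p300_decode_session <- function(model, prep, layout = speller_layout(),
                                repetitions = NULL) {
  score <- score_p300(model, prep$x)
  keep <- if (is.null(repetitions)) rep(TRUE, length(score)) else
    prep$repetition <= repetitions
  chars <- sort(unique(prep$char_index))
  out <- vapply(chars, function(ci) {
    sel <- keep & prep$char_index == ci
    decode_symbol(prep$rc_id[sel], score[sel], layout)
  }, "")
  paste(out, collapse = "")
}
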