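#' Feature-bank configuration
#'
#' Parameters of the per-channel motor-imagery feature bank. Defaults follow
#' the conventions standard for sensorimotor EEG: mu band 8-12 Hz, beta band
#' 13-30 Hz, AR order 4, entropy template length m = 2 with tolerance
#' r = 0.2 x channel standard deviation, ordinal patterns of order 3 at
#' delay 1, Higuchi kmax 10, Welch segments of 1 s with 50% overlap.
#'
#' @param mu_band,beta_band frequency intervals in Hz.
#' @param ar_order autoregressive model order p.
#' @param entropy_m template length for approximate/sample entropy.
#' @param entropy_r_scale tolerance as a multiple of the channel sd.
#' @param perm_order,perm_delay ordinal-pattern order and delay.
#' @param higuchi_kmax maximum curve-length scale.
#' @param welch_segment_s,welch_overlap Welch segment length (s) and overlap
#'   fraction.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(mu_band = c(8, 12), beta_band = c(13, 30),
                           ar_order = 4, entropy_m = 2,
                           entropy_r_scale = 0.2, perm_order = 3,
                           perm_delay = 1, higuchi_kmax = 10,
                           welch_segment_s = 1.0, welch_overlap = 0.5) {
  stopifnot(ar_order >= 1, entropy_r_scale > 0, perm_order >= 2,
            mu_band[1] > 0, beta_band[1] > 0,
            diff(mu_band) > 0, diff(beta_band) > 0)
  structure(list(mu_band = mu_band, beta_band = beta_band,
                 ar_order = ar_order, entropy_m = entropy_m,
                 entropy_r_scale = entropy_r_scale, perm_order = perm_order,
                 perm_delay = perm_delay, higuchi_kmax = higuchi_kmax,
                 welch_segment_s = welch_segment_s,
                 welch_overlap = welch_overlap),
            class = "feature_config")
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-windowed segments with the given
#' overlap, segment means removed, one-sided density in signal-units^2 / Hz.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param segment_s segment length in seconds.
#' @param overlap overlap fraction in `[0, 1)`.
#' @return list with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, segment_s = 1.0, overlap = 0.5) {
  L <- as.integer(round(segment_s * fs))
  n <- length(x)
  if (n < L) stop("signal shorter than one Welch segment (", L, " samples)")
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))  # Hann
  u <- sum(w^2)
  nf <- L %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nf)]
    acc <- acc + (Mod(X)^2) / (fs * u)
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when L is even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (L %% 2 == 0) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1) * fs / L, psd = psd * dbl)
}

#' Band power from the Welch PSD
#'
#' Integrates the one-sided Welch density over the frequency bins whose
#' centers fall inside `band`, by the trapezoidal rule. Nonnegative by
#' construction.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param band `c(lo, hi)` in Hz, inside `(0, fs/2)`.
#' @param cfg a [feature_config()] (Welch parameters).
#' @return scalar band power (signal-units^2).
#' @export
band_power_welch <- function(x, fs, band, cfg = feature_config()) {
  if (band[1] <= 0 || band[2] > fs / 2 || band[2] <= band[1]) {
    stop("band must lie inside (0, fs/2)")
  }
  p <- welch_psd(x, fs, cfg$welch_segment_s, cfg$welch_overlap)
  sel <- which(p$freq >= band[1] & p$freq <= band[2])
  if (length(sel) < 2) {
    stop("band narrower than the Welch frequency resolution")
  }
  sum(diff(p$freq[sel]) * (head(p$psd[sel], -1) + tail(p$psd[sel], -1)) / 2)
}

#' Hjorth parameters
#'
#' Activity is the signal variance (N-1 denominator); mobility the square
#' root of the variance ratio of the first difference to the signal;
#' complexity the mobility ratio of the first difference to the signal.
#' The derivative is the per-sample first difference (no fs scaling), so a
#' sinusoid of frequency f has mobility close to `2*pi*f/fs`. A constant
#' signal has activity 0 and undefined (NA) mobility/complexity, flagged
#' with a warning.
#'
#' @param x numeric signal, length >= 3.
#' @return named vector `c(activity, mobility, complexity)`.
#' @export
hjorth_params <- function(x) {
  stopifnot(length(x) >= 3)
  v0 <- var(x)
  if (v0 < .Machine$double.eps) {
    warning("constant signal: Hjorth mobility/complexity undefined")
    return(c(activity = 0, mobility = NA_real_, complexity = NA_real_))
  }
  d1 <- diff(x)
  d2 <- diff(d1)
  v1 <- var(d1); v2 <- var(d2)
  mob <- sqrt(v1 / v0)
  if (v1 < .Machine$double.eps) {
    warning("degenerate first difference: Hjorth complexity undefined")
    return(c(activity = v0, mobility = mob, complexity = NA_real_))
  }
  c(activity = v0, mobility = mob, complexity = sqrt(v2 / v1) / mob)
}

#' Autoregressive coefficients (Burg method)
#'
#' Fits `x(t) = sum_i phi_i x(t-i) + e(t)` of order `p` by Burg's method
#' (no windowing loss, the standard choice for short EEG segments) and
#' returns `phi_1..phi_p` in lag order. A Yule-Walker estimator is available
#' for cross-checks.
#'
#' @param x numeric signal, length > 3p, non-constant.
#' @param p model order.
#' @param method `"burg"` (default) or `"yule-walker"`.
#' @return numeric vector of length `p`.
#' @export
ar_coefficients <- function(x, p = 4, method = c("burg", "yule-walker")) {
  method <- match.arg(method)
  if (length(x) <= 3 * p) stop("signal too short for AR order ", p)
  if (var(x) < .Machine$double.eps) stop("constant signal: AR fit undefined")
  fit <- if (method == "burg") {
    ar.burg(x, aic = FALSE, order.max = p, demean = TRUE)
  } else {
    stats::ar.yw(x, aic = FALSE, order.max = p, demean = TRUE)
  }
  as.numeric(fit$ar)
}

#' Higuchi fractal dimension
#'
#' Estimates the box-counting dimension of the signal graph by Higuchi's
#' curve-length method: mean normalized curve length L(k) over scales
#' k = 1..kmax, slope of log L(k) against log(1/k). Values are reported
#' clipped to `[1, 2]` (with a warning) since that is the valid range for a
#' planar curve. Smooth signals approach 1, white noise approaches 2.
#'
#' @param x numeric signal, length >= 10 * kmax.
#' @param kmax maximum scale (default 10).
#' @return scalar in `[1, 2]`.
#' @export
fractal_dimension <- function(x, kmax = 10) {
  if (length(x) < 10 * kmax) {
    stop("signal too short for Higuchi kmax = ", kmax)
  }
  fd <- .higuchi_cpp(as.numeric(x), as.integer(kmax))
  if (!is.finite(fd)) {
    warning("Higuchi estimate undefined (degenerate signal)")
    return(NA_real_)
  }
  if (fd < 1 || fd > 2) {
    warning(sprintf("Higuchi estimate %.3f outside [1, 2]; clipped", fd))
    fd <- min(max(fd, 1), 2)
  }
  fd
}

#' Approximate entropy
#'
#' ApEn(m, r) in the standard Pincus formulation phi^m(r) - phi^(m+1)(r)
#' with Chebyshev template distance and self-matches included. Regular
#' signals score near 0; irregular signals score higher.
#'
#' @param x numeric signal, length > m + 1.
#' @param m template length.
#' @param r_abs absolute tolerance (same units as `x`).
#' @return nonnegative scalar.
#' @export
approximate_entropy <- function(x, m = 2, r_abs) {
  stopifnot(length(x) > m + 1, r_abs > 0)
  .apen_cpp(as.numeric(x), as.integer(m), r_abs)
}

#' Sample entropy
#'
#' SampEn(m, r) = -log(A/B) where B counts pairs of length-m templates
#' within Chebyshev distance r (self-matches excluded) and A the pairs still
#' matching when extended to length m + 1. Returns `Inf` (with a warning)
#' when A = 0 and `NaN` when B = 0.
#'
#' @inheritParams approximate_entropy
#' @return nonnegative scalar, possibly `Inf`.
#' @export
sample_entropy <- function(x, m = 2, r_abs) {
  stopifnot(length(x) > m + 1, r_abs > 0)
  out <- .sampen_cpp(as.numeric(x), as.integer(m), r_abs)
  if (!is.finite(out)) {
    warning("sample entropy undefined (no template matches); sentinel returned")
  }
  out
}

#' Permutation entropy
#'
#' Shannon entropy (natural log) of the distribution of ordinal patterns of
#' order `m` at the given delay; ties are ranked by temporal order of
#' appearance. Ranges from 0 (monotonic signal) to log(m!) (all patterns
#' equally likely). `normalized = TRUE` divides by log(m!).
#'
#' @param x numeric signal, length >= m * delay + 1.
#' @param m ordinal-pattern order (>= 2).
#' @param delay embedding delay.
#' @param normalized divide by log(m!).
#' @return scalar in `[0, log(m!)]` (or `[0, 1]` if normalized).
#' @export
permutation_entropy <- function(x, m = 3, delay = 1, normalized = FALSE) {
  stopifnot(m >= 2, length(x) >= m * delay + 1)
  h <- .perm_entropy_cpp(as.numeric(x), as.integer(m), as.integer(delay))
  if (normalized) h <- h / log(factorial(m))
  h
}

#' Higher-order statistics
#'
#' Skewness and excess kurtosis use the biased (1/N) moments with the
#' population standard deviation; variance uses the N-1 denominator and the
#' standard deviation is its square root. For {-1, +1} this gives skewness
#' 0, excess kurtosis -2, variance 2 and sd sqrt(2). Zero-spread signals get
#' NA skewness/kurtosis with a warning.
#'
#' @param x numeric signal, length >= 2.
#' @return named vector `c(skewness, kurtosis, variance, sd)`, kurtosis
#'   being the excess kurtosis.
#' @export
higher_order_stats <- function(x) {
  stopifnot(length(x) >= 2)
  n <- length(x)
  m <- mean(x)
  v_pop <- sum((x - m)^2) / n
  v <- sum((x - m)^2) / (n - 1)
  if (v_pop < .Machine$double.eps) {
    warning("zero-variance signal: skewness/kurtosis undefined")
    return(c(skewness = NA_real_, kurtosis = NA_real_, variance = v,
             sd = sqrt(v)))
  }
  s_pop <- sqrt(v_pop)
  c(skewness = sum(((x - m) / s_pop)^3) / n,
    kurtosis = sum(((x - m) / s_pop)^4) / n - 3,
    variance = v, sd = sqrt(v))
}

feature_names <- function(p = 4) {
  c("mu_power", "beta_power", "activity", "mobility", "complexity",
    paste0("ar", seq_len(p)), "fractal_dim", "apen", "sampen", "perm_en",
    "skewness", "kurtosis", "variance", "sd")
}

#' Per-channel feature bank
#'
#' Computes, for every channel of the epoch and in fixed order: mu and beta
#' Welch band power, Hjorth activity/mobility/complexity, AR(p) coefficients
#' (Burg), Higuchi fractal dimension, approximate/sample/permutation
#' entropy, skewness, excess kurtosis, variance and standard deviation -
#' 17 features per channel at the default AR order 4, concatenated
#' channel-major. The entropy tolerance is `entropy_r_scale` times the
#' channel standard deviation. Any undefined feature propagates as `NA` and
#' the epoch is flagged (attribute `"flagged"`); flagged epochs are meant to
#' be excluded from classifier training, never imputed.
#'
#' @param epoch a `bci_epoch`.
#' @param cfg a [feature_config()].
#' @return named numeric vector of length `n_channels * (13 + ar_order)`,
#'   with attributes `"layout"` (data.frame channel/feature) and
#'   `"flagged"`.
#' @export
featurize_epoch <- function(epoch, cfg = feature_config()) {
  stopifnot(inherits(epoch, "bci_epoch"))
  fn <- feature_names(cfg$ar_order)
  nc <- nrow(epoch$data)
  out <- matrix(NA_real_, nc, length(fn))
  for (c_i in seq_len(nc)) {
    x <- epoch$data[c_i, ]
    s <- sd(x)
    hj <- suppressWarnings(hjorth_params(x))
    hos <- suppressWarnings(higher_order_stats(x))
    ar <- if (s > 0) ar_coefficients(x, cfg$ar_order) else rep(NA_real_, cfg$ar_order)
    ent <- if (s > 0) {
      .apen_sampen_cpp(x, as.integer(cfg$entropy_m), cfg$entropy_r_scale * s)
    } else c(NA_real_, NA_real_)
    out[c_i, ] <- c(
      band_power_welch(x, epoch$fs, cfg$mu_band, cfg),
      band_power_welch(x, epoch$fs, cfg$beta_band, cfg),
      hj, ar,
      suppressWarnings(fractal_dimension(x, cfg$higuchi_kmax)),
      ent,
      permutation_entropy(x, cfg$perm_order, cfg$perm_delay),
      hos)
  }
  layout <- data.frame(channel = rep(epoch$channel_labels, each = length(fn)),
                       feature = rep(fn, nc), stringsAsFactors = FALSE)
  v <- as.vector(t(out))
  v[!is.finite(v)] <- NA_real_
  names(v) <- paste(layout$channel, layout$feature, sep = ".")
  attr(v, "layout") <- layout
  attr(v, "flagged") <- anyNA(v)
  v
}

#' Featurize a list of epochs into a matrix
#'
#' @param epochs list of `bci_epoch`.
#' @param cfg a [feature_config()].
#' @return list with `x` (epochs x features matrix), `labels` (character),
#'   and `flagged` (logical; epochs with undefined features).
#' @export
featurize_epochs <- function(epochs, cfg = feature_config()) {
  stopifnot(length(epochs) > 0)
  rows <- lapply(epochs, featurize_epoch, cfg = cfg)
  x <- do.call(rbind, rows)
  list(x = x,
       labels = vapply(epochs, function(e) as.character(e$label), ""),
       flagged = vapply(rows, function(r) attr(r, "flagged"), TRUE))
}

#' Feature normalization (z-score on training statistics)
#'
#' `fit_normalizer` learns per-feature mean and standard deviation from the
#' training matrix; `apply_normalizer` standardizes any matrix with the same
#' layout using those training parameters only (test data must never
#' contribute to the statistics). Zero-spread features pass through
#' unscaled, with a warning.
#'
#' @param x numeric matrix, rows = epochs (>= 2), columns = features.
#' @return `fit_normalizer`: object of class `bci_normalizer`.
#' @export
fit_normalizer <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  if (any(s == 0)) {
    warning(sum(s == 0), " constant feature(s) left unscaled")
    s[s == 0] <- 1
  }
  structure(list(mean = mu, sd = s, layout = colnames(x)),
            class = "bci_normalizer")
}

#' @param norm a `bci_normalizer`.
#' @rdname fit_normalizer
#' @export
apply_normalizer <- function(x, norm) {
  stopifnot(inherits(norm, "bci_normalizer"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (!is.null(colnames(x)) && !is.null(norm$layout) &&
      !identical(colnames(x), norm$layout)) {
    stop("feature layout does not match the normalizer's training layout")
  }
  sweep(sweep(x, 2, norm$mean), 2, norm$sd, "/")
}
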