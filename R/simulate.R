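#' 1/f^alpha background noise
#'
#' Frequency-domain synthesis of Gaussian noise with a power-law spectrum,
#' the standard stand-in for EEG background activity. The complex spectrum
#' is scaled by `f^(-alpha/2)`, made Hermitian, inverse-transformed and
#' rescaled to the requested standard deviation.
#'
#' @param n number of samples.
#' @param alpha spectral exponent (1 = pink noise).
#' @param sd target standard deviation (microvolts).
#' @return numeric vector of length `n`.
#' @export
noise_oneoverf <- function(n, alpha = 1, sd = 1) {
  nfft <- stats::nextn(n, 2)
  nf <- nfft %/% 2
  f <- seq_len(nf)
  amp <- f^(-alpha / 2)
  spec <- complex(real = rnorm(nf), imaginary = rnorm(nf)) * amp
  full <- complex(nfft)
  full[2:(nf + 1)] <- spec
  full[seq(nfft, nf + 2)] <- Conj(spec[seq_len(nf - 1)])
  x <- Re(fft(full, inverse = TRUE))[seq_len(n)]
  x <- x - mean(x)
  x / stats::sd(x) * sd
}

#' Motor-imagery simulation configuration
#'
#' Generative model for four-class motor-imagery sessions: pink-noise
#' background on every channel plus mu (10 Hz) and beta (20 Hz) oscillations
#' over the two lateral motor clusters. Event-related desynchronization is
#' modeled as amplitude attenuation by `erd_depth` of the rhythm on the
#' cluster(s) engaged by the imagined movement: the left-hemisphere (C3)
#' cluster for right-hand imagery, the right-hemisphere (C4) cluster for
#' left-hand imagery, both for both-hands, neither at rest. Negative
#' `erd_depth` yields synchronization (power increase) instead.
#'
#' @param n_channels 62 (default) or 64, drawn from [montage_1010()].
#' @param fs sampling rate in Hz.
#' @param trial_s trial length in seconds.
#' @param erd_depth fractional amplitude attenuation in `[-1, 1]`.
#' @param mu_amp,beta_amp rhythm amplitudes in microvolts.
#' @param noise_alpha,noise_sd background-noise spectral exponent and
#'   standard deviation (microvolts).
#' @param left_cluster,right_cluster electrode labels carrying the rhythms.
#' @return list of class `mi_sim_config`.
#' @export
mi_sim_config <- function(n_channels = 62, fs = 250, trial_s = 3.0,
                          erd_depth = 0.5, mu_amp = 10, beta_amp = 5,
                          noise_alpha = 1, noise_sd = 10,
                          left_cluster = c("C3", "C5", "C1", "FC3", "CP3"),
                          right_cluster = c("C4", "C6", "C2", "FC4", "CP4")) {
  stopifnot(erd_depth >= -1, erd_depth <= 1, fs > 0, trial_s > 0)
  montage <- montage_1010(n_channels)
  labs <- montage$positions$label
  stopifnot(all(left_cluster %in% labs), all(right_cluster %in% labs))
  structure(list(n_channels = n_channels, fs = fs, trial_s = trial_s,
                 erd_depth = erd_depth, mu_amp = mu_amp, beta_amp = beta_amp,
                 noise_alpha = noise_alpha, noise_sd = noise_sd,
                 left_cluster = left_cluster, right_cluster = right_cluster,
                 montage = montage),
            class = "mi_sim_config")
}

#' Simulate a four-class motor-imagery session
#'
#' Trials are concatenated back to back into one continuous recording with a
#' MI_CUE event at each trial onset; class order is randomized. A pure
#' function of `(cfg, n_per_class, seed)`.
#'
#' @param cfg a [mi_sim_config()].
#' @param n_per_class trials per class.
#' @param seed integer seed.
#' @param classes the four class labels.
#' @return list with `recording` (a `bci_recording`) and `labels` (per-trial
#'   class, in trial order).
#' @export
simulate_mi_dataset <- function(cfg = mi_sim_config(), n_per_class = 50,
                                seed = 1L,
                                classes = c("LEFT", "RIGHT", "BOTH", "REST")) {
  stopifnot(inherits(cfg, "mi_sim_config"), length(classes) == 4)
  labs <- cfg$montage$positions$label
  tn <- as.integer(round(cfg$trial_s * cfg$fs))
  with_seed(seed, {
    labels <- sample(rep(classes, n_per_class))
    n_trials <- length(labels)
    total <- n_trials * tn
    data <- matrix(0, length(labs), total, dimnames = list(labs, NULL))
    for (ch in seq_along(labs)) {
      data[ch, ] <- noise_oneoverf(total, cfg$noise_alpha, cfg$noise_sd)
    }
    # rhythm gain per trial per cluster: attenuated when the cluster's
    # contralateral limb is engaged
    att <- 1 - cfg$erd_depth
    t_idx <- seq_len(tn) / cfg$fs
    for (tr in seq_len(n_trials)) {
      g_left <- if (labels[tr] %in% c("RIGHT", "BOTH")) att else 1   # C3 cluster
      g_right <- if (labels[tr] %in% c("LEFT", "BOTH")) att else 1   # C4 cluster
      cols <- ((tr - 1) * tn + 1):(tr * tn)
      for (side in c("left", "right")) {
        g <- if (side == "left") g_left else g_right
        cl <- if (side == "left") cfg$left_cluster else cfg$right_cluster
        mu <- g * cfg$mu_amp * sin(2 * pi * 10 * t_idx + runif(1, 0, 2 * pi))
        be <- g * cfg$beta_amp * sin(2 * pi * 20 * t_idx + runif(1, 0, 2 * pi))
        data[cl, cols] <- sweep(data[cl, cols, drop = FALSE], 2, mu + be, "+")
      }
    }
    events <- events_table(sample = (seq_len(n_trials) - 1L) * tn,
                           kind = "MI_CUE", mi_class = labels)
    list(recording = new_recording(data, cfg$fs, labs, events),
         labels = labels)
  })
}

#' P300 simulation configuration
#'
#' Generative model for oddball speller sessions: pink-noise background on
#' 64 channels; target intensifications add a positive Gaussian voltage
#' bump (amplitude `erp_amplitude`, peak `erp_latency_s` after the stimulus,
#' full width at half maximum `erp_width_s`) over the centro-parietal
#' channels, the scalp distribution typical of the P300. Stimulus-onset
#' asynchrony defaults to 175 ms (100 ms flash + 75 ms gap), so consecutive
#' post-stimulus windows overlap as they do in real speller sessions.
#'
#' @param n_channels montage size (64 default).
#' @param fs sampling rate in Hz (240 default).
#' @param erp_amplitude bump amplitude, microvolts.
#' @param erp_latency_s bump peak latency, seconds (within the 0.667 s window).
#' @param erp_width_s bump FWHM, seconds.
#' @param target_channels electrodes carrying the deflection.
#' @param repetitions intensification rounds per character.
#' @param soa_s stimulus-onset asynchrony, seconds.
#' @param char_gap_s silent gap between characters, seconds.
#' @param noise_alpha,noise_sd background-noise parameters.
#' @return list of class `p300_sim_config`.
#' @export
p300_sim_config <- function(n_channels = 64, fs = 240, erp_amplitude = 5,
                            erp_latency_s = 0.3, erp_width_s = 0.1,
                            target_channels = c("Cz", "C1", "C2", "CPz",
                                                "CP1", "CP2", "Pz", "POz"),
                            repetitions = 15, soa_s = 0.175, char_gap_s = 1,
                            noise_alpha = 1, noise_sd = 10) {
  stopifnot(erp_latency_s > 0, erp_latency_s < 0.667, repetitions >= 1)
  montage <- montage_1010(n_channels)
  stopifnot(all(target_channels %in% montage$positions$label))
  structure(list(n_channels = n_channels, fs = fs,
                 erp_amplitude = erp_amplitude, erp_latency_s = erp_latency_s,
                 erp_width_s = erp_width_s, target_channels = target_channels,
                 repetitions = repetitions, soa_s = soa_s,
                 char_gap_s = char_gap_s, noise_alpha = noise_alpha,
                 noise_sd = noise_sd, montage = montage),
            class = "p300_sim_config")
}

#' Randomized intensification schedule
#'
#' For each character and repetition, a uniformly random permutation of the
#' 12 row/column ids, so each id appears exactly `repetitions` times per
#' character (180 intensifications per character at the standard 15).
#'
#' @param n_chars number of characters.
#' @param n_ids number of row/column ids (12).
#' @param repetitions rounds per character (15).
#' @param seed integer seed.
#' @return data.frame with `char_index` (0-based), `repetition` (1-based),
#'   `rc_id`.
#' @export
oddball_schedule <- function(n_chars, n_ids = 12, repetitions = 15,
                             seed = 1L) {
  stopifnot(n_chars >= 1, n_ids >= 1, repetitions >= 1)
  with_seed(seed, {
    rows <- expand.grid(rc_slot = seq_len(n_ids),
                        repetition = seq_len(repetitions),
                        char_index = seq_len(n_chars) - 1L)
    rc <- unlist(lapply(seq_len(n_chars * repetitions),
                        function(i) sample.int(n_ids)))
    data.frame(char_index = rows$char_index, repetition = rows$repetition,
               rc_id = as.integer(rc))
  })
}

#' Simulate a P300 speller session
#'
#' Generates the continuous recording of spelling `text`: for each character
#' the 12 ids are intensified in `repetitions` random permutations at the
#' configured stimulus-onset asynchrony; the two target ids (the character's
#' row and column) add the configured positive deflection on the
#' centro-parietal channels. INTENSIFICATION events carry `rc_id`,
#' `is_target` and `char_index`. A pure function of `(text, cfg, seed)`.
#'
#' @param text string to spell; all characters must be in the layout.
#' @param cfg a [p300_sim_config()].
#' @param layout a [speller_layout()].
#' @param seed integer seed.
#' @return a `bci_recording`.
#' @export
simulate_p300_session <- function(text, cfg = p300_sim_config(),
                                  layout = speller_layout(), seed = 1L) {
  stopifnot(inherits(cfg, "p300_sim_config"), nchar(text) >= 1)
  chars <- strsplit(text, "")[[1]]
  rc_targets <- lapply(chars, function(ch) symbol_rc(layout, ch))
  labs <- cfg$montage$positions$label
  soa <- as.integer(round(cfg$soa_s * cfg$fs))
  gap <- as.integer(round(cfg$char_gap_s * cfg$fs))
  per_char <- 12L * cfg$repetitions * soa + gap
  total <- length(chars) * per_char + as.integer(cfg$fs)  # tail for last epoch
  sched <- oddball_schedule(length(chars), 12, cfg$repetitions, seed)
  with_seed(seed + 1L, {
    data <- matrix(0, length(labs), total, dimnames = list(labs, NULL))
    for (ch in seq_along(labs)) {
      data[ch, ] <- noise_oneoverf(total, cfg$noise_alpha, cfg$noise_sd)
    }
    # stimulus onsets: consecutive SOA slots within each character block
    within <- stats::ave(seq_len(nrow(sched)), sched$char_index,
                         FUN = seq_along) - 1L
    onset <- sched$char_index * per_char + within * soa
    target <- mapply(function(ci, id) id %in% rc_targets[[ci + 1L]],
                     sched$char_index, sched$rc_id)
    # Gaussian deflection, FWHM -> sd
    sd_s <- cfg$erp_width_s / (2 * sqrt(2 * log(2)))
    t_bump <- seq(0, 0.667, by = 1 / cfg$fs)
    bump <- cfg$erp_amplitude * exp(-(t_bump - cfg$erp_latency_s)^2 / (2 * sd_s^2))
    tchan <- match(cfg$target_channels, labs)
    for (e in which(target)) {
      cols <- onset[e] + seq_along(bump)
      cols <- cols[cols <= total]
      data[tchan, cols] <- sweep(data[tchan, cols, drop = FALSE], 2,
                                 bump[seq_along(cols)], "+")
    }
    events <- events_table(sample = onset, kind = "INTENSIFICATION",
                           rc_id = sched$rc_id, is_target = target,
                           char_index = sched$char_index)
    new_recording(data, cfg$fs, labs, events)
  })
}
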