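#' EEG recording and epoch containers
#'
#' A `bci_recording` holds a channels-by-samples signal matrix in microvolts,
#' its sampling rate, channel labels in 10-10/10-20 nomenclature, and an
#' event table. Events are either motor-imagery cues (`MI_CUE`, carrying an
#' imagined-movement class) or speller intensifications (`INTENSIFICATION`,
#' carrying a row/column id, a target flag and a character index). Sample
#' indices are 0-based throughout.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz, positive scalar.
#' @param channel_labels character vector, one unique label per row of `data`.
#' @param events event table as returned by [events_table()]; may be empty.
#' @return An object of class `bci_recording`.
#' @seealso [events_table()], [extract_epochs()], [read_recording()]
#' @export
new_recording <- function(data, fs, channel_labels, events = events_table()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive scalar (Hz)")
  }
  if (nrow(data) != length(channel_labels)) {
    stop("channel_labels length (", length(channel_labels),
         ") does not match number of channels (", nrow(data), ")")
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  events <- validate_events(events, n_samples = ncol(data))
  rownames(data) <- channel_labels
  structure(list(data = data, fs = as.numeric(fs),
                 channel_labels = as.character(channel_labels),
                 events = events),
            class = "bci_recording")
}

#' Construct an event table
#'
#' @param sample integer vector of 0-based sample indices.
#' @param kind `"MI_CUE"` or `"INTENSIFICATION"`.
#' @param mi_class motor-imagery class (`"LEFT"`, `"RIGHT"`, `"BOTH"`,
#'   `"REST"`) for cue events, `NA` otherwise.
#' @param rc_id intensified row/column id 1-12, `NA` for cue events.
#' @param is_target logical target flag for intensifications.
#' @param char_index 0-based index of the spelled character.
#' @return data.frame with the six event columns.
#' @export
events_table <- function(sample = integer(0), kind = character(0),
                         mi_class = NA, rc_id = NA, is_target = NA,
                         char_index = NA) {
  n <- length(sample)
  data.frame(sample = as.integer(sample),
             kind = as.character(kind),
             mi_class = rep_len(as.character(mi_class), n),
             rc_id = rep_len(as.integer(rc_id), n),
             is_target = rep_len(as.logical(is_target), n),
             char_index = rep_len(as.integer(char_index), n),
             stringsAsFactors = FALSE)
}

validate_events <- function(events, n_samples) {
  req <- c("sample", "kind", "mi_class", "rc_id", "is_target", "char_index")
  if (!all(req %in% names(events))) {
    stop("event table must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(events) == 0L) return(events)
  if (any(events$sample < 0L) || any(events$sample >= n_samples)) {
    stop("event sample indices must lie within the recording")
  }
  bad <- !events$kind %in% c("MI_CUE", "INTENSIFICATION")
  if (any(bad)) stop("unknown event kind: ", events$kind[which(bad)[1]])
  mi <- events$kind == "MI_CUE"
  if (any(mi & is.na(events$mi_class))) stop("MI_CUE events must carry mi_class")
  it <- events$kind == "INTENSIFICATION"
  if (any(it & (is.na(events$rc_id) | is.na(events$is_target) |
                is.na(events$char_index)))) {
    stop("INTENSIFICATION events must carry rc_id, is_target and char_index")
  }
  if (any(it & !(events$rc_id %in% 1:12))) stop("rc_id must be in 1..12")
  events
}

#' @export
print.bci_recording <- function(x, ...) {
  cat(sprintf("<bci_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$events)))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

#' Read and write recordings
#'
#' Two on-disk formats are supported. `"delimited"` is a plain-text dialect:
#' header lines `#fs=<Hz>` and `#labels=<comma list>` followed by a
#' tab-separated numeric matrix, one channel per row. `"edf"` is a minimal
#' subset of the European Data Format (16-bit, one uniform sampling rate).
#' Events live in a sidecar TSV (see [read_events()]); `read_recording`
#' picks up `<path>.events.tsv` automatically when present.
#'
#' @param path file path.
#' @param format `"delimited"` or `"edf"`.
#' @param events_path optional explicit path to the events TSV.
#' @return `read_recording`: a [new_recording()] object. `write_recording`:
#'   `path`, invisibly.
#' @export
read_recording <- function(path, format = c("delimited", "edf"),
                           events_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  rec <- if (format == "delimited") read_delimited(path) else read_edf(path)
  ep <- events_path %||% paste0(path, ".events.tsv")
  if (file.exists(ep)) {
    rec$events <- validate_events(read_events(ep), n_samples = ncol(rec$data))
  }
  rec
}

#' @param rec a `bci_recording`.
#' @rdname read_recording
#' @export
write_recording <- function(rec, path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "bci_recording"))
  if (format == "delimited") write_delimited(rec, path) else write_edf(rec, path)
  if (nrow(rec$events) > 0L) write_events(rec$events, paste0(path, ".events.tsv"))
  invisible(path)
}

read_delimited <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  fs_line <- grep("^#fs=", hdr, value = TRUE)
  lab_line <- grep("^#labels=", hdr, value = TRUE)
  if (length(fs_line) != 1L || length(lab_line) != 1L) {
    stop("format error: expected single '#fs=' and '#labels=' header lines")
  }
  fs <- suppressWarnings(as.numeric(sub("^#fs=", "", fs_line)))
  if (is.na(fs)) stop("format error: non-numeric fs header")
  labels <- strsplit(sub("^#labels=", "", lab_line), ",", fixed = TRUE)[[1]]
  labels <- trimws(labels)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) != length(labels)) {
    stop("format error: header lists ", length(labels),
         " labels but matrix has ", length(body), " rows")
  }
  rows <- lapply(strsplit(body, "\t", fixed = TRUE), function(r) {
    v <- suppressWarnings(as.numeric(r))
    if (anyNA(v) && any(is.na(v) != (r %in% c("NA", "NaN")))) {
      stop("format error: non-numeric cell in signal matrix")
    }
    v
  })
  if (length(unique(lengths(rows))) != 1L) {
    stop("format error: ragged signal matrix")
  }
  new_recording(do.call(rbind, rows), fs, labels)
}

write_delimited <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#fs=%.10g", rec$fs),
               paste0("#labels=", paste(rec$channel_labels, collapse = ","))),
             con)
  write.table(format(rec$data, digits = 10, trim = TRUE, scientific = FALSE),
              con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
}

#' Read and write event tables
#'
#' Tab-separated, columns `sample, kind, mi_class, rc_id, is_target,
#' char_index`; empty cells mark absent fields.
#'
#' @param path file path.
#' @return `read_events`: data.frame in [events_table()] layout.
#' @export
read_events <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  events_table(sample = df$sample, kind = df$kind, mi_class = df$mi_class,
               rc_id = df$rc_id, is_target = df$is_target,
               char_index = df$char_index)
}

#' @param events event table.
#' @rdname read_events
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

# --- minimal EDF support (16-bit ints, single uniform sampling rate) -------

pad_str <- function(s, width) {
  s <- substr(s, 1, width)
  formatC(s, width = -width)
}

write_edf <- function(rec, path) {
  ns <- nrow(rec$data)
  n <- ncol(rec$data)
  spr <- as.integer(round(rec$fs))          # one-second data records
  n_rec <- as.integer(ceiling(n / spr))
  total <- n_rec * spr
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_str("0", 8),
    pad_str("synthetic subject", 80),
    pad_str("synthetic recording", 80),
    pad_str("01.01.00", 8), pad_str("00.00.00", 8),
    pad_str(as.character(256 * (ns + 1)), 8),
    pad_str("", 44),
    pad_str(as.character(n_rec), 8),
    pad_str(format(spr / rec$fs, digits = 8), 8),
    pad_str(as.character(ns), 4))
  writeChar(hdr, con, eos = NULL)
  pmin_ <- apply(rec$data, 1, min); pmax_ <- apply(rec$data, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  fields <- list(
    list(rec$channel_labels, 16), list(rep("", ns), 80),
    list(rep("uV", ns), 8),
    list(format(pmin_, digits = 8), 8), list(format(pmax_, digits = 8), 8),
    list(rep("-32768", ns), 8), list(rep("32767", ns), 8),
    list(rep("", ns), 80), list(rep(as.character(spr), ns), 8),
    list(rep("", ns), 32))
  for (f in fields) writeChar(paste0(vapply(f[[1]], pad_str, "", f[[2]]),
                                     collapse = ""), con, eos = NULL)
  scale <- (pmax_ - pmin_) / 65535
  dig <- round(sweep(sweep(rec$data, 1, pmin_), 1, scale, "/")) - 32768
  if (total > n) dig <- cbind(dig, matrix(0, ns, total - n))
  for (r in seq_len(n_rec)) {
    block <- dig[, ((r - 1) * spr + 1):(r * spr), drop = FALSE]
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("format error: bad EDF signal count")
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin_ <- as.numeric(rdv(8)); dmax_ <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  if (length(unique(spr)) != 1L) {
    stop("format error: EDF with per-signal sampling rates is not supported")
  }
  fs <- spr[1] / rec_dur
  out <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2, signed = TRUE,
                   endian = "little")
    out[, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      matrix(raw, nrow = ns, byrow = TRUE)
  }
  phys <- sweep(sweep(out, 1, dmin_), 1, (pmax_ - pmin_) / (dmax_ - dmin_), "*")
  phys <- sweep(phys, 1, pmin_, "+")
  new_recording(phys, fs, labels)
}

# --- epoching and cleaning -------------------------------------------------

#' Extract labeled epochs around events
#'
#' The window is half-open, `[event_sample + floor(t_start * fs),
#' ... + floor((t_end - t_start) * fs))`, so the epoch length is exactly
#' `floor((t_end - t_start) * fs)` samples. At 240 Hz the standard speller
#' window 0 to 0.667 s therefore yields 160 samples. Epochs that would run
#' past either end of the recording are dropped; the number dropped is
#' attached as attribute `"n_dropped"`.
#'
#' @param rec a `bci_recording`.
#' @param kind which events to epoch: `"MI_CUE"` or `"INTENSIFICATION"`.
#' @param t_start,t_end window in seconds relative to the event sample.
#' @return list of `bci_epoch` objects. Cue epochs are labeled with the
#'   imagined-movement class, intensification epochs with `"target"` /
#'   `"nontarget"` (and carry `rc_id` / `char_index`).
#' @export
extract_epochs <- function(rec, kind = c("MI_CUE", "INTENSIFICATION"),
                           t_start = 0, t_end) {
  kind <- match.arg(kind)
  stopifnot(inherits(rec, "bci_recording"), t_end > t_start)
  ev <- rec$events[rec$events$kind == kind, , drop = FALSE]
  n_ep <- as.integer(floor((t_end - t_start) * rec$fs))
  if (n_ep < 1L) stop("window shorter than one sample at fs = ", rec$fs)
  out <- list()
  dropped <- 0L
  for (i in seq_len(nrow(ev))) {
    start <- ev$sample[i] + as.integer(floor(t_start * rec$fs))  # 0-based
    if (start < 0L || start + n_ep > n_samples(rec)) {
      dropped <- dropped + 1L
      next
    }
    label <- if (kind == "MI_CUE") ev$mi_class[i] else
      if (isTRUE(ev$is_target[i])) "target" else "nontarget"
    out[[length(out) + 1L]] <- new_epoch(
      data = rec$data[, (start + 1L):(start + n_ep), drop = FALSE],
      fs = rec$fs, label = label, t_start = t_start, t_end = t_end,
      channel_labels = rec$channel_labels,
      rc_id = ev$rc_id[i], char_index = ev$char_index[i])
  }
  attr(out, "n_dropped") <- dropped
  out
}

#' Epoch constructor
#'
#' @param data channels x samples matrix.
#' @param fs sampling rate in Hz.
#' @param label class label or target flag.
#' @param t_start,t_end window in seconds relative to the event.
#' @param channel_labels channel names.
#' @param rc_id,char_index speller bookkeeping, `NA` for cue epochs.
#' @return object of class `bci_epoch`.
#' @export
new_epoch <- function(data, fs, label, t_start = 0,
                      t_end = t_start + ncol(data) / fs,
                      channel_labels = rownames(data),
                      rc_id = NA_integer_, char_index = NA_integer_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, label = label,
                 t_start = t_start, t_end = t_end,
                 channel_labels = channel_labels,
                 rc_id = rc_id, char_index = char_index),
            class = "bci_epoch")
}

#' @export
print.bci_epoch <- function(x, ...) {
  cat(sprintf("<bci_epoch> %d ch x %d samples @ %g Hz, label=%s\n",
              nrow(x$data), ncol(x$data), x$fs, x$label))
  invisible(x)
}

#' Discard incomplete recordings
#'
#' Removes recordings that are missing any required channel or that contain
#' non-finite samples; survivors are returned unchanged, with a removal
#' report attached as attribute `"removals"` (data.frame of index and
#' reason). Idempotent.
#'
#' @param recs list of `bci_recording`.
#' @param required_channels channel labels every surviving recording must have.
#' @return filtered list with attribute `"removals"`.
#' @export
clean_recordings <- function(recs, required_channels) {
  stopifnot(length(required_channels) > 0)
  keep <- logical(length(recs))
  reason <- character(0)
  idx <- integer(0)
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    missing <- setdiff(required_channels, r$channel_labels)
    if (length(missing) > 0) {
      idx <- c(idx, i)
      reason <- c(reason, paste0("missing channels: ",
                                 paste(missing, collapse = ",")))
    } else if (!all(is.finite(r$data))) {
      idx <- c(idx, i)
      reason <- c(reason, "non-finite samples")
    } else {
      keep[i] <- TRUE
    }
  }
  out <- recs[keep]
  attr(out, "removals") <- data.frame(index = idx, reason = reason,
                                      stringsAsFactors = FALSE)
  out
}
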