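#' Common average reference
#'
#' Subtracts the per-sample mean across all channels from every channel, the
#' standard re-referencing step that removes signal components common to the
#' whole montage. Requires at least two channels. The operation is linear and
#' idempotent (a projection).
#'
#' @param epoch a `bci_epoch`.
#' @return re-referenced `bci_epoch`, same shape and sampling rate.
#' @export
car_reference <- function(epoch) {
  stopifnot(inherits(epoch, "bci_epoch"))
  if (nrow(epoch$data) < 2) stop("CAR requires at least 2 channels")
  epoch$data <- sweep(epoch$data, 2, colMeans(epoch$data))
  epoch
}

#' Surface Laplacian reference
#'
#' Subtracts from each channel the mean of its neighboring electrodes
#' (4 nearest for `"small"`, 4 next-nearest for `"large"`), sharpening
#' spatial focus over the underlying cortex. Neighbor sets come from the
#' montage; neighbors missing from the epoch are ignored, so edge electrodes
#' fall back to their available subset rather than being dropped. With
#' `weighted = TRUE` neighbors are averaged with inverse-distance weights
#' instead of uniformly.
#'
#' @param epoch a `bci_epoch`.
#' @param montage a `bci_montage` containing every epoch channel.
#' @param size `"small"` or `"large"`.
#' @param weighted inverse-distance weighting of neighbors (default off:
#'   plain neighbor mean).
#' @return filtered `bci_epoch`, same shape and sampling rate.
#' @export
laplacian_reference <- function(epoch, montage, size = c("small", "large"),
                                weighted = FALSE) {
  size <- match.arg(size)
  stopifnot(inherits(epoch, "bci_epoch"), inherits(montage, "bci_montage"))
  labs <- epoch$channel_labels
  absent <- setdiff(labs, montage$positions$label)
  if (length(absent) > 0) {
    stop("channels absent from montage: ", paste(absent, collapse = ", "))
  }
  pos <- montage$positions
  out <- epoch$data
  for (i in seq_along(labs)) {
    nb <- montage_neighbors(montage, labs[i], size)
    nb <- intersect(nb, labs)
    if (length(nb) == 0) {
      stop("channel ", labs[i], " has no ", size, " neighbors in the epoch")
    }
    if (weighted) {
      p0 <- pos[pos$label == labs[i], c("x", "y")]
      d <- vapply(nb, function(l) {
        p <- pos[pos$label == l, c("x", "y")]
        sqrt((p$x - p0$x)^2 + (p$y - p0$y)^2)
      }, 0)
      w <- (1 / d) / sum(1 / d)
      out[i, ] <- epoch$data[i, ] - colSums(epoch$data[nb, , drop = FALSE] * w)
    } else {
      out[i, ] <- epoch$data[i, ] - colMeans(epoch$data[nb, , drop = FALSE])
    }
  }
  epoch$data <- out
  epoch
}

#' Apply the configured spatial-filter chain
#'
#' Convenience wrapper running CAR first (if enabled), then the Laplacian
#' (if requested), the default order of the motor-imagery chain. Each stage
#' is independently toggleable.
#'
#' @param epoch a `bci_epoch`.
#' @param montage montage for the Laplacian stage.
#' @param car apply the common average reference first.
#' @param laplacian `"none"`, `"small"` or `"large"`.
#' @param weighted passed to [laplacian_reference()].
#' @return filtered `bci_epoch`.
#' @export
apply_spatial <- function(epoch, montage = NULL, car = TRUE,
                          laplacian = c("small", "none", "large"),
                          weighted = FALSE) {
  laplacian <- match.arg(laplacian)
  if (car) epoch <- car_reference(epoch)
  if (laplacian != "none") {
    if (is.null(montage)) stop("laplacian filtering requires a montage")
    epoch <- laplacian_reference(epoch, montage, laplacian, weighted)
  }
  epoch
}
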