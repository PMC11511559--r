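#' Electrode montage with Laplacian neighbor sets
#'
#' A montage maps electrode labels to normalized 2-D scalp coordinates
#' (schematic top view: x negative left, y positive anterior, unit head
#' radius) and derives the neighbor sets used by the surface-Laplacian
#' spatial filters: `small` neighbors are the 4 nearest electrodes by
#' Euclidean distance, `large` neighbors the 4 next-nearest. Neighbor sets
#' never contain the electrode itself.
#'
#' @param labels electrode labels.
#' @param x,y coordinates, same length as `labels`.
#' @param n_small,n_large number of nearest / next-nearest neighbors.
#' @return object of class `bci_montage` with elements `positions`
#'   (data.frame label/x/y), `small_neighbors`, `large_neighbors` (named
#'   lists of label vectors).
#' @export
make_montage <- function(labels, x, y, n_small = 4, n_large = 4) {
  stopifnot(length(labels) == length(x), length(x) == length(y),
            !anyDuplicated(labels))
  pos <- data.frame(label = as.character(labels), x = x, y = y,
                    stringsAsFactors = FALSE)
  d <- as.matrix(dist(cbind(x, y)))
  small <- list(); large <- list()
  for (i in seq_along(labels)) {
    ord <- order(d[i, ])
    ord <- ord[ord != i]
    k1 <- min(n_small, length(ord))
    k2 <- min(n_small + n_large, length(ord))
    small[[labels[i]]] <- labels[ord[seq_len(k1)]]
    large[[labels[i]]] <- if (k2 > k1) labels[ord[(k1 + 1):k2]] else character(0)
  }
  structure(list(positions = pos, small_neighbors = small,
                 large_neighbors = large),
            class = "bci_montage")
}

#' @export
print.bci_montage <- function(x, ...) {
  cat(sprintf("<bci_montage> %d electrodes\n", nrow(x$positions)))
  invisible(x)
}

# Schematic 10-10 grid: one row per anterior-posterior line, electrodes at
# fixed lateral offsets. Positions are for neighbor determination only.
montage_1010_table <- function() {
  row9 <- function(prefix, y, outer = NULL) {
    labs <- if (is.null(outer)) {
      paste0(prefix, c("7", "5", "3", "1", "z", "2", "4", "6", "8"))
    } else {
      c(outer[1], paste0(prefix, c("5", "3", "1", "z", "2", "4", "6")), outer[2])
    }
    data.frame(label = labs,
               x = c(-0.8, -0.6, -0.4, -0.2, 0, 0.2, 0.4, 0.6, 0.8),
               y = y, stringsAsFactors = FALSE)
  }
  rbind(
    data.frame(label = c("Fp1", "Fpz", "Fp2"), x = c(-0.3, 0, 0.3), y = 0.95),
    data.frame(label = c("AF7", "AF3", "AFz", "AF4", "AF8"),
               x = c(-0.55, -0.3, 0, 0.3, 0.55), y = 0.78),
    row9("F", 0.6),
    row9("FC", 0.3, outer = c("FT7", "FT8")),
    row9("C", 0.0, outer = c("T7", "T8")),
    row9("CP", -0.3, outer = c("TP7", "TP8")),
    row9("P", -0.6),
    data.frame(label = c("PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8"),
               x = c(-0.65, -0.5, -0.3, 0, 0.3, 0.5, 0.65), y = -0.78),
    data.frame(label = c("O1", "Oz", "O2"), x = c(-0.3, 0, 0.3), y = -0.95),
    data.frame(label = "Iz", x = 0, y = -1.05))
}

#' Built-in 10-10 montage
#'
#' A 64-electrode schematic 10-10 montage covering the full scalp, including
#' the motor strip (FC/C/CP rows) used by the motor-imagery chain. The
#' 62-channel motor-imagery default drops the two most extreme midline sites
#' (`Fpz`, `Iz`).
#'
#' @param n_channels 64 (full set) or 62 (motor-imagery default).
#' @return a [make_montage()] object.
#' @export
montage_1010 <- function(n_channels = 64) {
  tab <- montage_1010_table()
  if (n_channels == 62) {
    tab <- tab[!tab$label %in% c("Fpz", "Iz"), ]
  } else if (n_channels != 64) {
    stop("built-in montage supports 62 or 64 channels")
  }
  make_montage(tab$label, tab$x, tab$y)
}

montage_neighbors <- function(montage, label, size = c("small", "large")) {
  size <- match.arg(size)
  nb <- if (size == "small") montage$small_neighbors else montage$large_neighbors
  if (!label %in% names(nb)) {
    stop("channel ", label, " absent from montage")
  }
  nb[[label]]
}
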