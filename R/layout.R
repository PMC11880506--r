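#' Standard 64-electrode scalp layout
#'
#' Returns the 64 channel labels of a standard 10-20-derived (BioSemi-style)
#' 64-electrode montage together with nominal 2-D scalp-grid coordinates
#' computed from the label geometry: `y` runs from posterior (negative) to
#' anterior (positive) rows (Iz ... Fp), `x` from left (negative, odd channel
#' numbers) to right (positive, even numbers), midline `z` channels at
#' `x = 0`. Coordinates are nominal grid positions intended for neighborhood
#' (searchlight adjacency) and region-of-interest construction, not digitized
#' electrode positions.
#'
#' @param n_channels number of channels; 64 gives the full montage, smaller
#'   values take a spatially spread subset (every k-th channel of the full
#'   list), handy for reduced simulations.
#' @return data.frame with columns `channel`, `x`, `y`.
#' @export
electrode_layout <- function(n_channels = 64) {
  labels <- c(
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
    "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
    "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz",
    "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8",
    "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6",
    "CP4", "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2"
  )
  if (n_channels < 2 || n_channels > length(labels)) {
    stop_invalid("n_channels must be between 2 and %d", length(labels))
  }
  row_y <- c(Fp = 4, AF = 3, F = 2, FT = 1, FC = 1, C = 0, T = 0,
             TP = -1, CP = -1, P = -2, PO = -3, O = -4, I = -5)
  pos <- t(vapply(labels, function(lab) {
    prefix <- sub("[0-9z]+$", "", lab)
    suffix <- sub("^[A-Za-z]+?(?=[0-9z]+$)", "", lab, perl = TRUE)
    y <- row_y[[prefix]]
    if (suffix == "z") {
      x <- 0
    } else {
      num <- as.integer(suffix)
      mag <- switch(as.character(num),
                    "1" = 1, "2" = 1, "3" = 2, "4" = 2, "5" = 3, "6" = 3,
                    "7" = 4, "8" = 4, "9" = 5, "10" = 5)
      x <- if (num %% 2 == 1) -mag else mag
    }
    c(x = x, y = y)
  }, numeric(2)))
  layout <- data.frame(channel = labels, x = pos[, "x"], y = pos[, "y"],
                       stringsAsFactors = FALSE, row.names = NULL)
  if (n_channels < 64) {
    idx <- unique(round(seq(1, 64, length.out = n_channels)))
    while (length(idx) < n_channels) {
      idx <- sort(unique(c(idx, setdiff(seq_len(64), idx)[1])))
    }
    layout <- layout[idx[seq_len(n_channels)], , drop = FALSE]
    rownames(layout) <- NULL
  }
  layout
}

#' Channel adjacency for searchlight decoding
#'
#' Builds the channel neighborhood map used by [searchlight_timecourse()] and
#' by spatio-temporal clustering: each channel's neighborhood is itself plus
#' all channels within `radius` grid units on the 2-D layout. On the nominal
#' integer grid of [electrode_layout()] the default radius 1.5 yields the
#' first-order neighbors including diagonals.
#'
#' @param layout data.frame from [electrode_layout()].
#' @param radius neighborhood radius in layout grid units.
#' @return named list; element `ch` is the character vector of neighbors of
#'   `ch` (always including `ch` itself). Symmetric by construction.
#' @export
channel_adjacency <- function(layout, radius = 1.5) {
  stopifnot(all(c("channel", "x", "y") %in% names(layout)))
  d <- as.matrix(stats::dist(layout[, c("x", "y")]))
  adj <- lapply(seq_len(nrow(layout)), function(i) {
    layout$channel[d[i, ] <= radius]
  })
  names(adj) <- layout$channel
  bad <- names(adj)[vapply(adj, length, 1L) < 2L]
  if (length(bad)) {
    stop_invalid("channels without neighbors at radius %g: %s",
                 radius, paste(bad, collapse = ", "))
  }
  adj
}

#' Six-region scalp map
#'
#' Partitions the montage into six regions of interest along the median
#' (left/right) and coronal (anterior/central/posterior) planes: LA, RA, LC,
#' RC, LP, RP. Rows Fp/AF/F are anterior, FC/C/CP (and temporal) central,
#' P/PO/O posterior. Midline channels (x = 0) are assigned to both the left
#' and right region of their coronal band so that the six regions cover the
#' whole montage.
#'
#' @param layout data.frame from [electrode_layout()].
#' @return named list of six character vectors of channel names.
#' @export
roi_map <- function(layout) {
  band <- ifelse(layout$y > 1, "A", ifelse(layout$y < -1, "P", "C"))
  out <- list()
  for (b in c("A", "C", "P")) {
    out[[paste0("L", b)]] <- layout$channel[band == b & layout$x <= 0]
    out[[paste0("R", b)]] <- layout$channel[band == b & layout$x >= 0]
  }
  out <- out[c("LA", "RA", "LC", "RC", "LP", "RP")]
  if (any(vapply(out, length, 1L) == 0L)) {
    stop_invalid("layout too sparse: an ROI is empty")
  }
  out
}
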