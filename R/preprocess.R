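#' Zero-phase band-pass filter
#'
#' Butterworth high-pass (2nd order) and low-pass (4th order) applied
#' forward-backward (`signal::filtfilt`), i.e. zero-phase. Default band
#' 0.1-40 Hz. Operates along the last dimension (time) of a vector, matrix
#' (signals x time) or 3-D epochs array (trials x channels x time).
#'
#' @param x numeric vector, matrix or 3-D array; time is the last dimension.
#' @param low,high band edges in Hz; `0 < low < high < sfreq/2`.
#' @param sfreq sampling rate in Hz.
#' @return filtered data, same shape as `x`.
#' @export
bandpass <- function(x, low = 0.1, high = 40, sfreq) {
  if (!(low > 0 && low < high && high < sfreq / 2)) {
    stop_invalid("invalid band: need 0 < low < high < sfreq/2")
  }
  hp <- signal::butter(2, low / (sfreq / 2), type = "high")
  lp <- signal::butter(4, high / (sfreq / 2), type = "low")
  filt1 <- function(v) {
    v <- v - mean(v)  # avoids long high-pass edge transients on offsets
    v <- signal::filtfilt(hp, v)
    signal::filtfilt(lp, v)
  }
  apply_time <- function(m) t(apply(m, 1, filt1))
  if (is.null(dim(x))) return(filt1(x))
  if (length(dim(x)) == 2) return(apply_time(x))
  if (length(dim(x)) == 3) {
    d <- dim(x)
    m <- matrix(aperm(x, c(3, 1, 2)), d[3], d[1] * d[2])
    m <- apply(m, 2, filt1)
    return(aperm(array(m, c(d[3], d[1], d[2])), c(2, 3, 1)))
  }
  stop_invalid("x must be a vector, matrix or 3-D array")
}

#' Epoch a continuous recording
#'
#' Cuts epochs on the half-open sample grid `[tmin, tmax)`: at 200 Hz a
#' -200..1200 ms window yields exactly 280 samples. Events whose window falls
#' outside the recording raise an error listing the offending events.
#'
#' @param data channels x time matrix of a continuous recording.
#' @param events integer sample indices (1-based) of stimulus onsets.
#' @param tmin,tmax epoch window in ms relative to the event.
#' @param sfreq sampling rate in Hz.
#' @return trials x channels x time array with a `times` attribute (ms).
#' @export
epoch_continuous <- function(data, events, tmin = -200, tmax = 1200, sfreq) {
  stopifnot(is.matrix(data))
  n_times <- round((tmax - tmin) * sfreq / 1000)
  offs <- round(tmin * sfreq / 1000)
  first <- events + offs
  last <- first + n_times - 1
  bad <- which(first < 1 | last > ncol(data))
  if (length(bad)) {
    stop_invalid("events outside recording, dropped trials would be: %s",
                 paste(bad, collapse = ", "))
  }
  out <- array(NA_real_, c(length(events), nrow(data), n_times))
  for (i in seq_along(events)) {
    out[i, , ] <- data[, first[i]:last[i]]
  }
  attr(out, "times") <- tmin + (seq_len(n_times) - 1) * 1000 / sfreq
  out
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline samples
#' (default the 200 ms preceding stimulus onset, `[-200, 0)` ms).
#'
#' @param epochs an `epochs_collection` or a 3-D array with a `times`
#'   attribute.
#' @param baseline `c(start, end)` in ms, half-open.
#' @return same type as input, baseline-corrected.
#' @export
baseline_correct <- function(epochs, baseline = c(-200, 0)) {
  fix_array <- function(a, times) {
    sel <- which(times >= baseline[1] & times < baseline[2])
    if (!length(sel)) stop_invalid("baseline window contains no samples")
    bl <- apply(a[, , sel, drop = FALSE], c(1, 2), mean)
    a - array(rep(bl, dim(a)[3]), dim(a))
  }
  if (inherits(epochs, "epochs_collection")) {
    epochs$participants <- lapply(epochs$participants, function(pp) {
      pp$data <- fix_array(pp$data, epochs$times)
      pp
    })
    return(epochs)
  }
  times <- attr(epochs, "times")
  if (is.null(times)) stop_invalid("array input needs a 'times' attribute")
  out <- fix_array(epochs, times)
  attr(out, "times") <- times
  out
}

#' Downsample epochs by integer decimation
#'
#' Anti-alias low-pass filters (zero-phase Butterworth at 0.8 x Nyquist of the
#' target rate) and keeps every k-th sample, where `k = sfreq/target` must be
#' an integer. `target == sfreq` is the identity.
#'
#' @param epochs an `epochs_collection`.
#' @param target target sampling rate in Hz.
#' @return the decimated `epochs_collection`.
#' @export
downsample <- function(epochs, target = 200) {
  stopifnot(inherits(epochs, "epochs_collection"))
  if (target > epochs$sfreq) stop_invalid("target rate exceeds source rate")
  factor <- epochs$sfreq / target
  if (abs(factor - round(factor)) > 1e-9) {
    stop_invalid("target must divide the source rate (integer decimation)")
  }
  factor <- round(factor)
  if (factor == 1) return(epochs)
  keep <- seq(1, length(epochs$times), by = factor)
  lp <- signal::butter(4, 0.8 * (target / 2) / (epochs$sfreq / 2), type = "low")
  epochs$participants <- lapply(epochs$participants, function(pp) {
    d <- dim(pp$data)
    m <- matrix(aperm(pp$data, c(3, 1, 2)), d[3], d[1] * d[2])
    m <- apply(m, 2, function(v) signal::filtfilt(lp, v))
    a <- aperm(array(m, c(d[3], d[1], d[2])), c(2, 3, 1))
    pp$data <- a[, , keep, drop = FALSE]
    pp
  })
  epochs$times <- epochs$times[keep]
  epochs$sfreq <- target
  epochs
}

#' Average same-image trials into pseudo-trials
#'
#' Per participant and image, trials are randomly partitioned into bins of
#' `bin_size` (default 3) and averaged; incomplete bins are dropped. With 12
#' repetitions and bins of 3 this yields 4 pseudo-trials per image, 128 per
#' participant, and reduces the noise variance by about `1/bin_size`.
#'
#' @param epochs an `epochs_collection`.
#' @param bin_size trials per bin.
#' @param seed integer seed for the random partitions.
#' @return a `pseudo_trial_set` (also an `epochs_collection`); metadata gains
#'   a `bin` column.
#' @export
bin_average <- function(epochs, bin_size = 3, seed = 1) {
  stopifnot(inherits(epochs, "epochs_collection"))
  if (bin_size < 1) stop_invalid("bin_size must be >= 1")
  epochs$participants <- lapply(seq_along(epochs$participants), function(p) {
    pp <- epochs$participants[[p]]
    rows <- list(); metas <- list(); dropped <- character(0)
    with_seed(substream_seed(seed, paste("bins", p)), {
      for (img in unique(pp$meta$image_id)) {
        idx <- which(pp$meta$image_id == img)
        if (length(idx) < bin_size) {
          dropped <- c(dropped, img)
          next
        }
        idx <- sample(idx)
        n_bins <- floor(length(idx) / bin_size)
        for (b in seq_len(n_bins)) {
          take <- idx[((b - 1) * bin_size + 1):(b * bin_size)]
          avg <- pp$data[take, , , drop = FALSE]
          rows[[length(rows) + 1L]] <-
            apply(avg, c(2, 3), mean)
          m <- pp$meta[take[1], , drop = FALSE]
          m$bin <- b
          metas[[length(metas) + 1L]] <- m
        }
      }
    })
    if (length(dropped)) {
      warning(sprintf("participant %d: %d image(s) dropped with fewer than %d trials: %s",
                      p, length(dropped), bin_size,
                      paste(dropped, collapse = ", ")))
    }
    dat <- array(NA_real_, c(length(rows), dim(pp$data)[2], dim(pp$data)[3]))
    for (i in seq_along(rows)) dat[i, , ] <- rows[[i]]
    meta <- do.call(rbind, metas)
    rownames(meta) <- NULL
    list(data = dat, meta = meta)
  })
  class(epochs) <- c("pseudo_trial_set", "epochs_collection")
  epochs
}
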