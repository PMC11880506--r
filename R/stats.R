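#' Bundle participant-level series for group inference
#'
#' @param values participant x time matrix, or participant x channel x time
#'   array (then `channels` names the second dimension).
#' @param chance the null reference value (scheme chance, or 0 for Fisher-z
#'   correlations).
#' @param sfreq sampling rate in Hz.
#' @param times optional time axis in ms.
#' @param channels optional channel names for 3-D input.
#' @return a `series_bundle`.
#' @export
series_bundle <- function(values, chance, sfreq, times = NULL, channels = NULL) {
  values <- if (is.matrix(values) || length(dim(values)) == 3) values else
    as.matrix(values)
  if (anyNA(values)) stop_invalid("series values must not contain NA")
  nt <- dim(values)[length(dim(values))]
  if (is.null(times)) times <- (seq_len(nt) - 1) * 1000 / sfreq
  structure(list(values = values, chance = chance, sfreq = sfreq,
                 times = times, channels = channels),
            class = "series_bundle")
}

#' Centered moving average
#'
#' Smooths a series with a centered mean over a window given in ms (converted
#' to an odd sample count at the sampling rate; 35 ms at 200 Hz spans 7
#' samples). Edges use shrinking (partial) windows.
#'
#' @param x numeric vector, matrix (rows smoothed) or `series_bundle`.
#' @param window_ms window width in ms.
#' @param sfreq sampling rate in Hz (taken from the bundle if omitted).
#' @return smoothed object of the same type.
#' @export
moving_average <- function(x, window_ms = 35, sfreq = NULL) {
  if (inherits(x, "series_bundle")) {
    sfreq <- sfreq %||% x$sfreq
    v <- x$values
    if (length(dim(v)) == 3) {
      for (c in seq_len(dim(v)[2])) {
        v[, c, ] <- moving_average(v[, c, , drop = TRUE], window_ms, sfreq)
      }
    } else {
      v <- moving_average(v, window_ms, sfreq)
    }
    x$values <- v
    return(x)
  }
  if (is.null(sfreq)) stop_invalid("sfreq required for raw input")
  k <- round(window_ms * sfreq / 1000)
  if (k < 1) stop_invalid("window shorter than one sample")
  if (k %% 2 == 0) k <- k + 1
  half <- (k - 1) / 2
  smooth_vec <- function(v) {
    n <- length(v)
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  if (is.null(dim(x))) return(smooth_vec(x))
  t(apply(x, 1, smooth_vec))
}

ma_kernel_samples <- function(window_ms, sfreq) {
  k <- round(window_ms * sfreq / 1000)
  if (k %% 2 == 0) k + 1 else k
}

# One-sample t statistics per column for all sign-flip rows at once.
# d: n x m matrix of (value - chance); signs: B x n matrix in {-1, 1}.
signflip_tstats <- function(d, signs) {
  n <- nrow(d)
  q <- colSums(d^2)
  m <- (signs %*% d) / n
  v <- (rep(q, each = nrow(signs)) - n * m^2) / (n - 1)
  v[v < .Machine$double.eps] <- .Machine$double.eps
  m / sqrt(v / n)
}

# Temporal clusters of a thresholded t series: list of index vectors and
# signed masses, for positive and negative exceedances separately.
temporal_clusters <- function(tvals, tcrit) {
  out <- list()
  for (sgn in c(1, -1)) {
    above <- sgn * tvals > tcrit
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      idx <- starts[i]:ends[i]
      out[[length(out) + 1L]] <- list(idx = idx, mass = sum(tvals[idx]))
    }
  }
  out
}

max_cluster_mass <- function(tvals, tcrit) {
  cl <- temporal_clusters(tvals, tcrit)
  if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, 1, "mass")))
}

# Spatio-temporal clusters on a channel x time t map: connected components of
# the suprathreshold mask where (c,t) touches (c,t+-1) and (neighbor(c),t).
spatiotemporal_clusters <- function(tmap, tcrit, neighbor_idx) {
  nc <- nrow(tmap); nt <- ncol(tmap)
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- sgn * tmap > tcrit
    visited <- matrix(FALSE, nc, nt)
    for (start in which(mask & !visited)) {
      if (visited[start]) next
      comp <- integer(0)
      stack <- start
      visited[start] <- TRUE
      while (length(stack)) {
        cur <- stack[length(stack)]; stack <- stack[-length(stack)]
        comp <- c(comp, cur)
        ci <- (cur - 1) %% nc + 1
        ti <- (cur - 1) %/% nc + 1
        cand <- integer(0)
        if (ti > 1) cand <- c(cand, cur - nc)
        if (ti < nt) cand <- c(cand, cur + nc)
        cand <- c(cand, (ti - 1) * nc + neighbor_idx[[ci]])
        cand <- cand[mask[cand] & !visited[cand]]
        if (length(cand)) {
          visited[cand] <- TRUE
          stack <- c(stack, cand)
        }
      }
      out[[length(out) + 1L]] <- list(idx = comp, mass = sum(tmap[comp]))
    }
  }
  out
}

max_cluster_mass_st <- function(tmap, tcrit, neighbor_idx) {
  cl <- spatiotemporal_clusters(tmap, tcrit, neighbor_idx)
  if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, 1, "mass")))
}

#' One-sample sign-flip cluster permutation test
#'
#' Tests participant-level series against the null reference by cluster-mass
#' permutation: per-point one-sample t statistics of (value - chance),
#' clustered by temporal contiguity (and channel adjacency for channel x time
#' input) where |t| exceeds the two-tailed p = `cluster_threshold_p` quantile
#' at n-1 df; cluster mass is the summed t. The null flips the sign of each
#' participant's whole (value - chance) series at random; positive and
#' negative clusters are each compared to the permutation distribution of the
#' maximum absolute mass. When `2^n <= n_perm` all sign patterns are
#' enumerated exhaustively (with a message); otherwise `n_perm` random flips
#' including the identity are drawn.
#'
#' @param bundle a [series_bundle()]; 2-D (participant x time) or 3-D
#'   (participant x channel x time, then `adjacency` is required).
#' @param n_perm permutation count (default 10000).
#' @param cluster_threshold_p cluster-forming two-tailed p (default 0.05).
#' @param adjacency channel adjacency list for spatio-temporal input.
#' @param seed integer seed for the random flips.
#' @return data.frame of cluster records: `start_ms`, `end_ms`, `n_points`,
#'   `mass`, `p`, `peak_ms`, `peak_d` (Cohen's d at the peak |t| point), and
#'   `channels` (comma-separated, spatio-temporal only). Attribute `tvals`
#'   carries the observed t map.
#' @export
cluster_permutation <- function(bundle, n_perm = 10000, cluster_threshold_p = 0.05,
                                adjacency = NULL, seed = 1) {
  stopifnot(inherits(bundle, "series_bundle"))
  v <- bundle$values
  spatio <- length(dim(v)) == 3
  if (spatio && is.null(adjacency)) {
    stop_invalid("adjacency required for channel x time input")
  }
  n <- dim(v)[1]
  if (n < 5) warning("fewer than 5 participants: permutation space is coarse")
  d <- if (spatio) {
    matrix(v - bundle$chance, n, prod(dim(v)[2:3]))
  } else v - bundle$chance
  tcrit <- stats::qt(1 - cluster_threshold_p / 2, df = n - 1)

  exhaustive <- 2^n <= n_perm
  signs <- if (exhaustive) {
    message(sprintf("enumerating all %d sign patterns exhaustively", 2^n))
    as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    s <- with_seed(substream_seed(seed, "signflip"), {
      matrix(sample(c(1, -1), (n_perm - 1) * n, replace = TRUE), n_perm - 1, n)
    })
    rbind(rep(1, n), s)
  }
  tall <- signflip_tstats(d, signs)
  obs_row <- if (exhaustive) which(apply(signs == 1, 1, all))[1] else 1L
  tobs <- tall[obs_row, ]

  if (spatio) {
    nc <- dim(v)[2]; nt <- dim(v)[3]
    chn <- bundle$channels %||% as.character(seq_len(nc))
    neighbor_idx <- lapply(chn, function(ch) {
      which(chn %in% setdiff(adjacency[[ch]], ch))
    })
    tobs_map <- matrix(tobs, nc, nt)
    clusters <- spatiotemporal_clusters(tobs_map, tcrit, neighbor_idx)
    null_max <- vapply(seq_len(nrow(tall)), function(b) {
      max_cluster_mass_st(matrix(tall[b, ], nc, nt), tcrit, neighbor_idx)
    }, 1)
  } else {
    clusters <- temporal_clusters(tobs, tcrit)
    null_max <- vapply(seq_len(nrow(tall)), function(b) {
      max_cluster_mass(tall[b, ], tcrit)
    }, 1)
  }

  dvals <- effect_size_values(d)
  times <- bundle$times
  rec <- lapply(clusters, function(cl) {
    idx <- cl$idx
    if (spatio) {
      nc <- dim(v)[2]
      ti <- (idx - 1) %/% nc + 1
      ci <- (idx - 1) %% nc + 1
      peak <- idx[which.max(abs(tobs[idx]))]
      data.frame(start_ms = min(times[ti]), end_ms = max(times[ti]),
                 n_points = length(idx), mass = cl$mass,
                 p = mean(null_max >= abs(cl$mass)),
                 peak_ms = times[(peak - 1) %/% nc + 1],
                 peak_d = dvals[peak],
                 channels = paste(sort(unique((bundle$channels %||%
                   as.character(seq_len(nc)))[ci])), collapse = ","),
                 stringsAsFactors = FALSE)
    } else {
      peak <- idx[which.max(abs(tobs[idx]))]
      data.frame(start_ms = times[min(idx)], end_ms = times[max(idx)],
                 n_points = length(idx), mass = cl$mass,
                 p = mean(null_max >= abs(cl$mass)),
                 peak_ms = times[peak], peak_d = dvals[peak],
                 stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rec)) do.call(rbind, rec) else
    data.frame(start_ms = numeric(0), end_ms = numeric(0),
               n_points = integer(0), mass = numeric(0), p = numeric(0),
               peak_ms = numeric(0), peak_d = numeric(0))
  out <- out[order(out$start_ms), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tvals") <- tobs
  attr(out, "tcrit") <- tcrit
  attr(out, "exhaustive") <- exhaustive
  out
}

effect_size_values <- function(d) {
  mu <- colMeans(d)
  sdv <- apply(d, 2, stats::sd)
  out <- mu / sdv
  out[sdv == 0 & mu == 0] <- 0
  out[sdv == 0 & mu != 0] <- sign(mu[sdv == 0 & mu != 0]) * Inf
  out
}

#' Per-timepoint Cohen's d against the null reference
#'
#' `d = mean(value - chance) / sd(value - chance)` over participants. A
#' zero-variance point with nonzero mean is flagged as +-Inf, not an error.
#'
#' @param bundle a [series_bundle()] (2-D).
#' @return numeric vector of d per timepoint.
#' @export
effect_size_series <- function(bundle) {
  stopifnot(inherits(bundle, "series_bundle"))
  if (dim(bundle$values)[1] < 2) stop_invalid("need >= 2 participants")
  effect_size_values(bundle$values - bundle$chance)
}

#' Interval-null Bayes factor for a one-sample t statistic
#'
#' Evidence for standardized effect sizes outside the practically-null
#' interval versus inside it: both hypotheses share a Cauchy(0, `prior_scale`)
#' prior on delta, truncated to |delta| > `interval_halfwidth` (alternative)
#' or |delta| <= `interval_halfwidth` (null). The marginal likelihood of the
#' observed t under each truncated prior is computed by numerical integration
#' of the noncentral-t density, and the Bayes factor is their ratio.
#'
#' @param t observed one-sample t statistic.
#' @param n sample size (participants).
#' @param prior_scale Cauchy scale r (default 0.707).
#' @param interval_halfwidth excluded-interval half-width on delta
#'   (default 0.5).
#' @return the Bayes factor (outside vs inside).
#' @export
bf_interval_t <- function(t, n, prior_scale = 0.707, interval_halfwidth = 0.5) {
  df <- n - 1
  h <- interval_halfwidth
  r <- prior_scale
  lik <- function(delta) stats::dt(t, df = df, ncp = delta * sqrt(n)) *
    stats::dcauchy(delta, 0, r)
  quad <- function(lo, hi) {
    res <- suppressWarnings(
      stats::integrate(lik, lo, hi, rel.tol = 1e-9, abs.tol = 1e-16,
                       subdivisions = 1000L, stop.on.error = FALSE))
    # numerically-zero segments may report roundoff; only a non-finite or
    # negative mass is a genuine failure
    if (!is.finite(res$value) || res$value < -1e-12) {
      stop_invalid("Bayes factor integration failed on [%g, %g] (t=%g, n=%d): %s",
                   lo, hi, t, n, res$message)
    }
    max(res$value, 0)
  }
  dhat <- t / sqrt(n)
  # split the integrals around the likelihood peak so the quadrature never
  # straddles a narrow mode on a semi-infinite interval
  seg_sum <- function(pts) {
    sum(vapply(seq_len(length(pts) - 1),
               function(i) quad(pts[i], pts[i + 1]), 1))
  }
  pos_pts <- sort(unique(pmax(h, c(h, abs(dhat), abs(dhat) + 5,
                                   abs(dhat) + 20))))
  m_out <- seg_sum(pos_pts) + quad(pos_pts[length(pos_pts)], Inf) +
    seg_sum(sort(-pos_pts)) + quad(-Inf, -pos_pts[length(pos_pts)])
  in_pts <- sort(unique(pmin(h, pmax(-h, c(-h, 0, dhat, h)))))
  m_in <- seg_sum(in_pts)
  z_out <- 2 * stats::pcauchy(-h, 0, r)
  z_in <- 1 - z_out
  (m_out / z_out) / (m_in / z_in)
}

#' Interval-null Bayes factor time course
#'
#' Computes, per timepoint, the one-sample t of (value - chance) across
#' participants and the interval-null Bayes factor of [bf_interval_t()].
#' Values above `threshold` (default 10) count as strong evidence.
#'
#' @param bundle a [series_bundle()] (2-D).
#' @param prior_scale,interval_halfwidth see [bf_interval_t()].
#' @param threshold evidence threshold stored with the series.
#' @return a `bayes_series` data.frame with columns `time_ms`, `t`, `bf`,
#'   `log10_bf`, `above`; attributes record the parameters.
#' @export
bayes_factor_series <- function(bundle, prior_scale = 0.707,
                                interval_halfwidth = 0.5, threshold = 10) {
  stopifnot(inherits(bundle, "series_bundle"))
  v <- bundle$values
  if (length(dim(v)) != 2) stop_invalid("bayes_factor_series needs 2-D input")
  n <- nrow(v)
  if (n < 3) stop_invalid("need >= 3 participants")
  d <- v - bundle$chance
  mu <- colMeans(d)
  se <- apply(d, 2, stats::sd) / sqrt(n)
  tvals <- ifelse(se == 0, sign(mu) * Inf, mu / se)
  bf <- vapply(tvals, function(tt) {
    if (!is.finite(tt)) return(Inf)
    bf_interval_t(tt, n, prior_scale, interval_halfwidth)
  }, 1)
  out <- data.frame(time_ms = bundle$times, t = tvals, bf = bf,
                    log10_bf = log10(bf), above = bf > threshold)
  attr(out, "prior_scale") <- prior_scale
  attr(out, "interval_halfwidth") <- interval_halfwidth
  attr(out, "threshold") <- threshold
  class(out) <- c("bayes_series", "data.frame")
  out
}

#' Point-null (JZS) Bayes factor for comparison
#'
#' The standard Cauchy-prior Bayes factor of the alternative against the
#' point null delta = 0, exposed alongside the interval-null variant.
#' @inheritParams bf_interval_t
#' @export
bf_point_t <- function(t, n, prior_scale = 0.707) {
  df <- n - 1
  lik <- function(delta) stats::dt(t, df = df, ncp = delta * sqrt(n)) *
    stats::dcauchy(delta, 0, prior_scale)
  m1 <- suppressWarnings(stats::integrate(lik, -Inf, Inf, rel.tol = 1e-9))$value
  m0 <- stats::dt(t, df = df)
  m1 / m0
}

#' Onset and first peak of a thresholded evidence series
#'
#' Onset is the first timepoint of the first run of at least `min_run`
#' suprathreshold samples; the peak is the first local maximum of the series
#' within that run. With no suprathreshold point the result is an explicit
#' null (NA onset), not an error.
#'
#' @param series a `bayes_series`, or any numeric series with `times` and
#'   `threshold` supplied.
#' @param times,threshold required for raw numeric input.
#' @param min_run minimum run length in samples (default 1).
#' @return list with `onset_ms`, `peak_ms`, `peak_value` (NA if none).
#' @export
onset_peak <- function(series, times = NULL, threshold = NULL, min_run = 1) {
  if (inherits(series, "bayes_series")) {
    times <- series$time_ms
    threshold <- threshold %||% attr(series, "threshold")
    vals <- series$bf
  } else {
    vals <- as.numeric(series)
    if (is.null(times) || is.null(threshold)) {
      stop_invalid("raw input needs times and threshold")
    }
  }
  above <- vals > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths >= min_run)
  if (!length(runs)) {
    return(list(onset_ms = NA_real_, peak_ms = NA_real_, peak_value = NA_real_))
  }
  idx <- starts[runs[1]]:ends[runs[1]]
  v <- vals[idx]
  # first strict local maximum within the run; a flat run falls back to the
  # first occurrence of its maximum
  strict <- which(v > c(-Inf, v[-length(v)]) & v > c(v[-1], -Inf))
  peak_local <- if (length(strict)) strict[1] else which.max(v)
  list(onset_ms = times[idx[1]], peak_ms = times[idx[peak_local]],
       peak_value = v[peak_local])
}
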