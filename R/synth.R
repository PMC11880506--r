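#' Specify a planted condition effect
#'
#' An effect plants, for every level of a stimulus attribute, a multivariate
#' channel pattern modulated by a temporal window. Patterns marked shared are
#' identical for all participants — the premise that lets a classifier trained
#' on some participants generalize to a held-out one; non-shared effects are
#' re-drawn per participant and are expected to defeat cross-participant
#' decoding.
#'
#' @param attribute one of `"sex"`, `"identity"`, `"expression"`, `"image"`.
#' @param onset,duration effect window in ms (within the epoch).
#' @param amplitude signal amplitude in the same units as the noise sd
#'   (microvolt-scale); the per-level patterns have unit RMS over channels.
#' @param topography optional per-channel weight vector (default all ones);
#'   recycled names are not matched — order must follow the cohort layout.
#' @param shared logical; identical patterns for all participants.
#' @param ramp_ms raised-cosine on/off ramp length in ms at the window edges
#'   (a plateau in between), mimicking the rapid rise of evoked components
#'   while keeping the edges smooth.
#' @param pattern_seed optional integer overriding the substream used to draw
#'   the level patterns.
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(attribute, onset, duration, amplitude,
                        topography = NULL, shared = TRUE, ramp_ms = 20,
                        pattern_seed = NULL) {
  attribute <- match.arg(attribute, c("sex", "identity", "expression", "image"))
  if (amplitude < 0) stop_invalid("amplitude must be >= 0")
  if (duration <= 0) stop_invalid("duration must be positive")
  if (ramp_ms < 0 || 2 * ramp_ms > duration) {
    stop_invalid("ramp_ms must be in [0, duration/2]")
  }
  structure(list(attribute = attribute, onset = onset, duration = duration,
                 amplitude = amplitude, topography = topography,
                 shared = isTRUE(shared), ramp_ms = ramp_ms,
                 pattern_seed = pattern_seed),
            class = "effect_spec")
}

tukey_envelope <- function(n, ramp_n) {
  env <- rep(1, n)
  if (ramp_n > 0 && n > 1) {
    r <- min(ramp_n, floor(n / 2))
    up <- 0.5 - 0.5 * cos(pi * seq_len(r) / r)
    env[seq_len(r)] <- up
    env[n + 1 - seq_len(r)] <- up
  }
  env
}

#' Configure a synthetic cohort
#'
#' Defaults mirror the study conditions the package emulates: 24 participants,
#' 64 channels, 200 Hz sampling, epochs from -200 to 1200 ms (280 samples on
#' the half-open grid), 12 repetitions per image. Background noise is Gaussian
#' with sd `noise_sd`, temporally smoothed by a Gaussian kernel of width
#' `noise_smooth_ms` (sd, in ms) to mimic EEG autocorrelation, and re-scaled
#' to keep its marginal sd.
#'
#' @param n_participants,n_channels,sfreq,tmin,tmax,repetitions see above.
#' @param noise_sd background noise sd (signal units).
#' @param noise_smooth_ms temporal smoothing kernel sd in ms; 0 disables.
#' @param effects list of [effect_spec()] objects.
#' @param seed master seed; all substreams derive from it.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 24, n_channels = 64, sfreq = 200,
                          tmin = -200, tmax = 1200, repetitions = 12,
                          noise_sd = 1, noise_smooth_ms = 20,
                          effects = list(), seed = 1) {
  if (n_participants < 1 || n_channels < 2 || sfreq <= 0 || repetitions < 1) {
    stop_invalid("config error: sizes must be positive")
  }
  if (!(tmin <= 0 && tmax > 0)) stop_invalid("config error: window must contain 0")
  n_times <- round((tmax - tmin) * sfreq / 1000)
  for (ef in effects) {
    stopifnot(inherits(ef, "effect_spec"))
    if (ef$onset < tmin || ef$onset + ef$duration > tmax) {
      stop_invalid("config error: effect window [%g, %g] outside epoch [%g, %g]",
                   ef$onset, ef$onset + ef$duration, tmin, tmax)
    }
    if (!is.null(ef$topography) && length(ef$topography) != n_channels) {
      stop_invalid("config error: topography length must equal n_channels")
    }
  }
  structure(list(n_participants = n_participants, n_channels = n_channels,
                 sfreq = sfreq, tmin = tmin, tmax = tmax,
                 repetitions = repetitions, noise_sd = noise_sd,
                 noise_smooth_ms = noise_smooth_ms, effects = effects,
                 seed = seed, n_times = n_times),
            class = "cohort_config")
}

epoch_times <- function(config) {
  config$tmin + (seq_len(config$n_times) - 1) * 1000 / config$sfreq
}

gaussian_smooth_rows <- function(x, sd_samples) {
  # smooth each row of x along columns with a variance-preserving Gaussian
  if (sd_samples <= 0) return(x)
  half <- max(1L, ceiling(3 * sd_samples))
  k <- stats::dnorm(seq(-half, half), sd = sd_samples)
  k <- k / sqrt(sum(k^2))
  nt <- ncol(x)
  kmat <- matrix(0, nt, nt)
  for (i in seq_len(nt)) {
    j <- (i - half):(i + half)
    ok <- j >= 1 & j <= nt
    kmat[j[ok], i] <- k[ok]
  }
  x %*% kmat
}

effect_levels <- function(attribute, stimulus_set) {
  switch(attribute,
         sex = SEXES,
         identity = unique(stimulus_set$identity),
         expression = EXPRESSIONS,
         image = stimulus_set$image_id)
}

stimulus_level <- function(attribute, stimulus_set) {
  switch(attribute,
         sex = stimulus_set$sex,
         identity = stimulus_set$identity,
         expression = stimulus_set$expression,
         image = stimulus_set$image_id)
}

#' Generate a synthetic multi-participant EEG cohort
#'
#' Each trial's signal is the sum over planted effects of the trial's
#' level-specific channel pattern, weighted by the effect topography and a
#' plateau envelope with raised-cosine ramps over the effect window, plus
#' temporally smoothed
#' Gaussian noise drawn independently per participant and trial. Shared
#' effects use one pattern per level for all participants; non-shared effects
#' re-draw the patterns per participant.
#'
#' @param config from [cohort_config()].
#' @param stimulus_set from [build_stimulus_set()].
#' @return an `epochs_collection`: list with `participants` (each
#'   `list(data = trials x channels x times array, meta = data.frame)`),
#'   `times` (ms), `channels`, `layout`, `sfreq`, and a `ground_truth` record
#'   holding the planted patterns.
#' @export
generate_cohort <- function(config, stimulus_set) {
  stopifnot(inherits(config, "cohort_config"))
  validate_stimulus_set(stimulus_set)
  layout <- electrode_layout(config$n_channels)
  times <- epoch_times(config)
  nt <- config$n_times
  nc <- config$n_channels
  sd_samp <- config$noise_smooth_ms * config$sfreq / 1000

  # level patterns per effect (shared ones drawn once from the master seed)
  draw_patterns <- function(ef, idx, who) {
    lv <- effect_levels(ef$attribute, stimulus_set)
    sd_seed <- ef$pattern_seed %||%
      substream_seed(config$seed, paste("pattern", idx, who))
    with_seed(sd_seed, {
      p <- matrix(stats::rnorm(length(lv) * nc), length(lv), nc,
                  dimnames = list(lv, NULL))
      p / sqrt(rowMeans(p^2))  # unit RMS over channels
    })
  }
  shared_patterns <- lapply(seq_along(config$effects), function(i) {
    ef <- config$effects[[i]]
    if (ef$shared) draw_patterns(ef, i, "shared") else NULL
  })

  participants <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    meta_idx <- rep(seq_len(nrow(stimulus_set)), config$repetitions)
    ord <- with_seed(substream_seed(config$seed, paste("order", p)),
                     sample(meta_idx))
    meta <- stimulus_set[ord, c("image_id", "identity", "sex", "expression")]
    rownames(meta) <- NULL
    n_trials <- nrow(meta)

    noise <- with_seed(substream_seed(config$seed, paste("noise", p)), {
      m <- matrix(stats::rnorm(n_trials * nc * nt, sd = config$noise_sd),
                  n_trials * nc, nt)
      gaussian_smooth_rows(m, sd_samp)
    })
    dat <- array(noise, dim = c(n_trials, nc, nt))

    for (i in seq_along(config$effects)) {
      ef <- config$effects[[i]]
      if (ef$amplitude == 0) next
      pat <- if (ef$shared) shared_patterns[[i]] else
        draw_patterns(ef, i, paste("participant", p))
      topo <- ef$topography %||% rep(1, nc)
      on_idx <- which(times >= ef$onset & times < ef$onset + ef$duration)
      env <- numeric(nt)
      env[on_idx] <- tukey_envelope(length(on_idx),
                                    round(ef$ramp_ms * config$sfreq / 1000))
      lev <- stimulus_level(ef$attribute, stimulus_set)[ord]
      for (l in unique(lev)) {
        sig <- ef$amplitude * outer(pat[l, ] * topo, env)  # channels x times
        tr <- which(lev == l)
        dat[tr, , ] <- dat[tr, , , drop = FALSE] +
          rep(sig, each = length(tr))
      }
    }
    participants[[p]] <- list(data = dat, meta = meta)
  }
  structure(list(participants = participants, times = times,
                 channels = layout$channel, layout = layout,
                 sfreq = config$sfreq,
                 ground_truth = list(config = config,
                                     shared_patterns = shared_patterns)),
            class = "epochs_collection")
}

#' @export
print.epochs_collection <- function(x, ...) {
  d <- dim(x$participants[[1]]$data)
  cat(sprintf("<%s> %d participants, %d trials x %d channels x %d samples (%g Hz)\n",
              class(x)[1], length(x$participants), d[1], d[2], d[3], x$sfreq))
  invisible(x)
}

#' Generate synthetic stimulus images
#'
#' Stand-in rasters for the face photographs: each image is a weighted sum of
#' an identity template, a sex template, an expression template and pixel
#' noise, all drawn as Gaussian fields. The weights control how strongly the
#' low-level image structure encodes each attribute, so image-property RDMs
#' with known attribute content can be constructed.
#'
#' @param stimulus_set from [build_stimulus_set()].
#' @param image_size `c(rows, cols)`.
#' @param structure_weights named vector with entries `identity`, `sex`,
#'   `expression`, `noise`.
#' @param seed integer seed.
#' @return named list of `image_size` matrices, one per `image_id`.
#' @export
generate_images <- function(stimulus_set, image_size = c(32, 32),
                            structure_weights = c(identity = 1, sex = 1,
                                                  expression = 1, noise = 1),
                            seed = 1) {
  validate_stimulus_set(stimulus_set)
  if (any(image_size <= 0)) stop_invalid("image_size must be positive")
  w <- structure_weights
  stopifnot(all(c("identity", "sex", "expression", "noise") %in% names(w)))
  npx <- prod(image_size)
  with_seed(substream_seed(seed, "images"), {
    tmpl <- function(levels) {
      m <- matrix(stats::rnorm(length(levels) * npx), length(levels), npx)
      rownames(m) <- levels
      m
    }
    t_id <- tmpl(unique(stimulus_set$identity))
    t_sex <- tmpl(SEXES)
    t_ex <- tmpl(EXPRESSIONS)
    imgs <- lapply(seq_len(nrow(stimulus_set)), function(i) {
      st <- stimulus_set[i, ]
      px <- w[["identity"]] * t_id[st$identity, ] +
        w[["sex"]] * t_sex[st$sex, ] +
        w[["expression"]] * t_ex[st$expression, ] +
        w[["noise"]] * stats::rnorm(npx)
      matrix(px, image_size[1], image_size[2])
    })
    names(imgs) <- stimulus_set$image_id
    imgs
  })
}

#' Generate synthetic face-embedding vectors
#'
#' Stand-ins for the 128-dimensional descriptors of a face-identification
#' network: per-identity Gaussian cluster centers scaled by
#' `identity_clustering`, plus unit Gaussian within-identity scatter. At
#' clustering 0 the embeddings carry no identity information.
#'
#' @param stimulus_set from [build_stimulus_set()].
#' @param dim embedding dimension (default 128).
#' @param identity_clustering cluster-center scale (>= 0).
#' @param seed integer seed.
#' @return numeric matrix, one row per stimulus (rownames = `image_id`).
#' @export
generate_embeddings <- function(stimulus_set, dim = 128,
                                identity_clustering = 1, seed = 1) {
  validate_stimulus_set(stimulus_set)
  if (dim < 2) stop_invalid("dim must be >= 2")
  if (identity_clustering < 0) stop_invalid("identity_clustering must be >= 0")
  with_seed(substream_seed(seed, "embeddings"), {
    ids <- unique(stimulus_set$identity)
    centers <- matrix(stats::rnorm(length(ids) * dim), length(ids), dim,
                      dimnames = list(ids, NULL))
    emb <- identity_clustering * centers[stimulus_set$identity, , drop = FALSE] +
      matrix(stats::rnorm(nrow(stimulus_set) * dim), nrow(stimulus_set), dim)
    rownames(emb) <- stimulus_set$image_id
    emb
  })
}
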