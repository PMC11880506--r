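# Shared fixtures, built once per test run on first use.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

stim32 <- function() fixture("stim32", build_stimulus_set)

# small noise-only pseudo-trial cohort: 4 participants, 8 channels, 25 samples
tiny_noise_pseudo <- function() {
  fixture("tiny_noise_pseudo", function() {
    cc <- cohort_config(n_participants = 4, n_channels = 8, sfreq = 200,
                        tmin = -50, tmax = 75, repetitions = 6, seed = 101)
    bin_average(baseline_correct(generate_cohort(cc, stim32()), c(-50, 0)),
                3, seed = 1)
  })
}

# strong shared sex effect at 40-140 ms: 5 participants, 8 channels
sex_effect_pseudo <- function() {
  fixture("sex_effect_pseudo", function() {
    eff <- list(effect_spec("sex", onset = 40, duration = 100, amplitude = 3))
    cc <- cohort_config(n_participants = 5, n_channels = 8, sfreq = 200,
                        tmin = -100, tmax = 250, repetitions = 6,
                        effects = eff, seed = 202)
    bin_average(baseline_correct(generate_cohort(cc, stim32()), c(-100, 0)),
                3, seed = 1)
  })
}

abind_rows <- function(a, b) {
  out <- array(NA_real_, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# hand-built pseudo-trial set over a few labelled stimuli, with per-stimulus
# mean patterns and iid noise; convenient for RDM and cross-decoding tests
toy_pseudo <- function(patterns, n_participants = 3, reps = 4, n_times = 3,
                       noise_sd = 0.1, seed = 1, meta_extra = NULL) {
  stims <- rownames(patterns)
  nc <- ncol(patterns)
  set.seed(seed)
  participants <- lapply(seq_len(n_participants), function(p) {
    meta <- data.frame(image_id = rep(stims, each = reps),
                       stringsAsFactors = FALSE)
    if (!is.null(meta_extra)) {
      for (nm in names(meta_extra)) meta[[nm]] <- rep(meta_extra[[nm]], each = reps)
    }
    dat <- array(stats::rnorm(nrow(meta) * nc * n_times, sd = noise_sd),
                 c(nrow(meta), nc, n_times))
    for (i in seq_len(nrow(meta))) {
      dat[i, , ] <- dat[i, , ] + patterns[meta$image_id[i], ]
    }
    list(data = dat, meta = meta)
  })
  structure(list(participants = participants,
                 times = (seq_len(n_times) - 1) * 5, sfreq = 200,
                 channels = paste0("ch", seq_len(nc)),
                 layout = data.frame(channel = paste0("ch", seq_len(nc)),
                                     x = seq_len(nc), y = 0)),
            class = c("pseudo_trial_set", "epochs_collection"))
}
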