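test_that("the discriminant separates Gaussian classes and matches closed form", {
  set.seed(21)
  # well-separated 2-D classes
  xtr <- rbind(matrix(stats::rnorm(80, 0, 0.2), 40, 2),
               matrix(stats::rnorm(80, 3, 0.2), 40, 2))
  ytr <- rep(c("a", "b"), each = 40)
  expect_equal(fit_predict_timepoint(xtr, ytr, xtr, ytr), 1)

  # shuffled labels at large n sit at chance within 3 binomial SEs
  set.seed(22)
  n <- 600
  x <- matrix(stats::rnorm(n * 4), n, 4)
  y <- sample(rep(c("a", "b"), each = n / 2))
  xt <- matrix(stats::rnorm(n * 4), n, 4)
  yt <- sample(rep(c("a", "b"), each = n / 2))
  acc <- fit_predict_timepoint(x, y, xt, yt)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n))

  # equal-covariance 2-class: decisions follow w = S^-1 (mu1 - mu0)
  set.seed(23)
  x2 <- rbind(matrix(stats::rnorm(60, 0), 30, 2),
              matrix(stats::rnorm(60, 1), 30, 2))
  y2 <- rep(c("a", "b"), each = 30)
  xt2 <- matrix(stats::rnorm(100), 50, 2)
  mu0 <- colMeans(x2[y2 == "a", ]); mu1 <- colMeans(x2[y2 == "b", ])
  xc <- rbind(sweep(x2[y2 == "a", ], 2, mu0), sweep(x2[y2 == "b", ], 2, mu1))
  s <- crossprod(xc) / nrow(x2)
  w <- solve(s, mu1 - mu0)
  thresh <- sum(w * (mu0 + mu1)) / 2
  oracle_pred <- ifelse(xt2 %*% w > thresh, "b", "a")
  got <- vapply(seq_len(50), function(i) {
    fit_predict_timepoint(x2, y2, xt2[i, , drop = FALSE], oracle_pred[i],
                          config = list(shrinkage = "none"))
  }, 1)
  expect_equal(mean(got), 1)

  expect_error(fit_predict_timepoint(x2, y2, xt2, rep("c", 50)),
               "absent from training")
  expect_error(fit_predict_timepoint(x2, y2, xt2[, 1, drop = FALSE],
                                     rep("a", 50)),
               "dimension")
})

test_that("shrinkage discriminant agrees with a reference LDA when well-posed", {
  skip_if_not_installed("MASS")
  set.seed(24)
  x <- rbind(matrix(stats::rnorm(200, 0), 100, 2),
             matrix(stats::rnorm(200, 0.8), 100, 2))
  y <- rep(c("a", "b"), each = 100)
  xt <- matrix(stats::rnorm(80), 40, 2)
  fit <- MASS::lda(x, grouping = y)
  ref <- as.character(stats::predict(fit, xt)$class)
  acc <- fit_predict_timepoint(x, y, xt, ref, config = list(shrinkage = "none"))
  expect_equal(acc, 1)
})

test_that("leave-one-participant-out schemes stay at chance on noise", {
  ps <- tiny_noise_pseudo()
  for (tg in c("identity", "sex", "emotion")) {
    res <- loso_timecourse(ps, scheme_spec(tg))
    expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
    expect_lt(abs(mean(res$accuracy) - res$chance), 0.05)
  }
  pr <- loso_timecourse(ps, scheme_spec("emotion_pair",
                                        pair = c("happy", "sad")))
  expect_equal(pr$chance, 0.5)
  expect_lt(abs(mean(pr$accuracy) - 0.5), 0.07)
})

test_that("a planted shared effect is decodable only after its onset", {
  ps <- sex_effect_pseudo()  # sex effect spans 40-140 ms
  res <- loso_timecourse(ps, scheme_spec("sex"))
  acc <- colMeans(apply(res$accuracy, c(1, 3), mean))
  pre <- acc[ps$times < 20]
  during <- acc[ps$times >= 60 & ps$times < 120]
  expect_lt(mean(pre), 0.6)
  expect_gt(mean(during), 0.9)
})

test_that("participant-specific patterns defeat cross-participant decoding", {
  # cross-participant decoding needs patterns shared across observers: with
  # per-participant patterns the held-out participant stays near chance,
  # while the identically-sized shared-pattern cohort decodes far above it.
  # Fold-level pattern draws are few, so the non-shared mean is averaged
  # over seeds.
  run_mean <- function(shared, seed) {
    eff <- list(effect_spec("sex", 0, 100, 1.5, shared = shared))
    cc <- cohort_config(n_participants = 5, n_channels = 8, sfreq = 200,
                        tmin = -25, tmax = 125, repetitions = 6,
                        effects = eff, seed = seed)
    ps <- bin_average(generate_cohort(cc, stim32()), 3, seed = 1)
    res <- loso_timecourse(ps, scheme_spec("sex"))
    mean(res$accuracy[, , ps$times >= 10 & ps$times < 90])
  }
  nonshared <- mean(vapply(33:35, function(s) run_mean(FALSE, s), 1))
  shared <- run_mean(TRUE, 33)
  expect_lt(abs(nonshared - 0.5), 0.12)
  expect_gt(shared, nonshared + 0.15)
})

test_that("no held-out participant or condition ever reaches the training set", {
  ps <- tiny_noise_pseudo()
  ss <- stim32()
  # identity scheme: held-out expression absent from training
  for (f in eegmvpa:::scheme_folds(scheme_spec("identity"), ss)) {
    tr <- ss[f$train_filter(ss), ]
    te <- ss[f$test_filter(ss), ]
    expect_length(intersect(unique(tr$expression), unique(te$expression)), 0)
    expect_equal(length(unique(te$expression)), 1)
    expect_setequal(unique(tr$identity), unique(ss$identity))
  }
  # sex-type schemes: held identity excluded, training sex-balanced 3/3
  for (f in eegmvpa:::scheme_folds(scheme_spec("sex"), ss)) {
    tr <- ss[f$train_filter(ss), ]
    te <- ss[f$test_filter(ss), ]
    expect_length(intersect(unique(tr$identity), unique(te$identity)), 0)
    sx <- table(unique(tr[, c("identity", "sex")])$sex)
    expect_equal(unname(sx), c(3L, 3L), ignore_attr = TRUE)
  }
})

test_that("direction-averaged cross-classification is symmetric and calibrated", {
  ps <- tiny_noise_pseudo()
  ca <- function(meta) meta$expression == "neutral"
  cb <- function(meta) meta$expression == "angry"
  x1 <- cross_classify_conditions(ps, ca, cb, scheme_spec("sex"))
  x2 <- cross_classify_conditions(ps, cb, ca, scheme_spec("sex"))
  expect_identical(x1$accuracy, x2$accuracy)
  expect_lt(abs(mean(x1$accuracy) - 0.5), 0.07)
  expect_error(cross_classify_conditions(
    ps, ca, function(meta) meta$expression == "nope", scheme_spec("sex")),
    "empty condition")

  # identity patterns shared across expressions generalize neutral <-> angry
  eff <- list(effect_spec("identity", 0, 100, 3))
  cc <- cohort_config(n_participants = 4, n_channels = 8, sfreq = 200,
                      tmin = -25, tmax = 125, repetitions = 6,
                      effects = eff, seed = 44)
  psi <- bin_average(generate_cohort(cc, stim32()), 3, seed = 1)
  xg <- cross_classify_conditions(psi, ca, cb, scheme_spec("identity"))
  expect_gt(mean(xg$accuracy[, , psi$times >= 20 & psi$times < 90]), 0.5)

  # image-specific patterns do not generalize across expressions
  effi <- list(effect_spec("image", 0, 100, 3))
  cci <- cohort_config(n_participants = 4, n_channels = 8, sfreq = 200,
                       tmin = -25, tmax = 125, repetitions = 6,
                       effects = effi, seed = 45)
  psn <- bin_average(generate_cohort(cci, stim32()), 3, seed = 1)
  xn <- cross_classify_conditions(psn, ca, cb, scheme_spec("identity"))
  expect_lt(abs(mean(xn$accuracy) - 0.125), 0.06)
})

test_that("cross-classification on duplicated data equals within-condition decoding", {
  ps <- tiny_noise_pseudo()
  # tag a copy of every neutral trial as condition "b"
  dup <- ps
  dup$participants <- lapply(ps$participants, function(pp) {
    sel <- pp$meta$expression == "neutral"
    meta <- pp$meta
    meta$grp <- "a"
    copy <- pp$meta[sel, , drop = FALSE]
    copy$grp <- "b"
    pp$meta <- rbind(meta, copy)
    pp$data <- abind_rows(pp$data, pp$data[sel, , , drop = FALSE])
    pp
  })
  ga <- function(meta) meta$grp == "a" & meta$expression == "neutral"
  gb <- function(meta) meta$grp == "b"
  x <- cross_classify_conditions(dup, ga, gb, scheme_spec("sex"))
  # oracle: train others' neutral trials, test the held-out participant's
  np <- length(ps$participants)
  manual <- sapply(seq_len(np), function(p) {
    train <- eegmvpa:::stack_participants(
      ps, setdiff(seq_len(np), p),
      function(meta) meta$expression == "neutral")
    test <- eegmvpa:::stack_participants(
      ps, p, function(meta) meta$expression == "neutral")
    eegmvpa:::run_fold_series(train, test, train$meta$sex, test$meta$sex,
                              scheme_spec("sex"))
  })
  expect_equal(x$accuracy[, 1, ], t(manual), ignore_attr = TRUE)
})

test_that("searchlight reduces to all-electrode decoding under universal adjacency", {
  ps <- tiny_noise_pseudo()
  adj <- stats::setNames(rep(list(ps$channels), length(ps$channels)),
                         ps$channels)
  sl <- searchlight_timecourse(ps, adj, scheme_spec("sex"))
  base <- loso_timecourse(ps, scheme_spec("sex"))
  for (ci in seq_along(ps$channels)) {
    expect_equal(sl$accuracy[, , ci, ], base$accuracy, ignore_attr = TRUE)
  }
  expect_error(searchlight_timecourse(ps, adj[-1], scheme_spec("sex")),
               "missing from adjacency")
})

test_that("searchlight localizes an effect confined to posterior channels", {
  lay <- electrode_layout(8)
  post <- as.numeric(lay$y <= -2)
  eff <- list(effect_spec("sex", 0, 100, 4, topography = post))
  cc <- cohort_config(n_participants = 4, n_channels = 8, sfreq = 200,
                      tmin = -25, tmax = 125, repetitions = 6,
                      effects = eff, seed = 55)
  ps <- bin_average(generate_cohort(cc, stim32()), 3, seed = 1)
  adj <- channel_adjacency(ps$layout, radius = 3)  # sparse 8-channel subset
  sl <- searchlight_timecourse(ps, adj, scheme_spec("sex"))
  during <- ps$times >= 20 & ps$times < 90
  ch_acc <- apply(sl$accuracy[, , , during, drop = FALSE], 3, mean)
  planted <- which(post == 1)
  # the best channel's neighborhood must touch the planted support
  best <- which.max(ch_acc)
  nb <- match(adj[[ps$channels[best]]], ps$channels)
  expect_gt(length(intersect(nb, planted)), 0)
  expect_gt(mean(ch_acc[planted]), mean(ch_acc[-planted]))
})

test_that("region-of-interest decoding respects the channel partition", {
  ps <- tiny_noise_pseudo()
  rois <- list(all = ps$channels, half = ps$channels[1:4])
  rr <- roi_timecourse(ps, rois, scheme_spec("sex"))
  base <- loso_timecourse(ps, scheme_spec("sex"))
  expect_equal(rr$all$accuracy, base$accuracy)
  expect_error(roi_timecourse(ps, list(bad = "nochan"), scheme_spec("sex")),
               "empty ROI")

  # posterior-confined effect favors posterior regions
  lay <- electrode_layout(16)
  post <- as.numeric(lay$y <= -2)
  eff <- list(effect_spec("sex", 0, 100, 4, topography = post))
  cc <- cohort_config(n_participants = 4, n_channels = 16, sfreq = 200,
                      tmin = -25, tmax = 125, repetitions = 6,
                      effects = eff, seed = 66)
  psx <- bin_average(generate_cohort(cc, stim32()), 3, seed = 1)
  rm6 <- roi_map(psx$layout)
  rr6 <- roi_timecourse(psx, rm6, scheme_spec("sex"))
  during <- psx$times >= 20 & psx$times < 90
  m <- vapply(rr6, function(r) mean(r$accuracy[, , during]), 1)
  expect_gt(mean(m[c("LP", "RP")]), mean(m[c("LA", "RA")]))
})

test_that("scheme specifications validate their structure", {
  expect_equal(scheme_spec("identity")$chance, 0.125)
  expect_equal(scheme_spec("sex")$chance, 0.5)
  expect_equal(scheme_spec("emotion")$chance, 0.25)
  expect_equal(scheme_spec("emotion_pair", pair = c("happy", "neutral"))$chance,
               0.5)
  expect_error(scheme_spec("emotion_pair"), "two distinct")
  expect_error(scheme_spec("emotion_pair", pair = c("happy", "happy")),
               "two distinct")
})
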