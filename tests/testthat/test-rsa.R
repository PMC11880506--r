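test_that("neural RDMs are symmetric pairwise-decoding maps with masked diagonal", {
  # four stimuli: A and B share a pattern, C and D are distinct
  pat <- rbind(A = c(1, 0, 0, 0), B = c(1, 0, 0, 0),
               C = c(0, 2, 0, 0), D = c(0, 0, 2, 0))
  ps <- toy_pseudo(pat, n_participants = 3, reps = 4, n_times = 2,
                   noise_sd = 0.05, seed = 2)
  rdm <- neural_rdm_series(ps)
  expect_equal(dim(rdm), c(3, 2, 4, 4))
  m <- rdm[1, 1, , ]
  expect_equal(m, t(m))
  expect_true(all(is.na(diag(m))))
  expect_true(all(rdm >= 0 & rdm <= 1, na.rm = TRUE))
  avg <- apply(rdm, c(3, 4), mean)
  # identical planted patterns decode at chance; distinct ones near 1
  expect_lt(avg["A", "B"], 0.7)
  expect_gt(avg["A", "C"], 0.9)
  expect_gt(avg["C", "D"], 0.9)

  flat <- neural_rdm_series(ps, fold_resolved = FALSE)
  expect_equal(dim(flat), c(2, 4, 4))

  # noise only: mean cell near pairwise chance 0.5
  ps0 <- toy_pseudo(pat * 0, n_participants = 3, reps = 4, n_times = 2,
                    noise_sd = 1, seed = 3)
  rdm0 <- neural_rdm_series(ps0)
  expect_lt(abs(mean(rdm0, na.rm = TRUE) - 0.5), 0.08)

  # a participant missing a stimulus is refused
  broken <- ps
  keep <- broken$participants[[1]]$meta$image_id != "A"
  broken$participants[[1]]$meta <- broken$participants[[1]]$meta[keep, ,
                                                                 drop = FALSE]
  broken$participants[[1]]$data <-
    broken$participants[[1]]$data[keep, , , drop = FALSE]
  expect_error(neural_rdm_series(broken), "missing stimuli")
})

test_that("binary attribute models encode class structure", {
  ss <- stim32()
  sx <- attribute_model_rdm(ss, "sex")
  expect_equal(dim(sx), c(32, 32))
  expect_true(all(sx[!is.na(sx)] %in% c(0, 1)))
  # within-sex blocks are zero: 16 stimuli per sex
  for (s in c("male", "female")) {
    ids <- ss$image_id[ss$sex == s]
    blk <- sx[ids, ids]
    expect_true(all(blk[!is.na(blk)] == 0))
  }
  idm <- attribute_model_rdm(ss, "identity")
  # each row has exactly 3 zero off-diagonal cells (4 images per identity)
  expect_equal(unname(rowSums(idm == 0, na.rm = TRUE)), rep(3, 32),
               ignore_attr = TRUE)
  pm <- attribute_model_rdm(ss, expression_pair = c("happy", "neutral"))
  expect_equal(dim(pm), c(16, 16))
  expect_error(attribute_model_rdm(ss, "age"), "unknown attribute")
  expect_error(attribute_model_rdm(ss, expression_pair = c("happy", "bored")),
               "unknown expressions")
})

test_that("FFT max cross-correlation equals the exhaustive shift search", {
  brute_max_corr <- function(a, b, frac = 0.5) {
    a <- (a - mean(a)) / stats::sd(a); b <- (b - mean(b)) / stats::sd(b)
    h <- nrow(a); w <- ncol(a); best <- -Inf
    n_min <- max(frac * h * w, 2)
    for (du in -(h - 1):(h - 1)) {
      for (dv in -(w - 1):(w - 1)) {
        ia <- max(1, 1 + du):min(h, h + du); ja <- max(1, 1 + dv):min(w, w + dv)
        va <- as.vector(a[ia, ja]); vb <- as.vector(b[ia - du, ja - dv])
        if (length(va) >= n_min && stats::sd(va) > 0 && stats::sd(vb) > 0) {
          best <- max(best, stats::cor(va, vb))
        }
      }
    }
    best
  }
  set.seed(31)
  for (rep_i in 1:3) {
    imgs <- list(a = matrix(stats::rnorm(256), 16),
                 b = matrix(stats::rnorm(256), 16))
    r <- max_crosscorr_rdm(imgs)
    expect_equal(r["a", "b"], 1 - brute_max_corr(imgs$a, imgs$b),
                 tolerance = 1e-10)
  }

  # self-comparison and translation invariance
  a <- matrix(stats::rnorm(256), 16)
  shifted <- matrix(0, 16, 16)
  shifted[4:16, 3:16] <- a[1:13, 1:14]
  r <- max_crosscorr_rdm(list(a = a, self = a, sh = shifted))
  expect_equal(r["a", "self"], 0, tolerance = 1e-12)
  expect_equal(r["a", "sh"], 0, tolerance = 1e-9)

  # euclidean-at-best-shift variant: zero for identical images
  re <- max_crosscorr_rdm(list(a = a, self = a),
                          metric = "euclidean_at_best_shift")
  expect_equal(re["a", "self"], 0, tolerance = 1e-5)
  expect_error(max_crosscorr_rdm(list(a = a, b = matrix(0, 4, 4))),
               "shapes differ")
})

test_that("embedding distances match a direct elementwise computation", {
  e <- rbind(a = c(0, 0), b = c(3, 4))
  expect_equal(embedding_rdm(e)["a", "b"], 5)
  set.seed(32)
  emb <- matrix(stats::rnorm(32 * 128), 32, 128,
                dimnames = list(paste0("s", 1:32), NULL))
  got <- embedding_rdm(emb)
  for (i in c(1, 7, 20)) {
    for (j in c(2, 15, 32)) {
      expect_equal(got[i, j], sqrt(sum((emb[i, ] - emb[j, ])^2)),
                   tolerance = 1e-12)
    }
  }
})

test_that("model correlation recovers structure and honors covariates", {
  ss <- stim32()
  idm <- attribute_model_rdm(ss, "identity")
  # a neural series equal to the model correlates perfectly
  neu <- array(NA_real_, c(2, 32, 32))
  neu[1, , ] <- unclass(idm); neu[2, , ] <- unclass(idm)
  neu_s <- structure(neu, stimuli = rownames(idm), class = "rdm_series")
  r <- rsa_correlate(neu_s, idm)
  expect_equal(r$rho, c(1, 1))
  expect_equal(r$z, atanh(r$rho))

  # partialling the model out of itself leaves nothing
  set.seed(33)
  noise <- matrix(stats::rnorm(32 * 32, sd = 0.1), 32)
  noisem <- unclass(idm) + (noise + t(noise)) / 2
  neu2 <- structure(array(noisem, c(1, 32, 32)), stimuli = rownames(idm),
                    class = "rdm_series")
  rp <- rsa_correlate(neu2, idm, covariates = list(idm))
  expect_lt(abs(rp$rho), 0.05)

  # ordering mismatches are refused, alignment must be explicit
  bad <- unclass(idm)[32:1, 32:1]
  badm <- structure(bad, kind = "attribute-binary",
                    class = c("model_rdm", "matrix"))
  expect_error(rsa_correlate(neu_s, idm, covariates = list(badm)),
               "ordering mismatch")
  expect_equal(align_rdm(badm, rownames(idm)), idm, ignore_attr = TRUE)
})

test_that("partial rank correlation matches the recursive formula on a toy", {
  # 6-stimulus hand-filled matrices
  set.seed(34)
  mk <- function() {
    m <- matrix(stats::rnorm(36), 6)
    m <- m + t(m); diag(m) <- NA
    m
  }
  x <- mk(); y <- mk(); z <- mk()
  stims <- paste0("s", 1:6)
  neu <- structure(array(x, c(1, 6, 6)), stimuli = stims, class = "rdm_series")
  ym <- structure(`dimnames<-`(y, list(stims, stims)),
                  class = c("model_rdm", "matrix"))
  zm <- structure(`dimnames<-`(z, list(stims, stims)),
                  class = c("model_rdm", "matrix"))
  got <- rsa_correlate(neu, ym, covariates = list(zm))$rho
  lv <- function(m) m[lower.tri(m)]
  rs <- function(a, b) stats::cor(rank(a), rank(b))
  rxy <- rs(lv(x), lv(y)); rxz <- rs(lv(x), lv(z)); ryz <- rs(lv(y), lv(z))
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("image-property covariates attenuate image-borne effects only", {
  ss <- stim32()
  idm <- attribute_model_rdm(ss, "identity")
  exm <- attribute_model_rdm(ss, "expression")
  imgs <- generate_images(ss, c(12, 12),
                          c(identity = 3, sex = 0, expression = 0, noise = 1),
                          seed = 5)
  imm <- align_rdm(max_crosscorr_rdm(imgs), rownames(idm))
  mk_series <- function(model, beta_img) {
    arr <- array(NA_real_, c(4, 32, 32))
    set.seed(35)
    for (t in 1:4) {
      noise <- matrix(stats::rnorm(32 * 32, sd = 0.3), 32)
      m <- unclass(model) + beta_img * unclass(imm) + (noise + t(noise)) / 2
      diag(m) <- NA
      arr[t, , ] <- m
    }
    structure(arr, stimuli = rownames(model), class = "rdm_series")
  }
  # identity effect rides on image structure: partialling attenuates it
  neu_id <- mk_series(idm, 1)
  full_id <- mean(rsa_correlate(neu_id, idm)$rho)
  part_id <- mean(rsa_correlate(neu_id, idm, covariates = list(imm))$rho)
  expect_lt(part_id, full_id - 0.03)
  # image-independent expression effect survives partialling
  neu_ex <- mk_series(exm, 1)
  full_ex <- mean(rsa_correlate(neu_ex, exm)$rho)
  part_ex <- mean(rsa_correlate(neu_ex, exm, covariates = list(imm))$rho)
  expect_lt(abs(part_ex - full_ex), 0.1)
  expect_gt(part_ex, 0.3)
})

test_that("fold-resolved RSA series reshape into a stats bundle", {
  pat <- rbind(A = c(2, 0, 0), B = c(0, 2, 0), C = c(1, 1, 0), D = c(0, 0, 2))
  ps <- toy_pseudo(pat, n_participants = 3, reps = 4, n_times = 2,
                   noise_sd = 1, seed = 6)
  rdm <- neural_rdm_series(ps)
  stims <- rownames(pat)
  m <- 1 - diag(4); m[1, 2] <- 0; m[2, 1] <- 0; diag(m) <- NA
  model <- structure(`dimnames<-`(m, list(stims, stims)),
                     class = c("model_rdm", "matrix"))
  rr <- rsa_correlate(rdm, model)
  expect_true(all(c("fold", "time_index", "rho", "z") %in% names(rr)))
  b <- rsa_series_bundle(rr, sfreq = 200)
  expect_equal(dim(b$values), c(3, 2))
  expect_equal(b$chance, 0)
})
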