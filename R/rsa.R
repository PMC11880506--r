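#' Time-resolved neural RDM series from cross-participant pairwise decoding
#'
#' For every unordered stimulus pair and timepoint, a two-class linear
#' discriminant is trained on all-but-one participants' pseudo-trials of the
#' two stimuli and tested on the held-out participant; the decoding accuracy
#' (a dissimilarity: 0.5 at chance, 1 for perfectly separable stimuli) fills
#' the pair's cell. The diagonal is undefined and masked as NA. At the study
#' scale this yields a 280 x 32 x 32 series per fold.
#'
#' @param pseudo a `pseudo_trial_set`; every stimulus must be present for
#'   every participant.
#' @param fold_resolved keep the per-held-out-participant matrices (default,
#'   the form consumed by group statistics) or average them.
#' @param classifier list passed to [fit_predict_timepoint()].
#' @return an `rdm_series`: array `participant x time x stim x stim` (fold
#'   resolved) or `time x stim x stim`; attribute `stimuli` records the
#'   stimulus ordering.
#' @export
neural_rdm_series <- function(pseudo, fold_resolved = TRUE, classifier = list()) {
  stopifnot(inherits(pseudo, "epochs_collection"))
  np <- length(pseudo$participants)
  if (np < 3) stop_invalid("need >= 3 participants")
  stims <- sort(unique(pseudo$participants[[1]]$meta$image_id))
  for (p in seq_len(np)) {
    have <- unique(pseudo$participants[[p]]$meta$image_id)
    if (!setequal(have, stims)) {
      stop_invalid("participant %d is missing stimuli: %s", p,
                   paste(setdiff(stims, have), collapse = ", "))
    }
  }
  ns <- length(stims)
  nt <- length(pseudo$times)
  rdm <- array(NA_real_, c(np, nt, ns, ns))
  scheme <- list(classifier = classifier)
  for (i in seq_len(ns - 1)) {
    for (j in seq.int(i + 1, ns)) {
      pick <- function(meta) meta$image_id %in% c(stims[i], stims[j])
      for (p in seq_len(np)) {
        train <- stack_participants(pseudo, setdiff(seq_len(np), p), pick)
        test <- stack_participants(pseudo, p, pick)
        acc <- run_fold_series(train, test, train$meta$image_id,
                               test$meta$image_id, scheme)
        rdm[p, , i, j] <- acc
        rdm[p, , j, i] <- acc
      }
    }
  }
  if (!fold_resolved) {
    rdm <- apply(rdm, c(2, 3, 4), mean)
    dimnames(rdm) <- list(NULL, stims, stims)
  } else {
    dimnames(rdm) <- list(NULL, NULL, stims, stims)
  }
  structure(rdm, stimuli = stims, class = "rdm_series")
}

#' Binary attribute model RDM
#'
#' Hypothesis matrix with 0 for within-class and 1 for cross-class stimulus
#' pairs, for identity, sex or expression, or for a pair of expressions
#' (restricted to the 16 stimuli of the two expressions). Diagonal masked NA.
#'
#' @param stimulus_set from [build_stimulus_set()].
#' @param attribute `"identity"`, `"sex"` or `"expression"`.
#' @param expression_pair optional two expressions; the model is then the
#'   16 x 16 between-expression matrix over those stimuli.
#' @return a `model_rdm` matrix with stimulus `image_id` dimnames.
#' @export
attribute_model_rdm <- function(stimulus_set, attribute = NULL,
                                expression_pair = NULL) {
  validate_stimulus_set(stimulus_set)
  if (!is.null(expression_pair)) {
    if (length(expression_pair) != 2 || !all(expression_pair %in% EXPRESSIONS)) {
      stop_invalid("unknown expressions in pair")
    }
    ss <- stimulus_set[stimulus_set$expression %in% expression_pair, ]
    cls <- ss$expression
  } else {
    if (is.null(attribute) ||
        !attribute %in% c("identity", "sex", "expression")) {
      stop_invalid("unknown attribute: %s", attribute %||% "<missing>")
    }
    ss <- stimulus_set
    cls <- ss[[attribute]]
  }
  ord <- order(ss$image_id)
  ss <- ss[ord, ]; cls <- cls[ord]
  m <- outer(cls, cls, FUN = `!=`) * 1
  diag(m) <- NA
  dimnames(m) <- list(ss$image_id, ss$image_id)
  structure(m, kind = "attribute-binary", class = c("model_rdm", "matrix"))
}

# 2-D linear cross-correlation of all integer shifts via FFT.
xcorr2_fft <- function(a, b) {
  ha <- nrow(a); wa <- ncol(a)
  m1 <- 2 * ha - 1; m2 <- 2 * wa - 1
  pa <- matrix(0, m1, m2); pa[1:ha, 1:wa] <- a
  pb <- matrix(0, m1, m2); pb[1:ha, 1:wa] <- b
  Re(stats::fft(stats::fft(pa) * Conj(stats::fft(pb)), inverse = TRUE)) /
    (m1 * m2)
}

#' Image dissimilarity by maximum cross-correlation
#'
#' Low-level image similarity: for each image pair, one image is translated
#' relative to the other through all integer 2-D shifts; at each shift the
#' Pearson correlation of the overlapping region is computed (images are
#' z-scored first), and the maximum over shifts with at least
#' `min_overlap_frac` of the pixels overlapping is the pair's similarity.
#' The default dissimilarity is `1 - max correlation`; the
#' `"euclidean_at_best_shift"` variant instead returns the Euclidean distance
#' of the overlapping pixels at the correlation-maximizing shift.
#'
#' The per-shift overlap statistics (sums, sums of squares, cross products)
#' are obtained with FFT cross-correlations, equivalent to the exhaustive
#' shift loop.
#'
#' @param rasters named list of equal-size numeric matrices (one per
#'   stimulus).
#' @param min_overlap_frac minimum overlapping-pixel fraction for a shift to
#'   be eligible (default 0.5).
#' @param metric `"one_minus_max_corr"` (default) or
#'   `"euclidean_at_best_shift"`.
#' @return a `model_rdm` dissimilarity matrix (diagonal NA).
#' @export
max_crosscorr_rdm <- function(rasters, min_overlap_frac = 0.5,
                              metric = c("one_minus_max_corr",
                                         "euclidean_at_best_shift")) {
  metric <- match.arg(metric)
  dims <- vapply(rasters, dim, integer(2))
  if (any(dims != dims[, 1])) stop_invalid("raster shapes differ")
  zs <- lapply(rasters, function(m) (m - mean(m)) / stats::sd(m))
  ones <- matrix(1, dims[1, 1], dims[2, 1])
  n_min <- min_overlap_frac * prod(dims[, 1])
  n_ov <- round(xcorr2_fft(ones, ones))
  valid <- n_ov >= pmax(n_min, 2)
  ns <- length(zs)
  ids <- names(rasters) %||% as.character(seq_len(ns))
  out <- matrix(NA_real_, ns, ns, dimnames = list(ids, ids))
  pre <- lapply(zs, function(a) {
    list(s = xcorr2_fft(a, ones), s2 = xcorr2_fft(a^2, ones),
         rs = xcorr2_fft(ones, a), rs2 = xcorr2_fft(ones, a^2))
  })
  for (i in seq_len(ns)) {
    for (j in i:ns) {
      a <- zs[[i]]; b <- zs[[j]]
      sab <- xcorr2_fft(a, b)
      sa <- pre[[i]]$s; sa2 <- pre[[i]]$s2
      sb <- pre[[j]]$rs; sb2 <- pre[[j]]$rs2
      va <- sa2 - sa^2 / n_ov
      vb <- sb2 - sb^2 / n_ov
      cov <- sab - sa * sb / n_ov
      denom <- sqrt(pmax(va, 0) * pmax(vb, 0))
      corr <- ifelse(valid & denom > 1e-12, cov / denom, -Inf)
      best <- which.max(corr)
      if (metric == "one_minus_max_corr") {
        val <- 1 - corr[best]
      } else {
        val <- sqrt(max(sa2[best] + sb2[best] - 2 * sab[best], 0))
      }
      out[i, j] <- val
      out[j, i] <- val
    }
  }
  diag(out) <- NA
  structure(out, kind = "max-crosscorr", metric = metric,
            class = c("model_rdm", "matrix"))
}

#' Embedding-distance model RDM
#'
#' Pairwise Euclidean distances between stimulus embedding vectors (e.g. the
#' 128-dimensional descriptors of a face-identification network).
#'
#' @param embeddings numeric matrix, one row per stimulus (rownames are
#'   stimulus ids).
#' @return a `model_rdm` (diagonal NA).
#' @export
embedding_rdm <- function(embeddings) {
  stopifnot(is.matrix(embeddings))
  m <- as.matrix(stats::dist(embeddings))
  diag(m) <- NA
  structure(m, kind = "embedding-distance", class = c("model_rdm", "matrix"))
}

#' Explicitly reorder a model RDM to a stimulus ordering
#'
#' [rsa_correlate()] refuses mismatched orderings rather than silently
#' reindexing; this helper performs the reindexing deliberately.
#'
#' @param rdm a `model_rdm` with stimulus dimnames.
#' @param stimuli target stimulus ordering (must be a permutation of, or
#'   subset of, the RDM's stimuli).
#' @return the reordered `model_rdm`.
#' @export
align_rdm <- function(rdm, stimuli) {
  if (is.null(rownames(rdm))) stop_invalid("RDM needs stimulus dimnames")
  idx <- match(stimuli, rownames(rdm))
  if (anyNA(idx)) {
    stop_invalid("stimuli absent from RDM: %s",
                 paste(stimuli[is.na(idx)], collapse = ", "))
  }
  out <- unclass(rdm)[idx, idx, drop = FALSE]
  structure(out, kind = attr(rdm, "kind"), class = c("model_rdm", "matrix"))
}

lower_vec <- function(m) m[lower.tri(m)]

# Partial rank correlation by residualization: rank-transform all vectors,
# regress the covariate ranks out of x and y, correlate the residuals.
partial_spearman <- function(x, y, covariates = list()) {
  rx <- rank(x); ry <- rank(y)
  if (!length(covariates)) return(stats::cor(rx, ry))
  z <- vapply(covariates, rank, numeric(length(x)))
  qr_z <- qr(cbind(1, z))
  stats::cor(qr.resid(qr_z, rx), qr.resid(qr_z, ry))
}

#' Correlate a neural RDM series with a model RDM
#'
#' Per timepoint (and per fold, for fold-resolved series) the lower triangles
#' of the neural and model matrices are vectorized and compared by Spearman
#' rank correlation; with covariate models a partial rank correlation is
#' computed by regressing the covariate ranks out of both vectors and
#' correlating the residuals. Fisher z (`atanh(rho)`) is returned alongside.
#' Stimulus orderings must match exactly; they are never silently reindexed.
#'
#' @param neural an `rdm_series`.
#' @param model a `model_rdm` over the same stimuli (or a subset in the same
#'   order, e.g. an expression-pair model; the neural series is then
#'   subsetted to those stimuli).
#' @param covariates list of `model_rdm` covariates (same stimuli as
#'   `model`).
#' @return an `rsa_result` data.frame: `time_ms` (index if unknown), `fold`
#'   (for fold-resolved input), `rho`, `z`.
#' @export
rsa_correlate <- function(neural, model, covariates = list()) {
  stopifnot(inherits(neural, "rdm_series"))
  stims <- attr(neural, "stimuli")
  mstims <- rownames(model)
  if (is.null(mstims)) stop_invalid("model RDM needs stimulus dimnames")
  if (!all(mstims %in% stims)) {
    stop_invalid("stimulus ordering mismatch: model stimuli absent from neural RDM")
  }
  for (cv in covariates) {
    if (!identical(rownames(cv), mstims)) {
      stop_invalid("stimulus ordering mismatch between model and covariate")
    }
  }
  sel <- match(mstims, stims)
  if (!identical(stims[sel], mstims)) {
    stop_invalid("stimulus ordering mismatch")
  }
  mv <- lower_vec(unclass(model))
  cvs <- lapply(covariates, function(cv) lower_vec(unclass(cv)))
  nd <- length(dim(neural))
  one <- function(mat) {
    nv <- lower_vec(mat[sel, sel, drop = FALSE])
    partial_spearman(nv, mv, cvs)
  }
  if (nd == 3) {
    rho <- vapply(seq_len(dim(neural)[1]),
                  function(t) one(neural[t, , ]), 1)
    out <- data.frame(time_index = seq_along(rho), rho = rho, z = atanh(rho))
  } else {
    np <- dim(neural)[1]; nt <- dim(neural)[2]
    out <- do.call(rbind, lapply(seq_len(np), function(p) {
      rho <- vapply(seq_len(nt), function(t) one(neural[p, t, , ]), 1)
      data.frame(fold = p, time_index = seq_len(nt), rho = rho,
                 z = atanh(rho))
    }))
  }
  class(out) <- c("rsa_result", "data.frame")
  out
}

#' Participant-resolved RSA series as a stats bundle
#'
#' Reshapes a fold-resolved [rsa_correlate()] result into the participant x
#' time Fisher-z matrix consumed by the stats module (null reference 0).
#'
#' @param rsa_result fold-resolved `rsa_result`.
#' @param sfreq sampling rate of the underlying series in Hz.
#' @param times optional time axis in ms.
#' @return a [series_bundle()].
#' @export
rsa_series_bundle <- function(rsa_result, sfreq, times = NULL) {
  stopifnot(inherits(rsa_result, "rsa_result"),
            "fold" %in% names(rsa_result))
  folds <- sort(unique(rsa_result$fold))
  nt <- max(rsa_result$time_index)
  z <- matrix(NA_real_, length(folds), nt)
  for (i in seq_along(folds)) {
    sub <- rsa_result[rsa_result$fold == folds[i], ]
    z[i, sub$time_index] <- sub$z
  }
  series_bundle(z, chance = 0, sfreq = sfreq, times = times)
}
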