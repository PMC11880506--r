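#' Linear discriminant training with Ledoit-Wolf shrinkage
#'
#' Fits a multi-class linear discriminant with a pooled (within-class)
#' covariance shrunk toward a scaled identity by the Ledoit-Wolf intensity
#' estimated from the class-centered data. Shrinkage keeps the discriminant
#' well-conditioned when channels approach (or exceed) trials per class, as
#' in searchlight-scale problems. Classes are assumed balanced (all schemes
#' here are balanced by design), so equal priors are used.
#'
#' @param x training patterns, n x p matrix.
#' @param y training labels (factor or character).
#' @param shrinkage `"ledoit-wolf"` (default) or `"none"` (plain pooled
#'   covariance, SVD-conditioned solve).
#' @return an `lda_model` with per-class weights and constants.
#' @keywords internal
lda_train <- function(x, y, shrinkage = c("ledoit-wolf", "none")) {
  shrinkage <- match.arg(shrinkage)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop_invalid("need >= 2 classes in training labels")
  n <- nrow(x); p <- ncol(x)
  mu <- t(vapply(classes, function(k) colMeans(x[y == k, , drop = FALSE]),
                 numeric(p)))
  xc <- x - mu[match(y, classes), , drop = FALSE]
  s <- crossprod(xc) / n
  if (shrinkage == "ledoit-wolf") {
    mdiag <- mean(diag(s))
    d2 <- sum((s - diag(mdiag, p))^2)
    if (d2 < .Machine$double.eps) {
      lam <- 0
    } else {
      row_norms2 <- rowSums(xc^2)
      # (1/n^2) * sum_i ||x_i x_i' - S||_F^2 = (sum ||x_i||^4 - n ||S||_F^2)/n^2
      b2 <- max(0, (sum(row_norms2^2) - n * sum(s^2)) / n^2)
      lam <- min(1, b2 / d2)
    }
    s <- (1 - lam) * s + lam * diag(mdiag, p)
  } else {
    lam <- NA_real_
    s <- s + diag(1e-10 * max(mean(diag(s)), 1), p)
  }
  w <- solve(s, t(mu))                     # p x K
  const <- -0.5 * colSums(t(mu) * w)       # K
  structure(list(classes = classes, w = w, const = const, shrinkage = lam),
            class = "lda_model")
}

lda_predict <- function(model, x) {
  scores <- x %*% model$w + rep(model$const, each = nrow(x))
  model$classes[max.col(scores, ties.method = "first")]
}

#' Train and test a linear discriminant at one timepoint
#'
#' @param train_x,test_x n x p pattern matrices (p equal across the two).
#' @param train_y,test_y labels; every test class must appear in training.
#' @param config list; `shrinkage` as in [lda_train()].
#' @return fraction of correct test predictions.
#' @export
fit_predict_timepoint <- function(train_x, train_y, test_x, test_y,
                                  config = list()) {
  if (ncol(train_x) != ncol(test_x)) {
    stop_invalid("pattern dimension differs between train (%d) and test (%d)",
                 ncol(train_x), ncol(test_x))
  }
  missing_cls <- setdiff(unique(as.character(test_y)),
                         unique(as.character(train_y)))
  if (length(missing_cls)) {
    stop_invalid("class absent from training: %s",
                 paste(missing_cls, collapse = ", "))
  }
  model <- lda_train(train_x, train_y,
                     shrinkage = config$shrinkage %||% "ledoit-wolf")
  mean(lda_predict(model, test_x) == as.character(test_y))
}

#' Specify a decoding scheme
#'
#' Targets and their theoretical chance levels: identity (8-class, 0.125),
#' sex (2-class, 0.5), emotion (4-class, 0.25), emotion_pair (2-class, 0.5,
#' restricted to two expressions given in `pair`). Generalization structure:
#' the identity scheme trains on three expressions and tests on the held-out
#' fourth; sex, emotion and pair schemes train on six sex-balanced identities
#' and test on a held-out identity.
#'
#' @param target one of `"identity"`, `"sex"`, `"emotion"`, `"emotion_pair"`.
#' @param pair for `emotion_pair`: the two expressions.
#' @param classifier list passed to [fit_predict_timepoint()].
#' @return a `scheme_spec`.
#' @export
scheme_spec <- function(target = c("identity", "sex", "emotion", "emotion_pair"),
                        pair = NULL, classifier = list()) {
  target <- match.arg(target)
  if (target == "emotion_pair") {
    if (is.null(pair) || length(pair) != 2 || !all(pair %in% EXPRESSIONS) ||
        pair[1] == pair[2]) {
      stop_invalid("emotion_pair needs two distinct expressions")
    }
  }
  n_classes <- switch(target, identity = 8, sex = 2, emotion = 4,
                      emotion_pair = 2)
  structure(list(target = target, pair = pair, chance = 1 / n_classes,
                 classifier = classifier),
            class = "scheme_spec")
}

scheme_label <- function(scheme, meta) {
  switch(scheme$target,
         identity = meta$identity,
         sex = meta$sex,
         emotion = meta$expression,
         emotion_pair = meta$expression)
}

# Stack pseudo-trials of a participant subset into one matrix per timepoint.
stack_participants <- function(pseudo, p_idx, row_filter) {
  mats <- list(); labs <- list()
  for (p in p_idx) {
    pp <- pseudo$participants[[p]]
    sel <- row_filter(pp$meta)
    if (any(sel)) {
      mats[[length(mats) + 1L]] <- pp$data[sel, , , drop = FALSE]
      labs[[length(labs) + 1L]] <- pp$meta[sel, , drop = FALSE]
    }
  }
  if (!length(mats)) return(NULL)
  d2 <- dim(mats[[1]])[2]; d3 <- dim(mats[[1]])[3]
  n <- sum(vapply(mats, function(m) dim(m)[1], 1L))
  dat <- array(NA_real_, c(n, d2, d3))
  at <- 0L
  for (m in mats) {
    dat[at + seq_len(dim(m)[1]), , ] <- m
    at <- at + dim(m)[1]
  }
  list(data = dat, meta = do.call(rbind, labs))
}

# Enumerate the held-out-condition folds of a scheme. Each fold describes
# which trials train and which test, guaranteeing structurally that neither
# the held-out participant nor the held-out condition enters training.
scheme_folds <- function(scheme, stimulus_set) {
  if (scheme$target == "identity") {
    folds <- lapply(EXPRESSIONS, function(e) {
      list(label = paste0("test_expr=", e),
           train_filter = function(meta) meta$expression != e,
           test_filter = function(meta) meta$expression == e)
    })
    return(folds)
  }
  ids <- unique(stimulus_set$identity)
  sex_of <- stats::setNames(
    vapply(ids, function(i) stimulus_set$sex[stimulus_set$identity == i][1], ""),
    ids)
  expr_ok <- if (scheme$target == "emotion_pair") {
    function(meta) meta$expression %in% scheme$pair
  } else function(meta) rep(TRUE, nrow(meta))
  folds <- list()
  for (held in ids) {
    opposite_sex <- ids[sex_of != sex_of[held]]
    # keep training sex-balanced at 3/3: the held-out identity's sex retains
    # its 3 other members, so one opposite-sex identity is dropped, rotating
    # the exclusion across folds
    for (excl in opposite_sex) {
      train_ids <- setdiff(ids, c(held, excl))
      folds[[length(folds) + 1L]] <- local({
        held_ <- held; excl_ <- excl; train_ids_ <- train_ids
        list(label = paste0("test_id=", held_, ";excl=", excl_),
             group = paste0("test_id=", held_),
             train_filter = function(meta) meta$identity %in% train_ids_ & expr_ok(meta),
             test_filter = function(meta) meta$identity == held_ & expr_ok(meta))
      })
    }
  }
  folds
}

slice_time <- function(a, t) {
  m <- a[, , t, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

run_fold_series <- function(train, test, labels_train, labels_test, scheme) {
  nt <- dim(train$data)[3]
  acc <- numeric(nt)
  for (t in seq_len(nt)) {
    acc[t] <- fit_predict_timepoint(slice_time(train$data, t), labels_train,
                                    slice_time(test$data, t), labels_test,
                                    scheme$classifier)
  }
  acc
}

#' Leave-one-participant-out decoding time course
#'
#' For each held-out participant the classifier is trained on all other
#' participants and tested on the held-out one, per timepoint, under the
#' scheme's condition generalization: identity decoding trains on three
#' expressions and tests on the fourth (4 folds per participant); sex,
#' emotion and expression-pair decoding train on six sex-balanced identities
#' (3 per sex: all three remaining identities of the held-out identity's sex
#' plus three of the other sex) and test on the held-out identity, with the
#' opposite-sex exclusion rotated and averaged (8 folds per participant
#' after averaging rotations).
#'
#' @param pseudo a `pseudo_trial_set` (or `epochs_collection`).
#' @param scheme a [scheme_spec()].
#' @param channels optional channel-name subset.
#' @return a `decoding_result`: `accuracy` array participant x fold x time,
#'   `folds` descriptor data.frame, `chance`, `times`, `scheme`.
#' @export
loso_timecourse <- function(pseudo, scheme, channels = NULL) {
  stopifnot(inherits(pseudo, "epochs_collection"),
            inherits(scheme, "scheme_spec"))
  np <- length(pseudo$participants)
  if (np < 3) stop_invalid("need >= 3 participants for leave-one-out decoding")
  pseudo <- subset_channels(pseudo, channels)
  ss <- stimulus_meta(pseudo)
  folds <- scheme_folds(scheme, ss)
  groups <- vapply(folds, function(f) f$group %||% f$label, "")
  ug <- unique(groups)
  acc <- array(NA_real_, c(np, length(ug), length(pseudo$times)),
               dimnames = list(NULL, ug, NULL))
  for (p in seq_len(np)) {
    train_p <- setdiff(seq_len(np), p)
    for (g in ug) {
      sub <- folds[groups == g]
      rot <- vapply(sub, function(f) {
        train <- stack_participants(pseudo, train_p, f$train_filter)
        test <- stack_participants(pseudo, p, f$test_filter)
        if (is.null(train) || is.null(test)) {
          stop_invalid("scheme/metadata mismatch: empty train or test set in fold %s",
                       f$label)
        }
        run_fold_series(train, test,
                        scheme_label(scheme, train$meta),
                        scheme_label(scheme, test$meta), scheme)
      }, numeric(length(pseudo$times)))
      rot <- matrix(rot, nrow = length(pseudo$times))
      acc[p, g, ] <- rowMeans(rot)
    }
  }
  structure(list(accuracy = acc, chance = scheme$chance, times = pseudo$times,
                 scheme = scheme,
                 folds = data.frame(fold = ug, stringsAsFactors = FALSE)),
            class = "decoding_result")
}

subset_channels <- function(pseudo, channels) {
  if (is.null(channels)) return(pseudo)
  idx <- match(channels, pseudo$channels)
  if (anyNA(idx)) {
    stop_invalid("unknown channels: %s",
                 paste(channels[is.na(idx)], collapse = ", "))
  }
  pseudo$participants <- lapply(pseudo$participants, function(pp) {
    pp$data <- pp$data[, idx, , drop = FALSE]
    pp
  })
  pseudo$channels <- pseudo$channels[idx]
  pseudo$layout <- pseudo$layout[idx, , drop = FALSE]
  pseudo
}

# Reconstruct the stimulus attribute table from trial metadata.
stimulus_meta <- function(pseudo) {
  m <- do.call(rbind, lapply(pseudo$participants, function(pp)
    pp$meta[, c("image_id", "identity", "sex", "expression")]))
  unique(m)
}

#' @export
print.decoding_result <- function(x, ...) {
  d <- dim(x$accuracy)
  cat(sprintf("<decoding_result> %s: %d participants x %d folds x %d timepoints, chance %.3f\n",
              x$scheme$target, d[1], d[2], d[3], x$chance))
  cat(sprintf("grand mean accuracy %.3f\n", mean(x$accuracy)))
  invisible(x)
}

#' Participant-mean accuracy series from a decoding result
#'
#' Averages over folds (and channels, for searchlight results) to the
#' participant x time matrix consumed by the stats module.
#' @param result a `decoding_result`.
#' @return a `series_bundle` (see [series_bundle()]).
#' @export
as_series_bundle <- function(result) {
  stopifnot(inherits(result, "decoding_result"))
  acc <- result$accuracy
  nd <- length(dim(acc))
  vals <- if (nd == 3) apply(acc, c(1, 3), mean) else apply(acc, c(1, 4), mean)
  series_bundle(vals, chance = result$chance,
                sfreq = infer_sfreq(result$times), times = result$times)
}

infer_sfreq <- function(times) {
  if (length(times) < 2) return(NA_real_)
  1000 / stats::median(diff(times))
}

#' Bidirectional cross-classification between two conditions
#'
#' Trains on condition A and tests on condition B and vice versa, under the
#' scheme's leave-one-participant-out fold structure; the two direction
#' accuracies are averaged within participant. Conditions are row filters on
#' the trial metadata (e.g. neutral vs angry trials).
#'
#' @param pseudo a `pseudo_trial_set`.
#' @param condition_a,condition_b functions `meta -> logical`, disjoint.
#' @param scheme a [scheme_spec()]; its own condition generalization is
#'   replaced by the A/B split (folds remain leave-one-participant-out, with
#'   the identity-rotation of sex-type schemes applied within conditions).
#' @return a `decoding_result` with direction-averaged accuracies.
#' @export
cross_classify_conditions <- function(pseudo, condition_a, condition_b, scheme) {
  stopifnot(inherits(pseudo, "epochs_collection"),
            inherits(scheme, "scheme_spec"))
  np <- length(pseudo$participants)
  if (np < 3) stop_invalid("need >= 3 participants")
  for (pp in pseudo$participants) {
    if (!any(condition_a(pp$meta)) || !any(condition_b(pp$meta))) {
      stop_invalid("empty condition subset for a participant")
    }
    if (any(condition_a(pp$meta) & condition_b(pp$meta))) {
      stop_invalid("conditions must be disjoint")
    }
  }
  nt <- length(pseudo$times)
  acc <- array(NA_real_, c(np, 1, nt))
  for (p in seq_len(np)) {
    train_p <- setdiff(seq_len(np), p)
    dir_acc <- vapply(list(c_ab = list(condition_a, condition_b),
                           c_ba = list(condition_b, condition_a)),
                      function(cond) {
      train <- stack_participants(pseudo, train_p, cond[[1]])
      test <- stack_participants(pseudo, p, cond[[2]])
      run_fold_series(train, test,
                      scheme_label(scheme, train$meta),
                      scheme_label(scheme, test$meta), scheme)
    }, numeric(nt))
    acc[p, 1, ] <- rowMeans(dir_acc)
  }
  structure(list(accuracy = acc, chance = scheme$chance, times = pseudo$times,
                 scheme = scheme,
                 folds = data.frame(fold = "cross", stringsAsFactors = FALSE)),
            class = "decoding_result")
}

#' Spatio-temporal searchlight decoding
#'
#' Repeats the leave-one-participant-out time course within each channel's
#' neighborhood (the channel plus its adjacency neighbors), yielding a
#' channel x time accuracy map per participant and fold; the channel-mean
#' series (used for onset estimation) is returned alongside.
#'
#' @param pseudo a `pseudo_trial_set`.
#' @param adjacency from [channel_adjacency()]; must cover all channels.
#' @param scheme a [scheme_spec()].
#' @return a `decoding_result` with `accuracy` participant x fold x channel x
#'   time and `channel_mean` participant x fold x time.
#' @export
searchlight_timecourse <- function(pseudo, adjacency, scheme) {
  stopifnot(inherits(pseudo, "epochs_collection"))
  missing_ch <- setdiff(pseudo$channels, names(adjacency))
  if (length(missing_ch)) {
    stop_invalid("channels missing from adjacency: %s",
                 paste(missing_ch, collapse = ", "))
  }
  per_ch <- lapply(pseudo$channels, function(ch) {
    neigh <- intersect(adjacency[[ch]], pseudo$channels)
    loso_timecourse(pseudo, scheme, channels = neigh)
  })
  d <- dim(per_ch[[1]]$accuracy)
  acc <- array(NA_real_, c(d[1], d[2], length(pseudo$channels), d[3]),
               dimnames = list(NULL, dimnames(per_ch[[1]]$accuracy)[[2]],
                               pseudo$channels, NULL))
  for (ci in seq_along(per_ch)) acc[, , ci, ] <- per_ch[[ci]]$accuracy
  structure(list(accuracy = acc, chance = scheme$chance, times = pseudo$times,
                 scheme = scheme, channels = pseudo$channels,
                 channel_mean = apply(acc, c(1, 2, 4), mean),
                 folds = per_ch[[1]]$folds),
            class = "decoding_result")
}

#' Region-of-interest decoding time courses
#'
#' Runs [loso_timecourse()] restricted to each region's channels.
#'
#' @param pseudo a `pseudo_trial_set`.
#' @param roi_map named list of channel subsets (see [roi_map()]).
#' @param scheme a [scheme_spec()].
#' @return named list of `decoding_result`, one per region.
#' @export
roi_timecourse <- function(pseudo, roi_map, scheme) {
  stopifnot(is.list(roi_map), length(roi_map) >= 1)
  lapply(roi_map, function(chs) {
    chs <- intersect(chs, pseudo$channels)
    if (!length(chs)) stop_invalid("empty ROI after channel matching")
    loso_timecourse(pseudo, scheme, channels = chs)
  })
}
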