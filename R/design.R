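#' Build the 32-image stimulus catalogue
#'
#' The stimulus space crosses 8 face identities (4 male, 4 female) with the 4
#' posed expressions happy, angry, sad and neutral, giving 32 unique images:
#' each (identity, expression) pair occurs exactly once.
#'
#' @param identity_labels character vector of 8 identity labels.
#' @param identity_sex named character vector mapping each identity label to
#'   `"male"` or `"female"`; exactly 4 of each.
#' @return a `stimulus_set`: data.frame with columns `image_id`, `identity`,
#'   `sex`, `expression` (32 rows).
#' @examples
#' ss <- build_stimulus_set()
#' nrow(ss)   # 32
#' @export
build_stimulus_set <- function(identity_labels = default_identities(),
                               identity_sex = default_identity_sex(identity_labels)) {
  if (length(identity_labels) != 8 || anyDuplicated(identity_labels)) {
    stop_invalid("invalid design: need 8 distinct identity labels")
  }
  if (!all(identity_labels %in% names(identity_sex))) {
    stop_invalid("invalid design: identity_sex must cover all identities")
  }
  sx <- identity_sex[identity_labels]
  if (!all(sx %in% SEXES) || sum(sx == "male") != 4 || sum(sx == "female") != 4) {
    stop_invalid("invalid design: need exactly 4 male and 4 female identities")
  }
  df <- expand.grid(expression = EXPRESSIONS, identity = identity_labels,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("identity", "expression")]
  df$sex <- unname(sx[df$identity])
  df$image_id <- paste(df$identity, df$expression, sep = "_")
  df <- df[, c("image_id", "identity", "sex", "expression")]
  rownames(df) <- NULL
  class(df) <- c("stimulus_set", "data.frame")
  validate_stimulus_set(df)
  df
}

default_identities <- function() {
  c("M1", "M2", "M3", "M4", "F1", "F2", "F3", "F4")
}

default_identity_sex <- function(ids) {
  # first four male, last four female by convention
  stats::setNames(rep(SEXES, each = 4), ids)
}

validate_stimulus_set <- function(ss) {
  stopifnot(is.data.frame(ss))
  if (nrow(ss) != 32 || anyDuplicated(ss$image_id)) {
    stop_invalid("invalid design: need 32 unique images")
  }
  if (length(unique(ss$identity)) != 8) stop_invalid("invalid design: need 8 identities")
  tab <- table(ss$identity, ss$expression)
  if (!all(tab == 1) || !setequal(colnames(tab), EXPRESSIONS)) {
    stop_invalid("invalid design: each identity needs each expression exactly once")
  }
  sex_per_id <- tapply(ss$sex, ss$identity, function(s) unique(s))
  if (sum(unlist(sex_per_id) == "male") != 4) {
    stop_invalid("invalid design: need 4 identities per sex")
  }
  invisible(ss)
}

#' Schedule a 2AFC session
#'
#' Builds the randomized trial schedule of the two-alternative forced-choice
#' expression task: every image is presented `repetitions` times; on each
#' presentation the veridical expression is paired with one of the three other
#' expressions as the foil, each foil serving `repetitions/3` times per image;
#' within each (image, foil) pair the correct response key alternates between
#' the left and right side (an even split when `repetitions` is divisible by
#' 12). With the default 32 images and 12 repetitions the schedule has 384
#' trials: 96 presentations per expression and 48 per identity.
#'
#' @param stimulus_set from [build_stimulus_set()].
#' @param repetitions presentations per image; must be divisible by 3.
#' @param seed integer seed controlling the presentation order and the
#'   left/right starting side.
#' @return a `trial_table`: data.frame with columns `trial_index`, `image_id`,
#'   `identity`, `sex`, `expression`, `foil_expression`, `correct_key_side`,
#'   `is_reinserted`, plus empty response columns `chosen_expression`,
#'   `correct`, `rt` (seconds) to be filled by [simulate_responder()] or an
#'   import.
#' @export
schedule_session <- function(stimulus_set, repetitions = 12, seed = 1) {
  validate_stimulus_set(stimulus_set)
  if (repetitions %% 3 != 0 || repetitions < 3) {
    stop_invalid("balance error: repetitions must be a positive multiple of 3")
  }
  per_foil <- repetitions / 3
  rows <- with_seed(substream_seed(seed, "schedule"), {
    out <- lapply(seq_len(nrow(stimulus_set)), function(i) {
      st <- stimulus_set[i, ]
      foils <- rep(setdiff(EXPRESSIONS, st$expression), each = per_foil)
      # alternate key sides within each (image, foil) pair; random start side
      sides <- unlist(lapply(seq_len(3), function(f) {
        start <- sample(c("left", "right"), 1)
        rep_len(if (start == "left") c("left", "right") else c("right", "left"),
                per_foil)
      }))
      data.frame(image_id = st$image_id, identity = st$identity, sex = st$sex,
                 expression = st$expression, foil_expression = foils,
                 correct_key_side = sides, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    out[sample.int(nrow(out)), ]
  })
  rows$trial_index <- seq_len(nrow(rows))
  rows$is_reinserted <- FALSE
  rows$chosen_expression <- NA_character_
  rows$correct <- NA
  rows$rt <- NA_real_
  rows <- rows[, c("trial_index", "image_id", "identity", "sex", "expression",
                   "foil_expression", "correct_key_side", "is_reinserted",
                   "chosen_expression", "correct", "rt")]
  rownames(rows) <- NULL
  class(rows) <- c("trial_table", "data.frame")
  rows
}

#' Simulate a responder with error re-insertion
#'
#' Plays back a scheduled session with a probabilistic responder. On each
#' trial the response is correct with the probability given for that trial's
#' expression; an incorrect trial is re-inserted at a uniformly random later
#' position of the remaining sequence (marked `is_reinserted`), so that every
#' image ends the session with exactly `repetitions` correct trials.
#'
#' @param trial_table from [schedule_session()].
#' @param accuracy_profile named numeric vector, expression -> P(correct).
#' @param rt_profile named list, expression -> `list(meanlog, sdlog)` of a
#'   log-normal RT distribution in seconds.
#' @param seed integer seed.
#' @param max_attempts per scheduled trial; exceeding it raises an error
#'   (guards against a zero-accuracy expression never terminating).
#' @return the trial table with responses filled and re-inserted trials
#'   appended in their played order; `trial_index` re-numbered to played order.
#' @export
simulate_responder <- function(trial_table, accuracy_profile,
                               rt_profile = default_rt_profile(),
                               seed = 1, max_attempts = 1000) {
  stopifnot(inherits(trial_table, "trial_table"))
  if (!all(EXPRESSIONS %in% names(accuracy_profile))) {
    stop_invalid("accuracy_profile must name all four expressions")
  }
  if (any(accuracy_profile < 0 | accuracy_profile > 1)) {
    stop_invalid("accuracy_profile values must be probabilities")
  }
  queue <- split(trial_table, seq_len(nrow(trial_table)))
  attempts <- integer(nrow(trial_table))
  played <- vector("list", 0)
  with_seed(substream_seed(seed, "responder"), {
    i <- 1L
    while (i <= length(queue)) {
      tr <- queue[[i]]
      src <- tr$trial_index[1]
      attempts[src] <- attempts[src] + 1L
      if (attempts[src] > max_attempts) {
        stop_invalid("responder did not terminate for image %s (expression %s)",
                     tr$image_id, tr$expression)
      }
      p <- accuracy_profile[[tr$expression]]
      ok <- stats::runif(1) < p
      rp <- rt_profile[[tr$expression]]
      tr$rt <- stats::rlnorm(1, rp$meanlog, rp$sdlog)
      tr$correct <- ok
      tr$chosen_expression <- if (ok) tr$expression else tr$foil_expression
      played[[length(played) + 1L]] <- tr
      if (!ok) {
        re <- tr
        re$is_reinserted <- TRUE
        re$chosen_expression <- NA_character_
        re$correct <- NA
        re$rt <- NA_real_
        pos <- if (i == length(queue)) length(queue) + 1L else
          sample(seq.int(i + 1L, length(queue) + 1L), 1)
        queue <- append(queue, list(re), after = pos - 1L)
      }
      i <- i + 1L
    }
  })
  out <- do.call(rbind, played)
  out$trial_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("trial_table", "data.frame")
  out
}

default_rt_profile <- function() {
  # medians near the observed happy-face advantage scale (~0.6-0.7 s)
  list(happy = list(meanlog = log(0.63), sdlog = 0.15),
       angry = list(meanlog = log(0.66), sdlog = 0.15),
       sad = list(meanlog = log(0.67), sdlog = 0.15),
       neutral = list(meanlog = log(0.64), sdlog = 0.15))
}

#' Summarize behavioral performance across participants
#'
#' Computes the group confusion matrix (mean percentage of each chosen
#' expression per true expression), per-expression accuracy (mean and sd
#' across participants), per-participant median RTs per expression, and
#' paired Wilcoxon signed-rank tests on median RTs for all six expression
#' pairs (p-values uncorrected). Only first presentations enter: re-inserted
#' trials are excluded.
#'
#' @param trial_tables list of completed trial tables, one per participant.
#' @return a `behavioral_report` list with elements `confusion` (4x4 matrix,
#'   rows sum to 100), `accuracy` (data.frame expression/mean/sd),
#'   `median_rt` (participant x expression matrix, seconds), `rt_tests`
#'   (data.frame pair/statistic/p), `overall_accuracy`.
#' @export
behavioral_summary <- function(trial_tables) {
  stopifnot(is.list(trial_tables), length(trial_tables) >= 2)
  firsts <- lapply(trial_tables, function(tt) {
    stopifnot(inherits(tt, "trial_table"))
    tt <- tt[!tt$is_reinserted, , drop = FALSE]
    if (anyNA(tt$correct) || anyNA(tt$chosen_expression)) {
      stop_invalid("missing responses: fill responses before summarizing")
    }
    tt
  })
  conf_per <- lapply(firsts, function(tt) {
    m <- matrix(0, 4, 4, dimnames = list(EXPRESSIONS, EXPRESSIONS))
    tab <- table(factor(tt$expression, EXPRESSIONS),
                 factor(tt$chosen_expression, EXPRESSIONS))
    m[] <- as.numeric(tab)
    100 * m / rowSums(m)
  })
  confusion <- Reduce(`+`, conf_per) / length(conf_per)
  acc_per <- t(vapply(firsts, function(tt) {
    tapply(tt$correct, factor(tt$expression, EXPRESSIONS), mean)
  }, numeric(4)))
  accuracy <- data.frame(expression = EXPRESSIONS,
                         mean = colMeans(acc_per),
                         sd = apply(acc_per, 2, stats::sd),
                         row.names = NULL)
  med_rt <- t(vapply(firsts, function(tt) {
    tapply(tt$rt, factor(tt$expression, EXPRESSIONS), stats::median)
  }, numeric(4)))
  pairs <- utils::combn(EXPRESSIONS, 2)
  rt_tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    wt <- suppressWarnings(stats::wilcox.test(med_rt[, a], med_rt[, b],
                                              paired = TRUE))
    data.frame(pair = paste(a, b, sep = " vs "),
               statistic = unname(wt$statistic), p = wt$p.value)
  }))
  out <- list(confusion = confusion, accuracy = accuracy, median_rt = med_rt,
              rt_tests = rt_tests,
              overall_accuracy = mean(vapply(firsts, function(tt) mean(tt$correct), 1)))
  class(out) <- "behavioral_report"
  out
}

#' @export
print.behavioral_report <- function(x, ...) {
  cat("Behavioral report:", nrow(x$median_rt), "participants\n")
  cat(sprintf("Overall accuracy: %.3f\n", x$overall_accuracy))
  cat("Confusion matrix (row %):\n")
  print(round(x$confusion, 1))
  invisible(x)
}

#' Round-trip a trial table to CSV
#'
#' Columns: trial_index (played order), image_id, identity, sex, expression
#' (veridical), foil_expression, correct_key_side, is_reinserted,
#' chosen_expression, correct, rt (seconds).
#' @param trial_table a `trial_table`.
#' @param path CSV path.
#' @export
write_trial_table <- function(trial_table, path) {
  stopifnot(inherits(trial_table, "trial_table"))
  utils::write.csv(as.data.frame(trial_table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$is_reinserted <- as.logical(df$is_reinserted)
  df$correct <- as.logical(df$correct)
  df$chosen_expression <- as.character(df$chosen_expression)
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Serialize a stimulus set to JSON
#' @param stimulus_set a `stimulus_set`.
#' @param path JSON path.
#' @export
write_stimulus_set <- function(stimulus_set, path) {
  validate_stimulus_set(stimulus_set)
  jsonlite::write_json(as.data.frame(stimulus_set), path, dataframe = "rows")
  invisible(path)
}

#' @rdname write_stimulus_set
#' @export
read_stimulus_set <- function(path) {
  df <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  class(df) <- c("stimulus_set", "data.frame")
  validate_stimulus_set(df)
  df
}
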