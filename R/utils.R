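#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation: every stage draws its randomness from a
# named substream of one master seed, so cohorts, schedules and permutations
# are independently reproducible.
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- 0
  for (k in utf8ToInt(as.character(name))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer((as.integer(master) %% 2147483647 + 7919 * h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

#' Expression and sex levels used throughout the package
#'
#' The stimulus space is 8 face identities (4 per sex), each photographed with
#' 4 posed expressions, giving 32 unique images.
#' @name levels-constants
#' @keywords internal
EXPRESSIONS <- c("happy", "angry", "sad", "neutral")
SEXES <- c("male", "female")
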