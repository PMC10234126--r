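# Seed derivation and independent RNG streams.
#
# Cohort simulations draw every animal-day from its own stream so a single
# unit can be regenerated in isolation, and so that the same (animal, day)
# stream is reused across diet groups (paired, common-random-number design:
# group contrasts are then differences in parameters, not in noise draws).

#' Derive a reproducible sub-seed
#'
#' Maps a master seed plus small indices to a positive integer below 2^31,
#' suitable for `set.seed()`. The mapping is deterministic and does not
#' depend on the diet group, so identically indexed units share noise across
#' cohorts.
#'
#' @param master_seed Integer master seed.
#' @param ... Further non-negative integer indices (e.g. animal, day, stage).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, ...) {
  idx <- c(...)
  h <- (abs(as.numeric(master_seed)) %% 2147483647)
  for (k in idx) {
    # all intermediates stay below 2^53, so double arithmetic is exact
    h <- (h * 69069 + as.numeric(k) * 48271 + 1013904223) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

# A stream is a closure holding its own .Random.seed state; draws swap the
# state in, sample, and swap back, leaving the global RNG untouched.
rng_stream <- function(seed) {
  old <- .save_rng()
  set.seed(seed)
  state <- get(".Random.seed", envir = globalenv())
  .restore_rng(old)
  env <- new.env(parent = emptyenv())
  env$state <- state
  function(rfun, ...) {
    outer <- .save_rng()
    assign(".Random.seed", env$state, envir = globalenv())
    out <- rfun(...)
    env$state <- get(".Random.seed", envir = globalenv())
    .restore_rng(outer)
    out
  }
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
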