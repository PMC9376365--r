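# Internal helpers: seeding, hashing, argument checks.

#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a private RNG state; the caller's .Random.seed is
# untouched. `seed` must be a single finite number.
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max), kind = "Mersenne-Twister")
  expr
}

# Deterministic 31-bit stream seed from (master seed, subject id, stream tag).
# Polynomial string hash so each subject owns an RNG stream independent of
# cohort size or ordering.
subject_seed <- function(seed, id, stream = "") {
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(paste0(id, "/", stream))) {
    h <- (h * 1159241 + ch) %% m
  }
  as.integer(h)
}

stop_if_not_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  invisible(x)
}

# Harmonic mean (Duncan/Kramer unequal-n adjustment).
harmonic_mean <- function(x) length(x) / sum(1 / x)
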