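#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derived from the cohort seed and a tag path.
# Every stochastic draw in the generator is keyed this way so that any
# session can be re-rendered in isolation, bit-identically, from the
# cohort seed alone.
rw_subseed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_rng <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rw_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "redoxwound_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

MAX_DN <- 16383  # 14-bit camera full scale
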