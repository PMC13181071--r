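# Internal helpers shared across modules.

# Classed error so the CLI can map failures to exit codes:
# "drf_usage_error" -> 2, "drf_data_error" (and anything else classed) -> 3.
drf_stop <- function(msg, class = "drf_data_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "drf_error")))
}

drf_usage_stop <- function(msg) drf_stop(msg, class = "drf_usage_error")

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is_scalar_number(seed)) drf_stop("`seed` must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Fixed-precision number formatting used by all text writers so repeated runs
# are byte-identical.
fmt_num <- function(x, digits = 6) {
  formatC(x, format = "f", digits = digits)
}
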