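# Internal helpers shared across the package.

KELVIN0 <- 273.15

celsius_to_kelvin <- function(x) x + KELVIN0
kelvin_to_celsius <- function(x) x - KELVIN0

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream seed from a base seed and a counter, staying inside the
# 32-bit integer range so reruns are reproducible on any platform.
stream_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 16807) %%
               2147483647)
}

stopf <- function(fmt, ..., class = NULL) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "heatdose_error")))
}
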