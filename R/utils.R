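# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

## truncated-normal draws by inverse-CDF; lo/hi are hard bounds
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  stats::qnorm(
    stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd)),
    mean, sd
  )
}

## One global seed governs all generator randomness through fixed stream
## offsets, so that parents / offspring demographics / event times /
## emigration / record artifacts are independently reproducible.
.stream_offsets <- c(
  parents = 11L, demographics = 23L, events = 37L,
  emigration = 41L, artifacts = 43L, impact = 0L
)

set_stream <- function(seed, stream) {
  stopifnot(stream %in% names(.stream_offsets))
  set.seed(as.integer(seed) + .stream_offsets[[stream]])
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

stop_parage <- function(...) stop(..., call. = FALSE)
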