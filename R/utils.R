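`%||%` <- function(a, b) if (is.null(a)) b else a

# run code under a temporary RNG seed, restoring caller RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# derive a bounded sub-seed from a base seed and a small stream offset;
# keeps everything a valid 32-bit integer whatever base seed the user picks
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + stream) %% .Machine$integer.max)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
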