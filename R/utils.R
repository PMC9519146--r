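## internal helpers

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.warnf <- function(...) warning(sprintf(...), call. = FALSE)

## Derive a per-stage seed from a global one; keeps derived seeds well below
## .Machine$integer.max so they remain valid 32-bit R seeds.
.deriveSeed <- function(seed, offset) {
  (as.integer(seed) * 1009L + as.integer(offset)) %% 2000000011L
}

.checkColumns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    .stopf("file '%s' is missing required column(s): %s", path,
           paste(miss, collapse = ", "))
}
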