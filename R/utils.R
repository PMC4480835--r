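# Internal helpers.

# Save/restore the global RNG state so seeded package internals do not
# disturb the caller's random stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

.restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Derive a child seed from a base seed and stream index, kept within the
# 32-bit integer range.
.child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483647)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.label_to01 <- function(label) {
  stopifnot(all(label %in% c("neutral", "effect")))
  as.integer(label == "effect")
}
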