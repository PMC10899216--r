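# Internal helpers shared across modules.

# Round half away from zero, then integer. Plain round() in R rounds half to
# even, which would make voxel indexing platform-lore dependent; this keeps
# world_to_voxel and HU windowing symmetric and reproducible.
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_binary_array <- function(x) {
  all(x == 0 | x == 1)
}

# Multiplicative congruential spawn of a sub-seed from a master seed, kept
# below 2^31 so it is always a valid R integer seed.
spawn_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1299721 * as.double(k)) %% 2147483399) + 1L
}
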