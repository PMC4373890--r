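# Counter-based deterministic RNG.
#
# Stochastic cell rules must draw deviates that depend only on (master seed,
# spatial site, timestep, stream), never on worker layout or iteration order,
# so that a partitioned run is bit-identical to a serial run. R's stateful
# generators cannot provide that, so deviates are produced by hashing the
# counter tuple with a 32-bit avalanche mix (murmur3-style finalizer).
# All arithmetic is done on doubles holding exact integers < 2^53.

.M32 <- 2^32
.M16 <- 65536

.split16 <- function(x) list(hi = x %/% .M16, lo = x %% .M16)

.xor32 <- function(a, b) {
  a1 <- .split16(a); b1 <- .split16(b)
  bitwXor(as.integer(a1$hi), as.integer(b1$hi)) * .M16 +
    bitwXor(as.integer(a1$lo), as.integer(b1$lo))
}

.mul32 <- function(a, b) {
  a1 <- .split16(a); b1 <- .split16(b)
  (a1$lo * b1$lo + ((a1$lo * b1$hi + a1$hi * b1$lo) %% .M16) * .M16) %% .M32
}

.fmix32 <- function(h) {
  h <- .xor32(h, h %/% .M16)
  h <- .mul32(h, 2246822507)   # 0x85ebca6b
  h <- .xor32(h, h %/% 8192)
  h <- .mul32(h, 3266489909)   # 0xc2b2ae35
  .xor32(h, h %/% .M16)
}

# fold one 32-bit word into the running hash
.hmix <- function(h, k) {
  h <- .xor32(h, .mul32(k %% .M32, 2654435761))  # Knuth multiplicative constant
  .fmix32((h + 2246822519) %% .M32)
}

# Per-site base hash: folds master seed and the (possibly > 2^32) stable site
# key. Precomputed once per run and reused by every per-step draw.
.site_hash_base <- function(site_key, master_seed) {
  h <- .fmix32((master_seed %% .M32) + 2654435769)
  h <- .hmix(h, site_key %% .M32)
  .hmix(h, site_key %/% .M32)
}

.rng_from_base <- function(h_base, timestep, stream_id) {
  h <- .hmix(h_base, timestep)
  h <- .hmix(h, stream_id)
  (h + 0.5) / .M32
}

#' Counter-based per-site uniform deviate
#'
#' Returns a deterministic uniform deviate in (0, 1) for each spatial site,
#' computed by hashing `(master_seed, global_site_key, timestep, stream_id)`.
#' The deviate depends only on those four counters; in particular it is
#' independent of how the tissue is partitioned across workers and of the
#' order in which sites are visited, which is what makes domain decomposition
#' invisible to the stochastic cell rules.
#'
#' @param global_site_key numeric vector of stable site keys (see
#'   [site_index()]; any non-negative integers < 2^53 are accepted).
#' @param timestep integer simulation step the draw belongs to.
#' @param stream_id integer substream (one per stochastic rule).
#' @param master_seed integer master seed of the run.
#' @return numeric vector of deviates in (0, 1), one per key.
#' @examples
#' u1 <- site_rng(1:5, timestep = 10, stream_id = 1, master_seed = 42)
#' u2 <- site_rng(1:5, timestep = 10, stream_id = 1, master_seed = 42)
#' identical(u1, u2)
#' @export
site_rng <- function(global_site_key, timestep, stream_id, master_seed) {
  .rng_from_base(.site_hash_base(global_site_key, master_seed),
                 timestep, stream_id)
}

# Stream ids used by the engine (one per stochastic rule).
.STREAM <- list(division_place = 1L, shed = 2L, death = 3L,
                migration_choice = 4L, resolve = 5L)
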