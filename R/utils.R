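# Seed plumbing: every stochastic routine takes an explicit seed and leaves
# the caller's RNG state untouched. A master seed is split into named
# sub-streams so adding a generator never shifts existing streams.

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Deterministic polynomial hash of a string into [0, 2^31 - 2].
.string_hash <- function(text) {
  h <- 0
  for (b in utf8ToInt(text)) h <- (h * 131 + b) %% 2147483647
  h
}

# Fold the master seed with a named stream into a valid set.seed() integer.
streamSeed <- function(master, name) {
  as.integer((as.numeric(master) * 69069 + .string_hash(name)) %%
               2147483646) + 1L
}

# Hex fingerprint for run manifests (no cryptographic claim).
fnvHash <- function(text) sprintf("%08x", as.integer(.string_hash(text)))
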