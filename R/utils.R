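# Small internal utilities: content hashing and scoped RNG use.

# 31-bit polynomial rolling hash of a character string (deterministic across
# platforms; exact in double arithmetic since h * 131 + byte < 2^53)
prohl_hash <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 17
  m <- 2147483629
  for (b in bytes) h <- (h * 131 + b) %% m
  as.integer(h)
}

# combine a user seed with a content hash into a valid set.seed() value
combine_seed <- function(seed, h) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(h)) %% 2147483629)
}

# evaluate expr under set.seed(seed), restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# order-sensitive fingerprint of an arbitrary nested numeric structure;
# used to prove that fitted state is identical across code paths
fingerprint <- function(x) {
  flat <- unlist(x, use.names = TRUE)
  txt <- paste(names(flat), vapply(unname(flat), function(v) {
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
  }, character(1)), collapse = "|")
  prohl_hash(txt)
}
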