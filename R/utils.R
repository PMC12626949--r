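# Internal helpers shared across modules.

# Derive a child seed from a base seed and a stream index, staying far below
# .Machine$integer.max so callers can offset further.
.childSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 7919) %%
               2000000011)
}

# Evaluate `expr` with the RNG seeded by `seed`, restoring the caller's RNG
# state afterwards so library functions do not perturb user-level randomness.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Majority label of a character vector over {F, NF}; ties -> NA.
.majorityFN <- function(x) {
  nf <- sum(x == "F")
  nn <- sum(x == "NF")
  if (nf > nn) "F" else if (nn > nf) "NF" else NA_character_
}

.isCount <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == round(x) && x >= 0

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
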