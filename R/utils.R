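#' @keywords internal
"_PACKAGE"

# Round half away from zero. base::round() rounds half to even, which would
# make grayscale rendering examples platform-ambiguous at .5 boundaries.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Derive a per-item RNG seed from a base seed and a counter so that cohorts
# are order-independent: generating eye k alone gives the same eye as
# generating it inside a loop. Kept below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}

# Evaluate `expr` under a local RNG seeded with `seed`, restoring the global
# RNG state afterwards so library calls never perturb user simulations.
with_local_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# MD5 digest of an arbitrary R object via its serialization.
object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
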