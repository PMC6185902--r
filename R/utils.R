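## Internal helpers: logging and seed derivation.

.log <- function(...) {
  if (isTRUE(getOption("meiodrive.verbose", TRUE)))
    message("[meiodrive] ", ...)
  invisible(NULL)
}

## Deterministic child seed from (seed, index), kept inside 32-bit integer
## range so downstream set.seed() calls are portable.  One stream per window
## (or per stage) means stage-level reruns reproduce pipeline-level results.
.childSeed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

## Run expr with a locally-set RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Format numbers for text outputs without scientific notation surprises.
.num <- function(x) format(x, scientific = FALSE, trim = TRUE)
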