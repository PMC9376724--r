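# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed stream: one global seed expands into per-component
# seeds via a counter, so adding a component never perturbs the draws of
# another.  Kept strictly below 2^31 - 1 (R integers are 32-bit).
sub_seed <- function(seed, counter) {
  s <- (abs(as.numeric(seed)) %% 2147483647) + 1
  as.integer((s * 48271 + as.numeric(counter) * 1000003) %% 2147483647)
}

# Run code under a local RNG state; the caller's RNG stream is untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

as_matrix2 <- function(x, what = "x") {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix or vector", what),
         call. = FALSE)
  storage.mode(x) <- "double"
  x
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive scalar", name), call. = FALSE)
  invisible(x)
}
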