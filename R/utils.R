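# Shared internal helpers.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards, so seeded operations never perturb user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic child seeds (< 2^31) derived from one parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_rgb <- function(x, what = "patch") {
  if (!(is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L) || !is.numeric(x)) {
    stop(sprintf("%s must be an H x W x 3 numeric RGB array", what), call. = FALSE)
  }
  invisible(x)
}
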