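# Internal helpers shared across modules.

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. Keeps every stochastic function free of global
# side effects.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` child seeds from one parent seed; all randomness in the package
# flows through this so that a single integer reproduces a whole run.
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Coerce a composition argument (numeric vector, matrix or data.frame with
# one row per observation) to a numeric matrix, remembering whether the
# input was a single vector so results can be returned in kind.
as_comp_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    m <- matrix(as.numeric(x), nrow = 1L, dimnames = list(NULL, names(x)))
    attr(m, "was_vector") <- TRUE
    return(m)
  }
  storage.mode(x) <- "double"
  attr(x, "was_vector") <- FALSE
  x
}

restore_shape <- function(m, template) {
  if (isTRUE(attr(template, "was_vector"))) {
    out <- drop(m[1L, ])
    names(out) <- colnames(m)
    out
  } else {
    attr(m, "was_vector") <- NULL
    m
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
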