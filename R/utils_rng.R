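# Seed plumbing: every randomized operation derives its own child seed from
# the user's root seed and a stream label, so simulations are bit-reproducible
# given (config, seed) and independent operations do not share a stream.

.child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 100003L
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% (.Machine$integer.max - 1L))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# A persistent child RNG stream: returns function(n) drawing n uniforms in
# (-1, 1) from its own state without disturbing the global stream.
.child_rng <- function(seed, label) {
  cs <- .child_seed(seed, label)
  env <- new.env(parent = emptyenv())
  function(n) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv) else NULL
    if (is.null(env$state)) set.seed(cs)
    else assign(".Random.seed", env$state, envir = genv)
    out <- stats::runif(n, -1, 1)
    env$state <- get(".Random.seed", envir = genv)
    if (had) assign(".Random.seed", old, envir = genv)
    else rm(".Random.seed", envir = genv)
    out
  }
}
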