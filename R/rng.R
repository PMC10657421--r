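# Each randomized operation draws from its own stream, derived from
# (seed, operation name). Adding new generators therefore never perturbs
# the draws of existing ones, and callers' global RNG state is preserved.
derive_seed <- function(seed, name) {
  chars <- utf8ToInt(name)
  h <- sum(chars * seq_along(chars)) %% 2048L
  (abs(as.integer(seed)) %% 1000003L) * 2048L + h
}

with_seed <- function(seed, name, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(derive_seed(seed, name))
  expr
}
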