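# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a temporary RNG state; restores the caller's .Random.seed
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

stop_if_not_gm <- function(m) {
  if (!inherits(m, "genotype_matrix"))
    stop("expected a 'genotype_matrix' object", call. = FALSE)
}
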