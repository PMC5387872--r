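# internal helpers shared across modules

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.assertSameDrugs <- function(a, b) {
  if (!identical(drugIds(a), drugIds(b)))
    stop("drug IDs do not match between inputs (", class(a), " vs ",
         class(b), ")")
  invisible(TRUE)
}

# tr(F' (I - W) F) without forming I - W
.smoothnessCost <- function(f, w) sum(f * f) - sum(f * (w %*% f))
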