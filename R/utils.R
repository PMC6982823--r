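# Internal helpers.

# Atomic text write: write to a temp file in the same directory, then rename.
write_atomic <- function(lines, file) {
  dir.create(dirname(file), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(file), fileext = ".tmp")
  writeLines(lines, tmp)
  if (!file.rename(tmp, file)) {
    file.copy(tmp, file, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(file)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# exp() with the exponent clipped to avoid overflow in the piecewise model.
exp_clip <- function(x, cap = 700) exp(pmin(x, cap))
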