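# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream (restores .Random.seed on exit).
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

# condition map utilities: a condition map is a named character vector
# sample id -> condition label
check_condition_map <- function(samples, condition_map) {
  if (is.null(names(condition_map)))
    stop("condition map must be a named character vector (sample -> condition)",
         call. = FALSE)
  missing <- setdiff(samples, names(condition_map))
  if (length(missing))
    stop("samples without a condition: ", paste(missing, collapse = ", "),
         call. = FALSE)
  condition_map[samples]
}
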