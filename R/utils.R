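`%||%` <- function(a, b) if (is.null(a)) b else a

# condition helpers: usage errors map to CLI exit 2, data errors to exit 1
stop_usage <- function(msg, call. = FALSE) {
  stop(structure(class = c("q53_usage_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_data <- function(msg) {
  stop(structure(class = c("q53_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Run `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards so library calls never perturb user simulations.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Largest-remainder apportionment of `counts` (a named non-negative vector,
# read as proportions) to a total of n, preserving names.
apportion <- function(counts, n) {
  stopifnot(all(counts >= 0), sum(counts) > 0, n >= 0)
  exact <- counts / sum(counts) * n
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- exact - base
    take <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(counts))
}
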