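# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All stochastic operations in the package draw their RNG state from one
#' master seed through this splitter, so that independent stages (sequence
#' simulation, frequency sampling, bootstrap, permutation tests) use
#' non-overlapping, label-addressed streams while remaining fully
#' reproducible from a single integer.
#'
#' @param seed master seed (integer).
#' @param label character stream label, e.g. `"bootstrap"`.
#' @param counter optional integer counter for repeated draws on one label.
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
split_seed <- function(seed, label, counter = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  ((seed %% m) * 48271 + h * 16807 + (counter %% m) * 69621) %% m
}

# stop() with a classed condition so tests can assert on error type
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "mtphylogeo_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean of upper-triangle entries of a square matrix restricted to rows i,
# cols j (i, j index vectors); used by clade/population summaries
cross_mean <- function(m, i, j) {
  if (identical(sort(i), sort(j))) {
    if (length(i) < 2L) return(NA_real_)
    sub <- m[i, i, drop = FALSE]
    return(mean(sub[upper.tri(sub)]))
  }
  mean(m[i, j, drop = FALSE])
}
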