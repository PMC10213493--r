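# internal helpers shared across modules

# argmax with uniform random tie-breaking (uses the session RNG so that runs
# are reproducible under set.seed)
argmax_random <- function(x) {
  mx <- max(x)
  idx <- which(x >= mx - 0L * mx & x == mx)
  if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
}

# row-wise argmax of an n x k matrix with random tie-breaking, returning the
# argmax index and the max value per row
rowmax_random <- function(a) {
  idx <- max.col(a, ties.method = "random")
  list(idx = idx, val = a[cbind(seq_len(nrow(a)), idx)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, name, lo = 0, hi = 1,
                                  lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) stop(sprintf("`%s` must be a single number in %s%g, %g%s", name,
                        if (lo_open) "(" else "[", lo, hi,
                        if (hi_open) ")" else "]"), call. = FALSE)
  invisible(x)
}
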