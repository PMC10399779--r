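# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# squared Pearson correlation; returns 0 (not NA) when either side is constant
r_squared <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)^2
}

# derive a stage seed from a master seed; offsets keep stages independently
# reproducible while staying inside 32-bit integer range
derive_seed <- function(master, offset) {
  as.integer((as.double(master) * 97L + offset * 7919) %% 2147483647)
}

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1]", name))
  }
  invisible(as.numeric(x))
}
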