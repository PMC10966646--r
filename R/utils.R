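# Shared internal helpers.

# Round to nearest integer, halves away from zero (for positive input this is
# "round half up"). base::round() rounds halves to even, which does not
# reproduce the usual top-k fraction convention.
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
local_seed_eval <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive `n` independent sub-seeds from one master seed. Used to give the
# initial-batch draw, the label-noise draw and any stochastic surrogate step
# their own reproducible streams.
derive_seeds <- function(seed, n) {
  local_seed_eval(seed, sample.int(.Machine$integer.max - 1L, n))
}

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %s, got %s.", name, min,
                  paste(format(x), collapse = ", ")))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (if (strict) x <= min else x < min) {
    abort(sprintf("`%s` must be %s %s.", name, if (strict) ">" else ">=", format(min)))
  }
  as.numeric(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
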