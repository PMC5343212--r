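# Currency helpers. Dollars are carried as numeric; rounding to cents uses
# round-half-away-from-zero (commercial rounding), not banker's rounding,
# so e.g. 28.0765 -> 28.08 regardless of binary representation.

round_cents <- function(x) {
  sign(x) * floor(abs(x) * 100 + 0.5 + 1e-9) / 100
}

round_dollars <- function(x) {
  sign(x) * floor(abs(x) + 0.5 + 1e-9)
}

stopifnot_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  invisible(x)
}
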