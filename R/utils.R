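# Internal argument checking helpers. All user-facing errors are classed so
# callers (in particular run_study()) can trap them per analysis cell.

.chk_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "chankit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

.chk_number <- function(x, name, lower = -Inf, upper = Inf,
                        allow_na = FALSE, strict_lower = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || (!allow_na && is.na(x)))
    .chk_stop(sprintf("`%s` must be a single number", name),
              "chankit_invalid_parameter")
  if (!is.na(x)) {
    bad <- if (strict_lower) x <= lower else x < lower
    if (bad || x > upper)
      .chk_stop(sprintf("`%s` = %g is outside [%g, %g]%s", name, x, lower,
                        upper, if (strict_lower) " (open below)" else ""),
                "chankit_invalid_parameter")
  }
  invisible(x)
}

.chk_flag <- function(x, name) {
  if (length(x) != 1L || !is.logical(x) || is.na(x))
    .chk_stop(sprintf("`%s` must be TRUE or FALSE", name),
              "chankit_invalid_parameter")
  invisible(x)
}

# Derive a child seed from a user seed, kept inside 32-bit integer range.
.derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 1e6) * 2039 + 7919 * index) %% 2147483646L + 1L
}
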