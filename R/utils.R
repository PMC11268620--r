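# Internal helpers shared across modules.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) {
    abort("cannot normalise a zero-length vector", class = "kinconform_geometry_error")
  }
  v / n
}

dist3 <- function(a, b) vnorm(a - b)

# Run `expr` under a fixed RNG seed when `seed` is given, otherwise use the
# session RNG stream as-is.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) force(expr) else withr::with_seed(as.integer(seed), expr)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == trunc(x)
}

assert_count <- function(x, name) {
  if (!is_count(x)) {
    abort(sprintf("`%s` must be a single positive integer", name),
          class = "kinconform_input_error")
  }
  invisible(as.integer(x))
}

# Collapse a character vector of flags into one semicolon-joined string.
join_flags <- function(flags) {
  flags <- flags[nzchar(flags)]
  if (length(flags) == 0L) "" else paste(flags, collapse = ";")
}
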