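#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Derive a reproducible child seed from a global seed and a stage counter.
# Keeps the result strictly below 2^31 so it is a valid R integer seed.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 104729) %% 2147483629L)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x))
    stop_input("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x > max)
    stop_input("`%s` must be a single number in [%s, %s]", name, min, max)
  as.numeric(x)
}

# Largest principal angle (degrees) between the column spans of two matrices.
# Used in tests and reported by the recovery demo.
principal_angles <- function(a, b) {
  qa <- qr.Q(qr(a))
  qb <- qr.Q(qr(b))
  sv <- svd(crossprod(qa, qb))$d
  acos(pmin(1, pmax(-1, sv))) * 180 / pi
}

# Deterministic ordering: value descending, then label ascending.
order_desc_by <- function(value, label) {
  order(-value, label, method = "radix")
}
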