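#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select group_by summarise ungroup
#'   distinct left_join bind_rows across n desc row_number rename count pull
#' @importFrom stats approx loess isoreg predict runif setNames
#' @importFrom utils head
NULL

# Derive a reproducible sub-seed (< 2^31) from a base seed and stream indices.
# Keeps parallel-safe, per-(network, class) streams without consuming the
# global RNG between unrelated stages.
derive_seed <- function(base, ...) {
  idx <- c(...)
  s <- as.double(base %% 2147483629L)
  for (i in idx) {
    s <- (s * 48271 + as.double(i)) %% 2147483629
  }
  as.integer(s) + 1L
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state;
# when seed is NULL the expression uses the ambient RNG.
with_seed_or_ambient <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

assert_scalar_prob <- function(x, name, lo = 0, hi = 1, lo_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && x <= hi
  if (!ok) abort(sprintf("`%s` must be a single number in %s%g, %g]",
                         name, if (lo_open) "(" else "[", lo, hi))
  invisible(x)
}
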