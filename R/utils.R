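# Internal helpers: error conditions and the keyed RNG stream used by the
# generator so that every well is reproducible independent of evaluation order.

stop_hcs <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("hcs_", class), "hcs_error"), ...)
}

#' @noRd
assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_hcs(sprintf("`%s` must be a single finite number.", name),
             "parameter_error")
  }
  invisible(x)
}

# Deterministic 31-bit hash of a character key (polynomial rolling hash,
# modulus 2^31 - 1). Used to derive independent per-well seeds.
hash_key <- function(key) {
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

# Seed for the (seed, ...) RNG substream, e.g. well_seed(7, "P01-01", "B03").
well_seed <- function(seed, ...) {
  hash_key(paste(c(seed, ...), collapse = "/"))
}

# Format a (row, col) pair as a plate well id, e.g. (2, 3) -> "B03".
well_name <- function(row, col) {
  paste0(LETTERS[row], sprintf("%02d", col))
}
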