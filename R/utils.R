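# Run code under an explicit seed without disturbing the caller's RNG stream;
# a NULL seed leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# Encode L/R factors/characters as the 0/1 integers used by the C++ core.
side_to_int <- function(x) {
  out <- rep.int(NA_integer_, length(x))
  out[x == "L"] <- 0L
  out[x == "R"] <- 1L
  out
}

int_to_side <- function(x) c("L", "R")[x + 1L]

assert_columns <- function(data, cols, what = "trial table") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(data)
}

# Column lookup with a default, avoiding tibble's unknown-column warning.
col_or <- function(data, name, default) {
  if (name %in% names(data)) data[[name]] else default
}

# Standard error of a binomial proportion.
binom_se <- function(p, n) sqrt(pmax(p * (1 - p), 0) / pmax(n, 1))
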