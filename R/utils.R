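# Shared internal helpers.

GO_ACCESSION_RE <- "^GO:[0-9]{7}$"

is_go_accession <- function(x) grepl(GO_ACCESSION_RE, x)

#' Round half-up
#'
#' Rounds with ties going away from zero at the given number of decimal
#' places (so 3.125 -> 3.13 at 2 digits, 31.25 -> 31.3 at 1 digit), unlike
#' [base::round()], which rounds ties to even. Used for reporting percentage
#' cells so printed tables are reproducible digit-for-digit.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(3.125, 31.25, 68.75), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Deterministic 32-bit-safe string hash (FNV-style), used to derive per-term
# permutation streams so results are independent of set iteration order.
.string_seed <- function(x, seed) {
  h <- (seed %% 2147483647) + 1
  for (code in utf8ToInt(x)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Uppercase gene symbols; gene identity throughout the package is the
# uppercased symbol so human and mouse-derived records collide correctly.
.norm_symbol <- function(x) toupper(x)

.assert_file_exists <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
}
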