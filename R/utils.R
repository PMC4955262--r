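# Shared validation helpers and the platform-stable string hash used by the
# deterministic mock-affinity generator.

#' The 20 standard amino-acid one-letter codes
#'
#' Alphabet used to validate 9-mer peptides. Anything outside this set
#' (including ambiguity codes B, J, O, U, X, Z) is treated as non-standard.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' standardAminoAcids()
standardAminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.AA20_REGEX <- "^[ACDEFGHIKLMNPQRSTVWY]{9}$"

#' Test whether strings are valid 9-mer peptides
#'
#' A valid 9-mer has length exactly 9 and every character in the 20-letter
#' standard amino-acid alphabet.
#'
#' @param x Character vector.
#' @return Logical vector the length of \code{x}.
#' @export
#' @examples
#' isValidPeptide9(c("KVAELVHFL", "KVAELVHF", "KVAELVHFX"))
isValidPeptide9 <- function(x) {
  !is.na(x) & grepl(.AA20_REGEX, x)
}

.assertPeptide9 <- function(x, what = "peptide") {
  bad <- !isValidPeptide9(x)
  if (any(bad)) {
    stop(sprintf(
      "invalid %s (must be a 9-mer over the 20 standard amino acids): %s",
      what, paste(utils::head(x[bad], 5L), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}

# Polynomial rolling hash (multiplier 31, modulus 2^31 - 1) evaluated in double
# arithmetic; intermediates stay below 2^53 so the result is identical on every
# platform and independent of R's RNG state.
.hashString <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Split character strings into an n x 9 character matrix.
.charMatrix9 <- function(x) {
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         ncol = 9L, byrow = TRUE)
}
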