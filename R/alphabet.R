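# Canonical state order of empirical amino acid replacement matrices
# (Dayhoff/JTT/WAG layout). All index-based storage in the package uses it.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Amino acid alphabet
#'
#' The 20 amino acid one-letter codes in the conventional empirical-matrix
#' order (A, R, N, D, ...). Every 20-vector and 20 x 20 matrix in the package
#' is indexed in this order.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() AA20

# Symbols treated as missing data everywhere downstream.
MISSING_SYMBOLS <- c("-", "X")

is_missing_symbol <- function(x) x %in% MISSING_SYMBOLS
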