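.jtt_cache <- new.env(parent = emptyenv())

#' JTT exchangeabilities and reference frequencies
#'
#' Loads the Jones-Taylor-Thornton (1992) empirical amino acid replacement
#' model shipped with the package as a plain-text file in the PAML dat
#' dialect: 19 lower-triangular rows of exchangeabilities followed by a line
#' of 20 equilibrium frequencies, states ordered as [aa_alphabet()].
#'
#' The gene-specific scans replace the reference frequencies with frequencies
#' estimated from each gene's own alignment (see [estimate_f_gene()]); the
#' frequency line is returned for completeness and for use as a neutral
#' default.
#'
#' @param path Optional path to an alternative dat-format file.
#' @return List with `S`, a symmetric 20 x 20 exchangeability matrix with
#'   zero diagonal, and `freq`, the file's frequency vector normalised to
#'   sum to 1. Both carry dimnames/names in alphabet order.
#' @export
#' @examples
#' jtt <- jtt_exchangeabilities()
#' all(jtt$S == t(jtt$S))
jtt_exchangeabilities <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.jtt_cache$default)) return(.jtt_cache$default)
    path <- system.file("extdata", "jtt_paml.dat", package = "convsites",
                        mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*#", lines)])
  lines <- lines[nzchar(lines)]
  if (length(lines) < 20L)
    stop("malformed exchangeability file: expected 19 triangle rows plus a ",
         "frequency line in ", path)
  vals <- lapply(lines, function(l) as.numeric(strsplit(l, "\\s+")[[1]]))
  tri <- vals[1:19]
  if (!all(lengths(tri) == 1:19))
    stop("malformed lower-triangular block in ", path)
  S <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  for (i in 2:20) S[i, 1:(i - 1)] <- tri[[i - 1]]
  S <- S + t(S)
  freq <- vals[[20]]
  if (length(freq) != 20L || any(freq <= 0))
    stop("malformed frequency line in ", path)
  freq <- freq / sum(freq)
  names(freq) <- AA20
  out <- list(S = S, freq = freq)
  if (cache) .jtt_cache$default <- out
  out
}
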