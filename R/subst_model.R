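#' Estimate gene-specific amino acid frequencies
#'
#' Empirical residue frequencies over all cells of the alignment, with gaps
#' and unknowns excluded, plus an additive pseudocount per state. With the
#' default pseudocount of 1 every residue has positive frequency even when
#' absent from the gene, so no state is unreachable under the null process.
#'
#' @param aln An [aa_alignment()].
#' @param pseudocount Nonnegative count added to each of the 20 states.
#' @return Named numeric vector of length 20 summing to 1 (alphabet order).
#' @export
#' @examples
#' estimate_f_gene(aa_alignment(c(a = "SA")), pseudocount = 0)
estimate_f_gene <- function(aln, pseudocount = 1) {
  stopifnot(inherits(aln, "aa_alignment"), pseudocount >= 0)
  counts <- table(factor(unclass(aln), levels = AA20))
  counts <- as.numeric(counts)
  if (sum(counts) == 0 && pseudocount == 0)
    stop("alignment '", attr(aln, "gene_id"),
         "' is entirely missing data; no frequencies estimable")
  f <- counts + pseudocount
  if (sum(f) == 0)
    stop("alignment '", attr(aln, "gene_id"),
         "' is entirely missing data; no frequencies estimable")
  f <- f / sum(f)
  names(f) <- AA20
  f
}

#' Build a reversible amino acid substitution model
#'
#' Assembles the general time-reversible rate matrix `Q[a,b] = s[a,b] *
#' pi[b]` (off-diagonal) from symmetric exchangeabilities `s` and equilibrium
#' frequencies `pi`, sets the diagonal so rows sum to zero, and rescales so
#' the expected rate at equilibrium, `-sum(pi * diag(Q))`, is exactly one
#' substitution per unit branch length. An eigendecomposition of the
#' symmetrised matrix `diag(sqrt(pi)) %*% Q %*% diag(1/sqrt(pi))` is cached
#' on the object so transition matrices for any branch length are a pair of
#' dense 20 x 20 products.
#'
#' @param freq Positive frequency vector of length 20 summing to 1
#'   (tolerance 1e-8), in alphabet order.
#' @param exchangeabilities Symmetric nonnegative 20 x 20 matrix with zero
#'   diagonal; defaults to the packaged JTT values.
#' @return An object of class `subst_model`: list with `S`, `freq`, `Q`,
#'   `scale` (the pre-normalisation expected rate) and the cached spectral
#'   factors.
#' @export
build_model <- function(freq, exchangeabilities = NULL) {
  if (is.null(exchangeabilities))
    exchangeabilities <- jtt_exchangeabilities()$S
  S <- exchangeabilities
  stopifnot(is.matrix(S), all(dim(S) == c(20L, 20L)))
  if (max(abs(S - t(S))) > 1e-8) stop("exchangeabilities must be symmetric")
  if (any(S < 0)) stop("exchangeabilities must be nonnegative")
  freq <- as.numeric(freq)
  if (length(freq) != 20L) stop("frequency vector must have length 20")
  if (any(freq <= 0))
    stop("all frequencies must be positive; use a pseudocount upstream")
  if (abs(sum(freq) - 1) > 1e-8) stop("frequencies must sum to 1")
  freq <- freq / sum(freq)

  Q <- S * rep(freq, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freq * diag(Q))
  if (scale <= 0) stop("degenerate model: zero expected substitution rate")
  Q <- Q / scale
  dimnames(Q) <- list(AA20, AA20)

  # Reversible Q is similar to a symmetric matrix through diag(sqrt(pi)):
  # B = D Q D^-1 with B = B', so Q = D^-1 U L U' D with orthonormal U.
  sp <- sqrt(freq)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2   # absorb rounding; exactly symmetric by reversibility
  eig <- eigen(B, symmetric = TRUE)
  structure(list(S = S, freq = setNames(freq, AA20), Q = Q, scale = scale,
                 eig_values = eig$values,
                 left = (1 / sp) * eig$vectors,         # D^-1 U
                 right = t(eig$vectors * sp)),          # U' D
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf(
    "subst_model: 20-state reversible amino acid process (scale %.4f)\n",
    x$scale))
  invisible(x)
}

#' Transition probability matrix over a branch
#'
#' `P(t) = exp(Q t)` evaluated through the cached spectral decomposition of
#' the reversible generator. Entries more negative than -1e-12 raise an
#' error; smaller negative rounding is clipped to zero and rows are
#' renormalised (the correction is below 1e-12 per row).
#'
#' @param model A [build_model()] object.
#' @param t Branch length in expected substitutions per site, `t >= 0`.
#' @return A 20 x 20 row-stochastic matrix in alphabet order.
#' @export
transition_probabilities <- function(model, t) {
  stopifnot(inherits(model, "subst_model"))
  if (!is.finite(t) || t < 0) stop("branch length must be a finite value >= 0")
  if (t == 0) {
    P <- diag(20L)
    dimnames(P) <- list(AA20, AA20)
    return(P)
  }
  P <- model$left %*% (exp(model$eig_values * t) * model$right)
  if (min(P) < -1e-12)
    stop(sprintf("transition matrix entry %.3e < -1e-12 at t = %g", min(P), t))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(AA20, AA20)
  P
}
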