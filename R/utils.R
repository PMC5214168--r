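# Shared numerical helpers.

#' Harmonic-type coalescent constants
#'
#' \code{a_n(n)} returns \eqn{a_n = \sum_{i=1}^{n-1} 1/i}, the denominator of
#' Watterson's estimator; \code{b_n(n)} returns \eqn{\sum_{i=1}^{n-1} 1/i^2},
#' used by Tajima's D and the HKA variance forms.
#'
#' @param n Sample size in chromosomes (\code{n >= 2}).
#' @return A numeric scalar (vectorised over \code{n}).
#' @export
a_n <- function(n) {
  vapply(n, function(ni) {
    if (ni < 2) stop("sample size must be >= 2")
    sum(1 / seq_len(ni - 1))
  }, numeric(1))
}

#' @rdname a_n
#' @export
b_n <- function(n) {
  vapply(n, function(ni) {
    if (ni < 2) stop("sample size must be >= 2")
    sum(1 / seq_len(ni - 1)^2)
  }, numeric(1))
}

#' Derive a labelled sub-seed from a master seed
#'
#' Deterministic string hash of \code{label} mixed with \code{seed}, so
#' pipeline stages and scripts can draw from independent, individually
#' rerunnable random streams. Always below \code{2^31 - 1}.
#'
#' @param seed Master integer seed.
#' @param label Character stream label.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, label) {
  bytes <- utf8ToInt(label)
  h <- as.double(seed %% 2147483647L)
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h %% 2147483647)
}

# The standard genetic code on DNA codons.
GENETIC_CODE_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  stats::setNames(aas, codons)
})

# Translate one codon; returns NA for codons containing non-ACGT characters.
translate_codon <- function(codon) {
  aa <- GENETIC_CODE_TABLE[codon]
  unname(aa)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
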