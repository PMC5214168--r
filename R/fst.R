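# Population differentiation: FST with permutation significance.
#
# Estimator: FST = 1 - Hw/Ht summed over analyzable columns, where Hw is
# the unweighted mean within-group per-site heterozygosity (1 - sum p_a^2,
# population frequencies, no sample-size correction) and Ht the pooled-
# frequency heterozygosity. With identical group allele frequencies the
# estimate is exactly 0; with groups fixed for different alleles it is 1.

fst_core <- function(mat_var, groups) {
  n <- nrow(mat_var)
  glev <- unique(groups)
  ht <- 0
  hw <- 0
  for (j in seq_len(ncol(mat_var))) {
    col <- mat_var[, j]
    pt <- table(col) / n
    ht <- ht + 1 - sum(pt^2)
    hwj <- vapply(glev, function(g) {
      pg <- table(col[groups == g]) / sum(groups == g)
      1 - sum(pg^2)
    }, numeric(1))
    hw <- hw + mean(hwj)
  }
  if (ht == 0) return(NA_real_)
  1 - hw / ht
}

#' Hudson-style FST among groups with permutation significance
#'
#' @param aln A \code{locus_alignment} (typically one species' subset).
#' @param grouping Name of the metadata column defining groups
#'   (default \code{"population"}), or a vector of group labels, one per
#'   ingroup haplotype.
#' @param classes A \code{site_classification} (full-alignment).
#' @param n_perm Number of permutations of sequences among groups for the
#'   significance test; 0 skips the test.
#' @param seed Optional RNG seed for the permutations.
#' @return An object of class \code{fst_result}: \code{fst},
#'   \code{permutation_p} (add-one estimator
#'   \eqn{(1 + \#\{F_{perm} \ge F_{obs}\})/(n_{perm}+1)}), and
#'   \code{n_permutations}. \code{fst} is \code{NA} when there is no
#'   variation.
#' @export
hudson_fst <- function(aln, grouping = "population",
                       classes = classify_sites(aln),
                       n_perm = 0L, seed = NULL) {
  groups <- if (length(grouping) == 1L && is.character(grouping))
    aln$meta[[grouping]] else as.character(grouping)
  if (length(groups) != nrow(aln$mat))
    stop("grouping length does not match haplotype count")
  tab <- table(groups)
  if (length(tab) < 2L) stop("need >= 2 groups")
  if (any(tab < 2L)) stop("every group needs >= 2 sequences")

  ok <- which(!classes$class %in% c("excluded_indel", "excluded_ambiguous"))
  is_var <- vapply(ok, function(j)
    length(unique(aln$mat[, j])) > 1L, logical(1))
  mat_var <- aln$mat[, ok[is_var], drop = FALSE]

  fst <- fst_core(mat_var, groups)
  p <- NA_real_
  if (n_perm > 0L && !is.na(fst)) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      f <- fst_core(mat_var, sample(groups))
      if (!is.na(f) && f >= fst) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_perm + 1)
  }
  structure(list(locus_id = aln$locus_id, fst = fst, permutation_p = p,
                 n_permutations = as.integer(n_perm)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("FST (", x$locus_id, "): ", format(x$fst, digits = 4), sep = "")
  if (!is.na(x$permutation_p))
    cat(", permutation p = ", format(x$permutation_p, digits = 4),
        " (", x$n_permutations, " permutations)", sep = "")
  cat("\n")
  invisible(x)
}

#' Permutation p-value for observed FST
#'
#' Convenience wrapper around \code{\link{hudson_fst}} returning just the
#' add-one permutation p-value.
#'
#' @inheritParams hudson_fst
#' @param n_perm Number of permutations (default 10000).
#' @return Numeric p-value in \eqn{(0, 1]}.
#' @export
fst_permutation_test <- function(aln, grouping = "population",
                                 classes = classify_sites(aln),
                                 n_perm = 10000L, seed = NULL) {
  hudson_fst(aln, grouping, classes, n_perm = n_perm, seed = seed)$permutation_p
}
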