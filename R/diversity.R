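# Per-locus diversity statistics: S, Watterson's theta, nucleotide
# diversity, Tajima's D, divergence to the outgroup. All statistics share
# the column exclusions of classify_sites(), and all site-class filters use
# the fractional Nei-Gojobori site counts as denominators.

# Variant columns that count against a class filter. Class-only filters
# (all / noncoding / coding) select by column class; effect-based filters
# (silent / synonymous / nonsynonymous) judge each variable column by the
# functional effect of its variant on the reference codon background.
numerator_columns <- function(aln, classes, filter) {
  info <- class_filter_info(classes, filter)
  idx <- which(info$ok)
  is_var <- vapply(idx, function(j)
    length(unique(aln$mat[, j])) > 1L, logical(1))
  var_idx <- idx[is_var]
  cols <- switch(filter,
    all = var_idx,
    noncoding = var_idx[classes$class[var_idx] == "noncoding"],
    coding = var_idx[!is.na(classes$syn_w[var_idx])],
    {
      effs <- vapply(var_idx, function(j) {
        info_j <- column_variant_info(classes, j, aln$mat[, j],
                                      aln$outgroup[j])
        info_j$effect %||% NA_character_
      }, character(1))
      want <- switch(filter,
        silent = c("synonymous", "noncoding"),
        synonymous = "synonymous",
        nonsynonymous = "nonsynonymous")
      var_idx[!is.na(effs) & effs %in% want]
    })
  list(cols = cols, L = info$L)
}

#' Watterson's estimator of the population mutation rate
#'
#' @param S Number of segregating sites.
#' @param n Sample size in chromosomes (\code{n >= 2}).
#' @param L Number of analyzable sites.
#' @return Per-site \eqn{\hat\theta_W = S / (a_n L)}.
#' @export
watterson_theta <- function(S, n, L) {
  if (any(n < 2)) stop("sample size must be >= 2")
  if (any(L <= 0)) stop("L must be positive")
  S / (a_n(n) * L)
}

#' Nucleotide diversity (pi)
#'
#' Mean per-site pairwise difference over analyzable columns of the chosen
#' site class. Pairwise differences at a column are computed from allele
#' counts: \eqn{[\binom{n}{2} - \sum_a \binom{c_a}{2}] / \binom{n}{2}}.
#'
#' @param aln A \code{locus_alignment} (possibly a species subset; pass the
#'   full-alignment \code{classes} so exclusions are shared).
#' @param classes A \code{site_classification}.
#' @param filter Site class: one of \code{"all"}, \code{"silent"},
#'   \code{"synonymous"}, \code{"nonsynonymous"}, \code{"noncoding"},
#'   \code{"coding"}. Silent means synonymous + noncoding.
#' @param per_site If \code{FALSE}, return the mean pairwise difference per
#'   locus (the quantity entering Tajima's D) instead of the per-site rate.
#' @return Numeric scalar.
#' @export
pi_diversity <- function(aln, classes = classify_sites(aln), filter = "all",
                         per_site = TRUE) {
  n <- nrow(aln$mat)
  if (n < 2) stop("pi requires >= 2 sequences")
  num <- numerator_columns(aln, classes, filter)
  if (num$L <= 0)
    stop("empty class filter: no analyzable sites in class '", filter, "'")
  npairs <- choose(n, 2)
  total <- 0
  for (j in num$cols) {
    cnt <- table(aln$mat[, j])
    total <- total + (npairs - sum(choose(cnt, 2))) / npairs
  }
  if (per_site) total / num$L else total
}

#' Number of segregating sites under a class filter
#'
#' @inheritParams pi_diversity
#' @return Integer count of variant columns attributed to the class.
#' @export
segregating_sites <- function(aln, classes = classify_sites(aln),
                              filter = "all") {
  length(numerator_columns(aln, classes, filter)$cols)
}

#' Tajima's D
#'
#' The 1989 statistic \eqn{D = (\hat\pi - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}}
#' with the canonical constants. \code{pi_total} is the mean pairwise
#' difference per locus (not per site).
#'
#' @param S Segregating sites.
#' @param n Chromosomes sampled.
#' @param pi_total Mean number of pairwise differences.
#' @return The statistic, or \code{NA_real_} when undefined (\code{S = 0}).
#' @export
tajimas_d <- function(S, n, pi_total) {
  if (n < 2) stop("sample size must be >= 2")
  if (S == 0) return(NA_real_)
  a1 <- a_n(n)
  a2 <- b_n(n)
  bb1 <- (n + 1) / (3 * (n - 1))
  bb2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- bb1 - 1 / a1
  c2 <- bb2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Divergence to the outgroup
#'
#' Mean over ingroup haplotypes of the per-site difference to the outgroup
#' across analyzable class-filtered columns. Raw (uncorrected) distance by
#' default; Jukes-Cantor correction behind \code{jc}.
#'
#' @inheritParams pi_diversity
#' @param jc Apply the Jukes-Cantor correction.
#' @return Per-site divergence.
#' @export
divergence_to_outgroup <- function(aln, classes = classify_sites(aln),
                                   filter = "all", jc = FALSE) {
  info <- class_filter_info(classes, filter)
  if (info$L <= 0)
    stop("empty class filter: no analyzable sites in class '", filter, "'")
  idx <- which(info$ok)
  # columns where at least one ingroup base differs from the outgroup
  differs <- vapply(idx, function(j) any(aln$mat[, j] != aln$outgroup[j]),
                    logical(1))
  cand <- idx[differs]
  keep <- switch(filter,
    all = cand,
    noncoding = cand[classes$class[cand] == "noncoding"],
    coding = cand[!is.na(classes$syn_w[cand])],
    {
      effs <- vapply(cand, function(j) {
        info_j <- column_variant_info(classes, j, aln$mat[, j],
                                      aln$outgroup[j])
        info_j$effect %||% NA_character_
      }, character(1))
      want <- switch(filter,
        silent = c("synonymous", "noncoding"),
        synonymous = "synonymous",
        nonsynonymous = "nonsynonymous")
      cand[!is.na(effs) & effs %in% want]
    })
  total <- 0
  for (j in keep) total <- total + mean(aln$mat[, j] != aln$outgroup[j])
  d <- total / info$L
  if (jc) {
    if (d >= 0.75) stop("Jukes-Cantor correction undefined at d >= 0.75")
    d <- -0.75 * log(1 - 4 * d / 3)
  }
  d
}

#' Silent fixed-difference and polymorphism counts for HKA input
#'
#' Counts, for one species subset, the silent segregating sites (S) and the
#' silent fixed differences to the outgroup (D), together with the silent
#' site total (L).
#'
#' @param aln A single-species \code{locus_alignment}
#'   (see \code{\link{subset_species}}).
#' @param classes The full-alignment \code{site_classification}.
#' @return Named list \code{S}, \code{D}, \code{L}, \code{n}.
#' @export
silent_poly_div <- function(aln, classes = classify_sites(aln)) {
  pol <- polarize_variants(aln, classes)
  silent <- !is.na(pol$effect) & pol$effect %in% c("synonymous", "noncoding")
  info <- class_filter_info(classes, "silent")
  list(S = sum(silent & pol$status != "fixed_difference"),
       D = sum(silent & pol$status == "fixed_difference"),
       L = info$L, n = nrow(aln$mat))
}

#' Per-locus, per-species diversity summary
#'
#' One row per ingroup species with sample size, analyzable site totals,
#' and the suite of statistics over all sites and over silent sites,
#' mirroring a per-locus polymorphism table.
#'
#' @param aln A \code{locus_alignment}.
#' @param classes A \code{site_classification} of \code{aln}.
#' @return Data frame with columns \code{locus_id}, \code{species},
#'   \code{n}, \code{sites}, \code{sites_sil}, \code{S}, \code{theta_w},
#'   \code{pi}, \code{tajima_d}, \code{div}, \code{S_sil},
#'   \code{theta_w_sil}, \code{pi_sil}, \code{tajima_d_sil},
#'   \code{div_sil}.
#' @export
diversity_summary <- function(aln, classes = classify_sites(aln)) {
  species <- unique(aln$meta$species)
  rows <- lapply(species, function(sp) {
    sub <- subset_species(aln, sp)
    n <- nrow(sub$mat)
    L_all <- class_filter_info(classes, "all")$L
    L_sil <- class_filter_info(classes, "silent")$L
    S <- segregating_sites(sub, classes, "all")
    S_sil <- segregating_sites(sub, classes, "silent")
    if (n >= 2) {
      pi_tot <- pi_diversity(sub, classes, "all", per_site = FALSE)
      pi_sil_tot <- pi_diversity(sub, classes, "silent", per_site = FALSE)
    } else pi_tot <- pi_sil_tot <- NA_real_
    data.frame(
      locus_id = aln$locus_id, species = sp, n = n,
      sites = L_all, sites_sil = L_sil,
      S = S,
      theta_w = if (n >= 2) watterson_theta(S, n, L_all) else NA_real_,
      pi = pi_tot / L_all,
      tajima_d = if (n >= 2) tajimas_d(S, n, pi_tot) else NA_real_,
      div = divergence_to_outgroup(sub, classes, "all"),
      S_sil = S_sil,
      theta_w_sil = if (n >= 2) watterson_theta(S_sil, n, L_sil)
        else NA_real_,
      pi_sil = pi_sil_tot / L_sil,
      tajima_d_sil = if (n >= 2) tajimas_d(S_sil, n, pi_sil_tot)
        else NA_real_,
      div_sil = divergence_to_outgroup(sub, classes, "silent"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
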