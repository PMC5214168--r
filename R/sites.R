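# Site classification: indel/ambiguity exclusion, coding/noncoding layout,
# fractional synonymous site weights, and outgroup polarization of variants.

#' Classify alignment columns and exclude indel/ambiguous sites
#'
#' Columns containing \code{-} in any row (ingroup or outgroup) are marked
#' \code{excluded_indel}; gap-free columns containing \code{N} are marked
#' \code{excluded_ambiguous}. Remaining columns are \code{coding} if covered
#' by an exon interval, else \code{noncoding}. Coding columns are mapped to
#' codons on the concatenated exon sequence (after the frame offset), and
#' fractional synonymous/nonsynonymous site weights are computed per intact
#' codon of the reference haplotype (the first ingroup row) by enumerating
#' all nine single-base mutations under the standard genetic code
#' (Nei-Gojobori counting). Mutations creating a stop codon count as
#' nonsynonymous; a reference codon that is itself a stop or contains an
#' excluded/ambiguous base is skipped with a warning and contributes no
#' site weights.
#'
#' @param aln A \code{locus_alignment}.
#' @return An object of class \code{site_classification}: per-column
#'   \code{class}, codon bookkeeping, and per-column \code{syn_w} /
#'   \code{nonsyn_w} weights summing to 1 on intact-codon columns.
#' @export
classify_sites <- function(aln) {
  L <- ncol(aln$mat)
  has_gap <- apply(aln$mat == "-", 2, any) | aln$outgroup == "-"
  has_n <- apply(aln$mat == "N", 2, any) | aln$outgroup == "N"
  cls <- rep("noncoding", L)
  in_exon <- rep(FALSE, L)
  if (nrow(aln$exons))
    for (i in seq_len(nrow(aln$exons)))
      in_exon[(aln$exons$start[i] + 1L):aln$exons$end[i]] <- TRUE
  cls[in_exon] <- "coding"
  cls[has_n] <- "excluded_ambiguous"
  cls[has_gap] <- "excluded_indel"

  # Codon layout on exon-concatenated coordinates.
  exon_cols <- which(in_exon)
  codon_map <- NULL
  if (length(exon_cols) > aln$frame) {
    cds_cols <- exon_cols[(aln$frame + 1L):length(exon_cols)]
    ncod <- length(cds_cols) %/% 3L
    if (ncod > 0L)
      codon_map <- matrix(cds_cols[seq_len(3L * ncod)], ncol = 3L,
                          byrow = TRUE)
  }

  ref <- aln$mat[1L, ]
  syn_w <- rep(NA_real_, L)
  nonsyn_w <- rep(NA_real_, L)
  codon_id <- rep(NA_integer_, L)
  codon_pos <- rep(NA_integer_, L)
  intact <- logical(0)
  n_skipped <- 0L
  if (!is.null(codon_map)) {
    intact <- logical(nrow(codon_map))
    for (ci in seq_len(nrow(codon_map))) {
      cols <- codon_map[ci, ]
      codon_id[cols] <- ci
      codon_pos[cols] <- 1:3
      if (any(cls[cols] %in% c("excluded_indel", "excluded_ambiguous")))
        next
      codon <- paste(ref[cols], collapse = "")
      if (!all(ref[cols] %in% c("A", "C", "G", "T"))) next
      aa0 <- translate_codon(codon)
      if (is.na(aa0) || aa0 == "*") {
        n_skipped <- n_skipped + 1L
        next
      }
      intact[ci] <- TRUE
      for (p in 1:3) {
        nsyn <- 0L
        for (b in setdiff(c("A", "C", "G", "T"), ref[cols[p]])) {
          mut <- codon
          substr(mut, p, p) <- b
          if (identical(translate_codon(mut), aa0)) nsyn <- nsyn + 1L
        }
        syn_w[cols[p]] <- nsyn / 3
        nonsyn_w[cols[p]] <- 1 - nsyn / 3
      }
    }
  }
  if (n_skipped > 0L)
    warning("locus '", aln$locus_id, "': ", n_skipped,
            " codon(s) with a premature stop in the reference frame skipped")

  structure(list(
    class = cls, codon_map = codon_map, codon_id = codon_id,
    codon_pos = codon_pos, intact_codon = intact,
    syn_w = syn_w, nonsyn_w = nonsyn_w, ref = ref),
    class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  cat("site_classification:", length(x$class), "columns (",
      sum(x$class == "excluded_indel"), "indel-excluded,",
      sum(x$class == "excluded_ambiguous"), "ambiguous,",
      sum(x$class == "coding"), "coding,",
      sum(x$class == "noncoding"), "noncoding )\n")
  invisible(x)
}

#' Count analyzable sites per class
#'
#' Fractional synonymous and nonsynonymous site counts are summed over
#' columns of intact codons; noncoding sites are analyzable non-exon
#' columns. Coding columns falling in non-intact codons contribute to no
#' class.
#'
#' @param aln A \code{locus_alignment}.
#' @param classes Result of \code{\link{classify_sites}}; computed if
#'   missing.
#' @return Named numeric vector \code{c(nonsyn_sites, syn_sites,
#'   noncoding_sites)}.
#' @export
count_site_classes <- function(aln, classes = classify_sites(aln)) {
  ok <- !classes$class %in% c("excluded_indel", "excluded_ambiguous")
  on_intact <- !is.na(classes$codon_id) &
    classes$codon_id %in% which(classes$intact_codon)
  c(nonsyn_sites = sum(classes$nonsyn_w[ok & on_intact], na.rm = TRUE),
    syn_sites = sum(classes$syn_w[ok & on_intact], na.rm = TRUE),
    noncoding_sites = sum(ok & classes$class == "noncoding"))
}

# Columns eligible for a class filter, and the matching site-count
# denominator. Variant-effect-dependent filters (synonymous, nonsynonymous,
# silent) return all candidate columns; the per-variant effect decides
# whether a specific variant is counted against the class.
class_filter_info <- function(classes, filter = c("all", "silent",
                                                  "synonymous",
                                                  "nonsynonymous",
                                                  "noncoding", "coding")) {
  filter <- match.arg(filter)
  ok <- !classes$class %in% c("excluded_indel", "excluded_ambiguous")
  counts <- c(
    nonsyn = sum(classes$nonsyn_w[ok], na.rm = TRUE),
    syn = sum(classes$syn_w[ok], na.rm = TRUE),
    noncoding = sum(ok & classes$class == "noncoding"),
    coding_counted = sum(ok & !is.na(classes$syn_w)))
  L <- switch(filter,
    all = sum(ok),
    silent = counts[["syn"]] + counts[["noncoding"]],
    synonymous = counts[["syn"]],
    nonsynonymous = counts[["nonsyn"]],
    noncoding = counts[["noncoding"]],
    coding = counts[["coding_counted"]])
  list(filter = filter, ok = ok, L = L)
}

#' Polarize variants against the outgroup
#'
#' Scans every analyzable column. Columns with more than one ingroup allele
#' are polymorphic (attributed to species 1, species 2, or both); columns
#' monomorphic in the ingroup whose allele differs from the outgroup allele
#' are fixed differences. The functional effect of each variant is judged on
#' the codon background of the reference haplotype, substituting one variant
#' allele at a time: if the amino acid changes, the variant is nonsynonymous.
#' Variants at noncoding columns are noncoding; variants at coding columns of
#' non-intact codons have effect \code{NA}. Tri-allelic columns are retained
#' as a single segregating site; the effect is taken from the most frequent
#' derived allele and the column index is recorded in the
#' \code{multiallelic} attribute.
#'
#' @param aln A \code{locus_alignment}.
#' @param classes Result of \code{\link{classify_sites}}.
#' @return Data frame of class \code{polarized_variants}, one row per
#'   variant column: \code{pos} (0-based), \code{status}, \code{effect},
#'   \code{ref_allele}, \code{alt_allele}, \code{outgroup_allele},
#'   per-species minor allele counts.
#' @export
polarize_variants <- function(aln, classes = classify_sites(aln)) {
  ok <- which(!classes$class %in% c("excluded_indel", "excluded_ambiguous"))
  species <- unique(aln$meta$species)
  sp1 <- species[1]
  sp2 <- if (length(species) > 1L) species[2] else NA_character_
  rows1 <- aln$meta$species == sp1
  rows2 <- if (!is.na(sp2)) aln$meta$species == sp2 else rep(FALSE, nrow(aln$mat))

  out <- list()
  multiallelic <- integer(0)
  for (j in ok) {
    col <- aln$mat[, j]
    og <- aln$outgroup[j]
    info <- column_variant_info(classes, j, col, og)
    if (is.null(info)) next

    if (info$status == "polymorphic") {
      poly1 <- length(unique(col[rows1])) > 1L
      poly2 <- if (!is.na(sp2)) length(unique(col[rows2])) > 1L else FALSE
      status <- if (poly1 && poly2) "polymorphic_both"
        else if (poly2) "polymorphic_sp2" else "polymorphic_sp1"
      if (info$multi) multiallelic <- c(multiallelic, j)
    } else {
      status <- "fixed_difference"
    }
    alt <- info$alt
    eff <- info$effect
    cnt1 <- sum(col[rows1] == alt)
    cnt2 <- if (!is.na(sp2)) sum(col[rows2] == alt) else NA_integer_
    out[[length(out) + 1L]] <- data.frame(
      pos = j - 1L, status = status, effect = eff,
      ref_allele = classes$ref[j], alt_allele = alt, outgroup_allele = og,
      count_sp1 = cnt1, n_sp1 = sum(rows1),
      count_sp2 = cnt2, n_sp2 = if (!is.na(sp2)) sum(rows2) else NA_integer_,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    pos = integer(0), status = character(0), effect = character(0),
    ref_allele = character(0), alt_allele = character(0),
    outgroup_allele = character(0), count_sp1 = integer(0),
    n_sp1 = integer(0), count_sp2 = integer(0), n_sp2 = integer(0))
  attr(res, "multiallelic") <- multiallelic - 1L
  attr(res, "species") <- c(sp1, sp2)
  class(res) <- c("polarized_variants", "data.frame")
  res
}

# Summarise one analyzable column against the outgroup: NULL if invariant
# and equal to the outgroup; otherwise the variant pair (alt = most frequent
# derived allele, other = the allele it is compared against), its status and
# functional effect. Used by polarization and by class-filtered diversity.
column_variant_info <- function(classes, j, col, og) {
  alleles <- sort(unique(col))
  if (length(alleles) == 1L) {
    if (alleles == og) return(NULL)
    return(list(status = "fixed_difference", alt = alleles, other = og,
                effect = variant_effect(classes, j, alleles, og),
                multi = FALSE))
  }
  derived <- setdiff(alleles, og)
  if (length(derived) == 0L) derived <- alleles
  counts <- table(factor(col, levels = derived))
  alt <- names(which.max(counts))
  other <- if (og %in% alleles) og else {
    rest <- table(factor(col, levels = setdiff(alleles, alt)))
    names(which.max(rest))
  }
  list(status = "polymorphic", alt = alt, other = other,
       effect = variant_effect(classes, j, alt, other),
       multi = length(alleles) > 2L)
}

# Effect of the change bg -> alt at column j, evaluated on the reference
# codon background (one variant at a time). For fixed differences `bg` is
# the outgroup allele; for polymorphisms it is the other segregating allele.
variant_effect <- function(classes, j, alt, bg) {
  if (classes$class[j] == "noncoding") return("noncoding")
  ci <- classes$codon_id[j]
  if (is.na(ci) || !isTRUE(classes$intact_codon[ci])) return(NA_character_)
  cols <- classes$codon_map[ci, ]
  codon_a <- codon_b <- classes$ref[cols]
  p <- classes$codon_pos[j]
  codon_a[p] <- bg
  codon_b[p] <- alt
  aa_a <- translate_codon(paste(codon_a, collapse = ""))
  aa_b <- translate_codon(paste(codon_b, collapse = ""))
  if (is.na(aa_a) || is.na(aa_b)) return(NA_character_)
  if (identical(aa_a, aa_b)) "synonymous" else "nonsynonymous"
}
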