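# Simulation-based selection scans:
#  (a) reference-calibrated genomewide neutral null for (pi_sil, D_sil) with
#      candidate outlier flagging;
#  (b) the pi_T-S between-species differentiation test with coalescent 95%
#      confidence intervals.

#' Calibrate a genomewide neutral null from reference loci
#'
#' For each replicate a reference locus is drawn uniformly (resampling the
#' per-locus theta estimates rather than their mean, so genomewide
#' heterogeneity propagates into the null), a neutral genealogy of
#' \code{n_chrom} chromosomes is simulated, mutations are dropped at that
#' locus's theta, and per-site silent diversity and Tajima's D are recorded.
#'
#' @param reference_summaries Data frame with one row per reference locus
#'   and columns \code{theta} (per-site silent Watterson estimate) and
#'   \code{L} (silent sites); \code{diversity_summary} columns
#'   \code{theta_w_sil} / \code{sites_sil} are accepted too.
#' @param n_chrom Chromosomes to simulate (e.g. 80 or 50).
#' @param reps Number of replicates.
#' @param seed Optional RNG seed.
#' @return Object of class \code{null_distribution}: \code{points}
#'   (data frame \code{pi_sil}, \code{D}), \code{n_chrom}, \code{reps},
#'   and the calibration table.
#' @export
calibrate_null <- function(reference_summaries, n_chrom, reps = 1e4,
                           seed = NULL) {
  rs <- as.data.frame(reference_summaries)
  if (!"theta" %in% names(rs) && "theta_w_sil" %in% names(rs))
    rs$theta <- rs$theta_w_sil
  if (!"L" %in% names(rs) && "sites_sil" %in% names(rs))
    rs$L <- rs$sites_sil
  if (!all(c("theta", "L") %in% names(rs)))
    stop("reference summaries need columns theta and L")
  rs <- rs[!is.na(rs$theta), , drop = FALSE]
  if (nrow(rs) < 2L) stop(">=2 reference loci with defined theta required")
  if (all(rs$theta == 0)) stop("all reference theta estimates are zero")
  if (!is.null(seed)) set.seed(seed)

  pick <- sample.int(nrow(rs), reps, replace = TRUE)
  pi_sil <- numeric(reps)
  D <- numeric(reps)
  npairs <- choose(n_chrom, 2)
  for (r in seq_len(reps)) {
    th <- rs$theta[pick[r]] * rs$L[pick[r]]
    tree <- sim_genealogy(n_chrom)
    S <- stats::rpois(1, th / 2 * tree$total_length)
    if (S > 0) {
      branches <- which(tree$parent > 0L)
      idx <- branches[sample.int(length(branches), S, replace = TRUE,
                                 prob = tree$blen[branches])]
      counts <- tree$nleaves[idx]
      pi_tot <- sum(counts * (n_chrom - counts)) / npairs
    } else pi_tot <- 0
    pi_sil[r] <- pi_tot / rs$L[pick[r]]
    D[r] <- tajimas_d(S, n_chrom, pi_tot)
  }
  structure(list(points = data.frame(pi_sil = pi_sil, D = D),
                 n_chrom = as.integer(n_chrom), reps = as.integer(reps),
                 calibration = rs[, c("theta", "L")]),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("neutral null distribution: ", x$reps, " replicates at n = ",
      x$n_chrom, " chromosomes\n", sep = "")
  print(summary(x$points))
  invisible(x)
}

#' @description Plot the simulated (pi_sil, D) cloud with optional
#'   candidate loci overlaid (solid points where flagged).
#' @param x A \code{null_distribution}.
#' @param candidates Optional \code{outlier_report} (or data frame with
#'   \code{pi_sil}, \code{D_sil}, \code{flagged}, \code{locus}).
#' @param ... Passed to \code{plot}.
#' @rdname print.null_distribution
#' @export
plot.null_distribution <- function(x, candidates = NULL, ...) {
  pts <- x$points[!is.na(x$points$D), ]
  graphics::plot(pts$pi_sil, pts$D, pch = ".", col = "grey60",
                 xlab = expression(pi[sil]), ylab = "Tajima's D", ...)
  if (!is.null(candidates)) {
    pch <- ifelse(candidates$flagged %in% TRUE, 19, 1)
    graphics::points(candidates$pi_sil, candidates$D_sil, pch = pch,
                     col = "firebrick", cex = 1.2)
    graphics::text(candidates$pi_sil, candidates$D_sil,
                   candidates$locus, pos = 3, cex = 0.6)
  }
  invisible(x)
}

#' Plot per-locus differentiation against simulated confidence intervals
#'
#' Draws the simulated 95% interval of pi_T - pi_S per locus as bars with
#' the observed value as a diamond (solid where outside the interval).
#'
#' @param pi_ts_table Data frame with columns \code{locus}, \code{pi_TS},
#'   \code{ci_low}, \code{ci_high}, \code{significant} (the pipeline's
#'   pi_TS report).
#' @return Invisibly, the table.
#' @export
plot_pi_ts <- function(pi_ts_table) {
  t <- as.data.frame(pi_ts_table)
  n <- nrow(t)
  ylim <- range(c(t$pi_TS, t$ci_low, t$ci_high), na.rm = TRUE)
  graphics::plot(NA, xlim = c(0.5, n + 0.5), ylim = ylim, xaxt = "n",
                 xlab = "", ylab = expression(pi[T] - pi[S]))
  graphics::rect(seq_len(n) - 0.25, t$ci_low, seq_len(n) + 0.25,
                 t$ci_high, col = "grey80", border = NA)
  graphics::points(seq_len(n), t$pi_TS, pch = ifelse(t$significant, 18, 5),
                   cex = 1.4)
  graphics::axis(1, at = seq_len(n), labels = t$locus, las = 2,
                 cex.axis = 0.7)
  graphics::abline(h = 0, lty = 3)
  invisible(t)
}

#' Flag candidate loci against a simulated neutral null
#'
#' A candidate is flagged when its (pi_sil, D_sil) point falls outside the
#' empirical (1 - alpha) highest-density region of the simulated cloud,
#' estimated by density-ranking the cells of a 50 x 50 histogram of the
#' null points (candidates falling outside the null's bounding box are
#' flagged directly). Marginal percentile positions on each axis are also
#' reported so the simpler one-dimensional rule can be applied.
#'
#' @param candidate_summaries Data frame with columns \code{locus} (or
#'   \code{locus_id}), \code{pi_sil} and \code{D_sil} (or
#'   \code{tajima_d_sil}).
#' @param null A \code{null_distribution} with at least 1000 points.
#' @param alpha Flagging level (default 0.05).
#' @param bins Histogram cells per axis.
#' @return Data frame of class \code{outlier_report}: per candidate, the
#'   observed values, marginal percentiles, and \code{flagged}
#'   (\code{NA} when D is undefined).
#' @export
flag_outliers <- function(candidate_summaries, null, alpha = 0.05,
                          bins = 50L) {
  cs <- as.data.frame(candidate_summaries)
  if (!"locus" %in% names(cs) && "locus_id" %in% names(cs))
    cs$locus <- cs$locus_id
  if (!"D_sil" %in% names(cs) && "tajima_d_sil" %in% names(cs))
    cs$D_sil <- cs$tajima_d_sil
  if (!all(c("locus", "pi_sil", "D_sil") %in% names(cs)))
    stop("candidate summaries need columns locus, pi_sil, D_sil")
  pts <- null$points[!is.na(null$points$D), , drop = FALSE]
  if (nrow(pts) < 1000L) stop("null distribution needs >= 1000 points")

  brk_x <- seq(min(pts$pi_sil), max(pts$pi_sil), length.out = bins + 1L)
  brk_y <- seq(min(pts$D), max(pts$D), length.out = bins + 1L)
  bx <- findInterval(pts$pi_sil, brk_x, rightmost.closed = TRUE,
                     all.inside = TRUE)
  by <- findInterval(pts$D, brk_y, rightmost.closed = TRUE,
                     all.inside = TRUE)
  cnt <- matrix(0L, bins, bins)
  for (i in seq_along(bx)) cnt[bx[i], by[i]] <- cnt[bx[i], by[i]] + 1L
  # highest-density region: greedily keep densest cells until they hold
  # >= (1 - alpha) of the null mass
  ord <- order(as.vector(cnt), decreasing = TRUE)
  cum <- cumsum(as.vector(cnt)[ord])
  keep_k <- which(cum >= (1 - alpha) * nrow(pts))[1]
  in_hdr <- logical(bins * bins)
  in_hdr[ord[seq_len(keep_k)]] <- TRUE
  in_hdr <- matrix(in_hdr, bins, bins)

  out <- cs[, c("locus", "pi_sil", "D_sil")]
  out$pct_pi <- vapply(cs$pi_sil, function(v) mean(pts$pi_sil <= v),
                       numeric(1))
  out$pct_D <- vapply(cs$D_sil, function(v)
    if (is.na(v)) NA_real_ else mean(pts$D <= v), numeric(1))
  out$flagged <- vapply(seq_len(nrow(cs)), function(i) {
    x <- cs$pi_sil[i]
    y <- cs$D_sil[i]
    if (is.na(y)) return(NA)
    if (x < brk_x[1] || x > brk_x[bins + 1L] ||
        y < brk_y[1] || y > brk_y[bins + 1L]) return(TRUE)
    cx <- findInterval(x, brk_x, rightmost.closed = TRUE, all.inside = TRUE)
    cy <- findInterval(y, brk_y, rightmost.closed = TRUE, all.inside = TRUE)
    !in_hdr[cx, cy]
  }, logical(1))
  class(out) <- c("outlier_report", "data.frame")
  out
}

#' Between-species differentiation test (pi_T - pi_S)
#'
#' Computes pi_T (nucleotide diversity of the pooled two-species sample),
#' pi_S (mean within-species diversity) and their difference, and compares
#' the observed difference with the 2.5%/97.5% quantiles of neutral
#' coalescent replicates. The null is a single panmictic population: each
#' replicate simulates a genealogy of the pooled sample size conditioned on
#' the observed total number of segregating sites (no recombination),
#' splits the chromosomes into two pseudo-species of the observed sizes by
#' fixed block, and recomputes pi_T - pi_S.
#'
#' @param aln A two-species \code{locus_alignment}.
#' @param classes A \code{site_classification} of \code{aln}.
#' @param filter Site-class filter for the diversities (default
#'   \code{"all"}).
#' @param reps Simulation replicates (default 10000).
#' @param seed Optional RNG seed.
#' @return Object of class \code{pi_ts_result}: observed \code{pi_T},
#'   \code{pi_S}, \code{pi_TS}, simulated \code{ci_low}/\code{ci_high},
#'   \code{significant}, or a skipped marker when S = 0.
#' @export
pi_ts_test <- function(aln, classes = classify_sites(aln), filter = "all",
                       reps = 1e4, seed = NULL) {
  species <- unique(aln$meta$species)
  if (length(species) != 2L)
    stop("pi_ts_test needs both species at the locus")
  if (!is.null(seed)) set.seed(seed)
  info <- class_filter_info(classes, filter)
  L <- info$L
  n1 <- sum(aln$meta$species == species[1])
  n2 <- sum(aln$meta$species == species[2])

  pi_T <- pi_diversity(aln, classes, filter)
  pi_S <- mean(vapply(species, function(sp)
    pi_diversity(subset_species(aln, sp), classes, filter), numeric(1)))
  obs <- pi_T - pi_S
  S <- segregating_sites(aln, classes, filter)
  if (S == 0) {
    return(structure(list(
      locus_id = aln$locus_id, pi_T = pi_T, pi_S = pi_S, pi_TS = obs,
      ci_low = NA_real_, ci_high = NA_real_, significant = NA,
      skipped = "no segregating sites", reps = 0L),
      class = "pi_ts_result"))
  }

  ntot <- n1 + n2
  g1 <- seq_len(n1)
  g2 <- n1 + seq_len(n2)
  npairs_t <- choose(ntot, 2)
  npairs_1 <- choose(n1, 2)
  npairs_2 <- choose(n2, 2)
  sim <- numeric(reps)
  for (r in seq_len(reps)) {
    tree <- sim_genealogy(ntot)
    samp <- place_mutations(tree, S, "fixed_S")
    c_t <- colSums(samp$mat)
    c_1 <- colSums(samp$mat[g1, , drop = FALSE])
    c_2 <- colSums(samp$mat[g2, , drop = FALSE])
    piT <- sum(c_t * (ntot - c_t)) / npairs_t / L
    pi1 <- sum(c_1 * (n1 - c_1)) / npairs_1 / L
    pi2 <- sum(c_2 * (n2 - c_2)) / npairs_2 / L
    sim[r] <- piT - (pi1 + pi2) / 2
  }
  ci <- stats::quantile(sim, c(0.025, 0.975), names = FALSE)
  structure(list(
    locus_id = aln$locus_id, pi_T = pi_T, pi_S = pi_S, pi_TS = obs,
    ci_low = ci[1], ci_high = ci[2],
    significant = obs < ci[1] || obs > ci[2],
    skipped = NULL, reps = as.integer(reps)),
    class = "pi_ts_result")
}

#' @export
print.pi_ts_result <- function(x, ...) {
  cat("pi_T-S test (", x$locus_id, ")\n", sep = "")
  if (!is.null(x$skipped)) {
    cat("  skipped:", x$skipped, "\n")
    return(invisible(x))
  }
  cat(sprintf("  pi_T = %.5g  pi_S = %.5g  pi_T-S = %.5g\n",
              x$pi_T, x$pi_S, x$pi_TS))
  cat(sprintf("  neutral 95%% CI [%.5g, %.5g] (%d reps): %s\n",
              x$ci_low, x$ci_high, x$reps,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}
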