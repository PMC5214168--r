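# Synthetic two-species + outgroup multilocus datasets with known truth.
#
# Selection is emulated at the level of summary intensities, which is what
# the downstream estimators consume: a per-locus factor k rescales the
# within-species coalescent (diversity scaling, the mlHKA quantity), and
# replacement-site mutations are thinned/boosted by the PRF factors
# G(gamma, n) on branches that would create polymorphism and H(gamma) on
# branches that create fixed differences. Exons are built from codon
# families whose third position is four-fold degenerate and whose first and
# second positions admit only amino-acid-changing single-base mutations, so
# mutations can be threaded onto the sequence with their intended effect
# class by position alone.

# Codon families used for synthetic exons: third-position changes are
# always synonymous, first/second-position changes always nonsynonymous,
# and no family member is a stop codon.
SYNTH_CODON_PREFIX <- c("GT", "TC", "CC", "AC", "GC", "GG")

#' Default generator configuration
#'
#' Defaults emulate the study conditions the package is designed around:
#' 10 candidate and 16 reference loci; 80 and 50 chromosomes in the two
#' species; per-site silent diversity near 0.0034 and 0.0053; candidate
#' loci of 4-9 kb and reference loci of 0.4-0.7 kb; an outgroup at scaled
#' divergence T = 15; 11 and 6 populations per species with migration rates
#' chosen so FST falls in the observed ranges (roughly 0.25 and 0.15).
#'
#' @param ... Named overrides of any default field.
#' @return A \code{generator_config} list.
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_candidate = 10L,
    n_reference = 16L,
    n_chrom = c(80L, 50L),
    species = c("sp1", "sp2"),
    candidate_length = c(4000L, 9000L),
    reference_length = c(400L, 700L),
    coding_frac = c(candidate = 0.35, reference = 0.5),
    theta_sil = c(0.0034, 0.0053),  # per silent site, per species
    rep_frac = 1,                   # replacement theta / silent theta
    tau = 6,
    T_div = 15,
    demes = c(11L, 6L),
    # island-model migration rates calibrated so realized mean FST across
    # reference loci sits near 0.26 and 0.15 at the default sample design
    mig = c(55, 62),
    m_between = c(0, 0),
    k_candidate = rep(1, 10L),
    k_reference = rep(1, 16L),
    gamma_candidate = rep(0, 10L),
    gamma_reference = rep(0, 16L))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown generator_config field(s): ",
         paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$k_candidate <- rep_len(cfg$k_candidate, cfg$n_candidate)
  cfg$k_reference <- rep_len(cfg$k_reference, cfg$n_reference)
  cfg$gamma_candidate <- rep_len(cfg$gamma_candidate, cfg$n_candidate)
  cfg$gamma_reference <- rep_len(cfg$gamma_reference, cfg$n_reference)
  if (any(c(cfg$k_candidate, cfg$k_reference) <= 0))
    stop("all k must be > 0")
  if (any(cfg$theta_sil < 0) || cfg$rep_frac < 0)
    stop("rates must be >= 0")
  structure(cfg, class = "generator_config")
}

# Per-branch tip composition: counts of species-1 and species-2 tips and
# outgroup membership under every node.
branch_composition <- function(tree, n1, n2) {
  nn <- length(tree$parent)
  N <- tree$n
  c1 <- integer(nn)
  c2 <- integer(nn)
  og <- logical(nn)
  c1[seq_len(min(n1, N))] <- 1L
  if (n2 > 0) c2[n1 + seq_len(n2)] <- 1L
  og[N] <- TRUE
  c1[N] <- 0L
  for (v in (N + 1L):nn)
    if (tree$children[v, 1] > 0L) {
      kids <- tree$children[v, ]
      c1[v] <- c1[kids[1]] + c1[kids[2]]
      c2[v] <- c2[kids[1]] + c2[kids[2]]
      og[v] <- og[kids[1]] || og[kids[2]]
    }
  list(c1 = c1, c2 = c2, og = og)
}

# Generate one locus: returns the alignment plus realized truth counts.
generate_locus <- function(locus_id, class, L, coding_frac, cfg, k, gamma) {
  n1 <- cfg$n_chrom[1]
  n2 <- cfg$n_chrom[2]
  ntot <- n1 + n2
  ne_rel <- if (cfg$theta_sil[1] > 0)
    cfg$theta_sil[2] / cfg$theta_sil[1] else 1

  # exon layout: one central exon of whole codons
  coding_len <- max(0L, 3L * (round(L * coding_frac) %/% 3L))
  ex_start <- (L - coding_len) %/% 2L
  exons <- if (coding_len > 0)
    data.frame(start = ex_start, end = ex_start + coding_len)
    else NULL

  # ancestral sequence
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  syn_pos <- integer(0)
  nonsyn_pos <- integer(0)
  if (coding_len > 0) {
    ncod <- coding_len %/% 3L
    pref <- sample(SYNTH_CODON_PREFIX, ncod, replace = TRUE)
    third <- sample(c("A", "C", "G", "T"), ncod, replace = TRUE)
    cod <- paste0(pref, third)
    anc[(ex_start + 1L):(ex_start + coding_len)] <-
      unlist(strsplit(cod, ""))
    base1 <- ex_start + 3L * (seq_len(ncod) - 1L)
    syn_pos <- base1 + 3L        # 1-based column index of 3rd codon pos
    nonsyn_pos <- c(base1 + 1L, base1 + 2L)
  }
  noncod_pos <- setdiff(seq_len(L),
                        if (coding_len > 0)
                          (ex_start + 1L):(ex_start + coding_len)
                        else integer(0))
  sil_pool <- c(noncod_pos, syn_pos)
  rep_pool <- sort(nonsyn_pos)

  # genealogy
  sim <- sim_two_species_genealogy(
    n1, n2, tau = cfg$tau, T_div = cfg$T_div, demes = cfg$demes,
    mig = cfg$mig, k = k, ne_rel = ne_rel, m_between = cfg$m_between)
  tree <- sim$tree
  comp <- branch_composition(tree, n1, n2)
  branches <- which(tree$parent > 0L)
  poly_branch <- (comp$c1[branches] > 0L & comp$c1[branches] < n1) |
                 (comp$c2[branches] > 0L & comp$c2[branches] < n2)

  # mutation counts: silent neutral everywhere; replacement scaled by the
  # PRF factors on polymorphism- vs fixation-creating branches
  th_site <- cfg$theta_sil[1]
  w_sil <- tree$blen[branches]
  mult <- ifelse(poly_branch,
                 prf_polymorphism_factor(gamma, ntot),
                 prf_fixation_factor(gamma))
  w_rep <- tree$blen[branches] * mult
  n_sil <- stats::rpois(1, th_site / 2 * length(sil_pool) * sum(w_sil))
  n_rep <- stats::rpois(1, th_site * cfg$rep_frac / 2 * length(rep_pool) *
                          sum(w_rep))
  if (n_sil > length(sil_pool))
    stop("locus ", locus_id, ": silent layout too short for ", n_sil,
         " mutations")
  if (n_rep > length(rep_pool))
    stop("locus ", locus_id, ": exon layout incompatible with ", n_rep,
         " replacement mutations")

  ls <- leaf_sets(tree)
  mat <- matrix(rep(anc, each = ntot), nrow = ntot)
  og_seq <- anc
  truth_cnt <- c(P_sil_sp1 = 0L, P_sil_sp2 = 0L, D_sil_sp1 = 0L,
                 D_sil_sp2 = 0L, P_rep_sp1 = 0L, P_rep_sp2 = 0L,
                 D_rep_sp1 = 0L, D_rep_sp2 = 0L)
  apply_mutations <- function(n_mut, pool, weights, tag) {
    if (n_mut == 0L) return(invisible())
    pos <- sample(pool, n_mut)
    br <- branches[sample.int(length(branches), n_mut, replace = TRUE,
                              prob = weights)]
    for (i in seq_len(n_mut)) {
      p <- pos[i]
      b <- br[i]
      newb <- sample(setdiff(c("A", "C", "G", "T"), anc[p]), 1L)
      set <- ls[[b]]
      ing <- set[set <= ntot]
      if (length(ing)) mat[ing, p] <<- newb
      if (comp$og[b]) og_seq[p] <<- newb
      # realized truth bookkeeping per species
      for (s in 1:2) {
        cs <- if (s == 1) comp$c1[b] else comp$c2[b]
        ns <- if (s == 1) n1 else n2
        key_p <- paste0("P_", tag, "_sp", s)
        key_d <- paste0("D_", tag, "_sp", s)
        if (cs > 0L && cs < ns)
          truth_cnt[key_p] <<- truth_cnt[key_p] + 1L
        else if ((cs == ns) != comp$og[b])
          truth_cnt[key_d] <<- truth_cnt[key_d] + 1L
      }
    }
  }
  apply_mutations(n_sil, sil_pool, w_sil, "sil")
  apply_mutations(n_rep, rep_pool, w_rep, "rep")

  ids <- c(paste0(cfg$species[1], "_h", seq_len(n1)),
           paste0(cfg$species[2], "_h", seq_len(n2)))
  rownames(mat) <- ids
  meta <- data.frame(
    haplotype_id = ids,
    species = c(rep(cfg$species[1], n1), rep(cfg$species[2], n2)),
    population = sim$populations,
    stringsAsFactors = FALSE)
  aln <- locus_alignment(locus_id, mat, paste(og_seq, collapse = ""),
                         meta, exons = exons)
  truth <- data.frame(
    locus = locus_id, class = class, length = L,
    sites_sil = length(sil_pool), sites_rep = length(rep_pool),
    k = k, gamma = gamma, n_sil_mut = n_sil, n_rep_mut = n_rep,
    as.list(truth_cnt), stringsAsFactors = FALSE)
  list(aln = aln, truth = truth)
}

#' Generate a synthetic multilocus dataset with known truth
#'
#' @param config A \code{\link{generator_config}}.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @param dir Optional directory: when given, every locus is written as
#'   FASTA + metadata TSV + exon TSV (the formats
#'   \code{\link{read_locus_alignment}} consumes) plus a \code{truth.tsv}.
#' @return List with \code{alignments} (named list of
#'   \code{locus_alignment}), \code{truth} (per-locus generating and
#'   realized values), and \code{config}.
#' @export
generate_dataset <- function(config = generator_config(), seed = 1L,
                             dir = NULL) {
  set.seed(seed)
  ids <- c(sprintf("cand%02d", seq_len(config$n_candidate)),
           sprintf("ref%02d", seq_len(config$n_reference)))
  cls <- rep(c("candidate", "reference"),
             c(config$n_candidate, config$n_reference))
  lens <- c(
    round(stats::runif(config$n_candidate, config$candidate_length[1],
                       config$candidate_length[2])),
    round(stats::runif(config$n_reference, config$reference_length[1],
                       config$reference_length[2])))
  kk <- c(config$k_candidate, config$k_reference)
  gg <- c(config$gamma_candidate, config$gamma_reference)

  alignments <- list()
  truth <- list()
  for (i in seq_along(ids)) {
    frac <- config$coding_frac[[cls[i]]]
    gl <- generate_locus(ids[i], cls[i], lens[i], frac, config,
                         kk[i], gg[i])
    alignments[[ids[i]]] <- gl$aln
    truth[[i]] <- gl$truth
  }
  truth <- do.call(rbind, truth)
  truth$seed <- seed
  out <- list(alignments = alignments, truth = truth, config = config)
  if (!is.null(dir)) {
    for (a in alignments) write_locus_alignment(a, dir)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

#' Compare generating truth with pipeline estimates
#'
#' Joins a truth table with per-locus estimates by locus name and reports
#' per-locus (truth, estimate) pairs plus bias and root-mean-square error
#' for every estimate column supplied (\code{k_hat} against true \code{k},
#' \code{gamma_mean} against true \code{gamma}, \code{flagged} against
#' whether the locus was generated non-neutrally).
#'
#' @param truth Truth data frame from \code{\link{generate_dataset}}.
#' @param estimates Data frame with a \code{locus} column and any of
#'   \code{k_hat}, \code{gamma_mean}, \code{flagged}.
#' @return List: \code{table} (joined per-locus rows) and \code{metrics}
#'   (bias/RMSE per estimated quantity).
#' @export
truth_vs_estimates_report <- function(truth, estimates) {
  estimates <- as.data.frame(estimates)
  if (!"locus" %in% names(estimates)) stop("estimates need a locus column")
  missing <- setdiff(estimates$locus, truth$locus)
  if (length(missing))
    stop("estimates for unknown locus/loci: ",
         paste(missing, collapse = ", "))
  tab <- merge(truth[, intersect(c("locus", "class", "k", "gamma"),
                                 names(truth))],
               estimates, by = "locus")
  metrics <- list()
  if ("k_hat" %in% names(tab))
    metrics$k <- c(bias = mean(tab$k_hat - tab$k),
                   rmse = sqrt(mean((tab$k_hat - tab$k)^2)))
  if ("gamma_mean" %in% names(tab))
    metrics$gamma <- c(bias = mean(tab$gamma_mean - tab$gamma),
                       rmse = sqrt(mean((tab$gamma_mean - tab$gamma)^2)))
  if ("flagged" %in% names(tab)) {
    neutral <- tab$k == 1 & tab$gamma == 0
    metrics$flags <- c(
      false_positive_rate = mean(tab$flagged[neutral], na.rm = TRUE),
      true_positive_rate = if (any(!neutral))
        mean(tab$flagged[!neutral], na.rm = TRUE) else NA_real_)
  }
  list(table = tab, metrics = metrics)
}
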