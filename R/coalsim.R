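# Standard neutral coalescent simulation without recombination.
#
# Conventions (pinned by the test-suite calibration properties):
#   * time is measured in units of 2Ne generations, so the coalescence rate
#     for k lineages is k(k-1)/2 and E[height] = 1 for n = 2;
#   * theta = 4*Ne*mu per locus, and mutations fall on branches as a Poisson
#     process of rate theta/2 per unit branch length, giving E[S] = theta*a_n.

#' Simulate a neutral coalescent genealogy
#'
#' Kingman coalescent for \code{n} chromosomes: with \code{k} lineages the
#' waiting time is exponential with rate \code{k(k-1)/2}, then a uniformly
#' random pair merges.
#'
#' @param n Number of chromosomes (\code{n >= 2}).
#' @param seed Optional RNG seed.
#' @return An object of class \code{genealogy}: node times, parent pointers,
#'   per-branch lengths, leaf counts, and \code{total_length}. Nodes
#'   \code{1..n} are leaves; the root is node \code{2n-1}.
#' @export
sim_genealogy <- function(n, seed = NULL) {
  if (n < 2) stop("n must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  nn <- 2L * n - 1L
  parent <- integer(nn)
  node_time <- numeric(nn)
  children <- matrix(0L, nn, 2L)
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  for (k in seq(n, 2L)) {
    t <- t + stats::rexp(1, k * (k - 1) / 2)
    pick <- sample.int(k, 2L)
    a <- active[pick[1]]
    b <- active[pick[2]]
    parent[a] <- nxt
    parent[b] <- nxt
    children[nxt, ] <- c(a, b)
    node_time[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  finish_genealogy(n, parent, node_time, children, n_tips = n)
}

# Shared tail: branch lengths, leaf counts, total length.
finish_genealogy <- function(n, parent, node_time, children, n_tips) {
  nn <- length(parent)
  blen <- numeric(nn)
  has_parent <- parent > 0L
  blen[has_parent] <- node_time[parent[has_parent]] - node_time[has_parent]
  nleaves <- integer(nn)
  nleaves[seq_len(n_tips)] <- 1L
  for (v in (n_tips + 1L):nn)
    if (children[v, 1] > 0L)
      nleaves[v] <- nleaves[children[v, 1]] + nleaves[children[v, 2]]
  structure(list(n = n_tips, parent = parent, node_time = node_time,
                 children = children, blen = blen, nleaves = nleaves,
                 total_length = sum(blen)),
            class = "genealogy")
}

# Leaf index sets under every node, computed on demand.
leaf_sets <- function(tree) {
  nn <- length(tree$parent)
  ls <- vector("list", nn)
  for (v in seq_len(tree$n)) ls[[v]] <- v
  for (v in (tree$n + 1L):nn)
    if (tree$children[v, 1] > 0L)
      ls[[v]] <- c(ls[[tree$children[v, 1]]], ls[[tree$children[v, 2]]])
  ls
}

#' @export
print.genealogy <- function(x, ...) {
  cat("genealogy: ", x$n, " leaves, height ",
      format(max(x$node_time), digits = 4), ", total length ",
      format(x$total_length, digits = 4), " (2Ne units)\n", sep = "")
  invisible(x)
}

# Place S mutations multinomially on branches (probability proportional to
# branch length) and build the 0/1 haplotype matrix.
place_mutations <- function(tree, S, mode) {
  n <- tree$n
  if (S == 0) {
    return(structure(list(
      mat = matrix(0L, n, 0L), derived_counts = integer(0),
      positions = numeric(0), mode = mode), class = "simulated_sample"))
  }
  branches <- which(tree$parent > 0L)
  idx <- branches[sample.int(length(branches), S, replace = TRUE,
                             prob = tree$blen[branches])]
  ls <- leaf_sets(tree)
  mat <- matrix(0L, n, S)
  for (i in seq_len(S)) mat[ls[[idx[i]]], i] <- 1L
  structure(list(mat = mat, derived_counts = tree$nleaves[idx],
                 positions = sort(stats::runif(S)), mode = mode),
            class = "simulated_sample")
}

#' Drop a fixed number of segregating sites on a genealogy
#'
#' Mutations are placed conditional on the genealogy, each on a branch
#' chosen with probability proportional to branch length (multinomial
#' placement, the approach used for fixed-S confidence-interval simulation).
#'
#' @param tree A \code{genealogy}.
#' @param S Number of mutations; every mutation yields one polymorphic
#'   column.
#' @param seed Optional RNG seed.
#' @return A \code{simulated_sample}: 0/1 haplotype matrix (rows =
#'   chromosomes), derived counts, uniform positions, and the generating
#'   mode.
#' @export
drop_mutations_fixed_s <- function(tree, S, seed = NULL) {
  if (S < 0) stop("S must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  place_mutations(tree, as.integer(S), "fixed_S")
}

#' Drop mutations at a locus-wide theta
#'
#' The mutation count is Poisson with mean \code{theta/2 * total_length},
#' so that \code{E[S] = theta * a_n} under the package's conventions.
#'
#' @param tree A \code{genealogy}.
#' @param theta Locus-wide population mutation rate (\code{4*Ne*mu}).
#' @param seed Optional RNG seed.
#' @return A \code{simulated_sample}.
#' @export
drop_mutations_theta <- function(tree, theta, seed = NULL) {
  if (theta < 0) stop("theta must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  S <- stats::rpois(1, theta / 2 * tree$total_length)
  place_mutations(tree, S, "fixed_theta")
}

#' @export
print.simulated_sample <- function(x, ...) {
  cat("simulated_sample: ", nrow(x$mat), " chromosomes x ", ncol(x$mat),
      " segregating sites (mode ", x$mode, ")\n", sep = "")
  invisible(x)
}

# Summaries straight from derived counts (no matrix built): mean pairwise
# differences and Tajima's D.
counts_to_pi <- function(counts, n) {
  if (length(counts) == 0) return(0)
  sum(counts * (n - counts)) / choose(n, 2)
}

#' Simulate replicate summary statistics under the neutral model
#'
#' @param n Chromosomes per replicate.
#' @param mode \code{"fixed_theta"} or \code{"fixed_S"}.
#' @param param Locus-wide theta (fixed-theta mode) or S (fixed-S mode).
#' @param reps Number of replicates.
#' @param seed Optional RNG seed.
#' @param L Optional locus length in sites; when given, per-site \code{pi}
#'   and \code{theta_w} columns are added.
#' @return Data frame with one row per replicate: \code{S}, \code{pi}
#'   (mean pairwise differences per locus), \code{tajima_d}, and optionally
#'   \code{pi_site}, \code{theta_w_site}.
#' @export
simulate_summaries <- function(n, mode = c("fixed_theta", "fixed_S"),
                               param, reps, seed = NULL, L = NULL) {
  mode <- match.arg(mode)
  if (reps < 1) stop("reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  S_out <- integer(reps)
  pi_out <- numeric(reps)
  d_out <- numeric(reps)
  for (r in seq_len(reps)) {
    tree <- sim_genealogy(n)
    S <- if (mode == "fixed_S") as.integer(param)
      else stats::rpois(1, param / 2 * tree$total_length)
    if (S > 0) {
      branches <- which(tree$parent > 0L)
      idx <- branches[sample.int(length(branches), S, replace = TRUE,
                                 prob = tree$blen[branches])]
      counts <- tree$nleaves[idx]
      pi_out[r] <- counts_to_pi(counts, n)
    } else pi_out[r] <- 0
    S_out[r] <- S
    d_out[r] <- tajimas_d(S, n, pi_out[r])
  }
  out <- data.frame(S = S_out, pi = pi_out, tajima_d = d_out)
  if (!is.null(L)) {
    out$pi_site <- out$pi / L
    out$theta_w_site <- out$S / (a_n(n) * L)
  }
  out
}

#' Simulate a two-species genealogy with an outgroup
#'
#' Structured coalescent for two sister species splitting at \code{tau}
#' (backwards in time all surviving lineages then form one ancestral pool)
#' with an outgroup lineage joining the ancestral pool at \code{T_div}.
#' Within each species an island model across \code{demes} populations is
#' simulated: within-deme pairs coalesce and lineages migrate between demes
#' at rate \code{mig/2}. The within-species process is time-normalised so
#' that the mean pairwise coalescence time of a random within-species pair
#' equals \code{k * ne_rel_s} exactly (island-model mean pair time is
#' \eqn{1 + (1-1/d)(d-1)/mig} before normalisation), so the per-site theta
#' handed to the mutation dropper translates directly into expected
#' within-species diversity while \code{mig} controls FST:
#' \eqn{F_{ST} \approx 1 - 1/\bar T} with
#' \eqn{\bar T = 1 + (1-1/d)(d-1)/mig}.
#' \code{k} slows (k > 1) or speeds (k < 1) the within-species time scale,
#' emulating locus-specific diversity scaling; \code{ne_rel} rescales
#' species 2's coalescent relative to species 1 (time is in units of 2*Ne
#' of species 1). \code{m_between} gives optional interspecies lineage
#' exchange rates during the species phase.
#'
#' @param n1,n2 Chromosomes sampled from species 1 and 2 (either may be 0).
#' @param tau Species split time.
#' @param T_div Outgroup divergence time (\code{>= tau}).
#' @param demes Integer vector of length 2: populations per species.
#' @param mig Scaled within-species migration rates, length 2.
#' @param k Within-species coalescent scaling (locus diversity factor).
#' @param ne_rel Relative effective size of species 2 (species 1 = 1).
#' @param m_between Interspecies exchange rates (sp1 -> sp2, sp2 -> sp1),
#'   generation-level colour only.
#' @param seed Optional RNG seed.
#' @return A list: \code{tree} (a \code{genealogy} over
#'   \code{n1 + n2 + 1} tips, tips \code{1..n1} = species 1,
#'   \code{n1+1..n1+n2} = species 2, last tip = outgroup) and
#'   \code{populations} (deme label per ingroup tip).
#' @export
sim_two_species_genealogy <- function(n1, n2, tau, T_div,
                                      demes = c(1L, 1L), mig = c(1, 1),
                                      k = 1, ne_rel = 1,
                                      m_between = c(0, 0), seed = NULL) {
  if (n1 + n2 < 1) stop("need at least one ingroup chromosome")
  if (T_div < tau) stop("T_div must be >= tau")
  if (!is.null(seed)) set.seed(seed)
  N <- n1 + n2 + 1L
  nn <- 2L * N - 1L
  parent <- integer(nn)
  node_time <- numeric(nn)
  children <- matrix(0L, nn, 2L)
  nxt <- N + 1L

  # active lineages: node id, species, deme
  lin_node <- seq_len(n1 + n2)
  lin_sp <- c(rep(1L, n1), rep(2L, n2))
  lin_deme <- c(if (n1) rep_len(seq_len(demes[1]), n1) else integer(0),
                if (n2) rep_len(seq_len(demes[2]), n2) else integer(0))
  populations <- paste0("sp", lin_sp, "_pop", lin_deme)
  if (any(demes > 1L & mig <= 0))
    stop("mig must be > 0 when a species has more than one deme")
  # island-model mean pairwise coalescence time before normalisation
  tbar <- ifelse(demes > 1L, 1 + (1 - 1 / demes) * (demes - 1) / mig, 1)
  # multiply all within-species rates by this so the realised mean pair
  # time is exactly k * ne_rel_s
  rate_mult <- tbar / (c(1, ne_rel) * k)  # divides within-species rates

  merge_pair <- function(i, j, t) {
    parent[lin_node[i]] <<- nxt
    parent[lin_node[j]] <<- nxt
    children[nxt, ] <<- c(lin_node[i], lin_node[j])
    node_time[nxt] <<- t
    lin_node[i] <<- nxt
    lin_node <<- lin_node[-j]
    lin_sp <<- lin_sp[-j]
    lin_deme <<- lin_deme[-j]
    nxt <<- nxt + 1L
  }

  # Phase 1: two structured species, until tau.
  t <- 0
  repeat {
    if (length(lin_node) <= 1L) break
    # event rates
    coal_rates <- list()
    for (s in 1:2) {
      for (d in seq_len(demes[s])) {
        idx <- which(lin_sp == s & lin_deme == d)
        if (length(idx) >= 2L)
          coal_rates[[length(coal_rates) + 1L]] <- list(
            idx = idx,
            rate = demes[s] * choose(length(idx), 2) * rate_mult[s])
      }
    }
    r_coal <- sum(vapply(coal_rates, `[[`, numeric(1), "rate"))
    n_sp <- c(sum(lin_sp == 1L), sum(lin_sp == 2L))
    mig_eff <- mig * rate_mult
    r_mig <- sum(ifelse(demes > 1L, mig_eff / 2 * n_sp, 0))
    r_swap <- m_between[1] / 2 * n_sp[1] + m_between[2] / 2 * n_sp[2]
    total <- r_coal + r_mig + r_swap
    if (total == 0) { t <- tau; break }
    dt <- stats::rexp(1, total)
    if (t + dt >= tau) { t <- tau; break }
    t <- t + dt
    u <- stats::runif(1) * total
    if (u < r_coal) {
      for (ev in coal_rates) {
        u <- u - ev$rate
        if (u < 0) {
          pick <- sample.int(length(ev$idx), 2L)
          merge_pair(ev$idx[pick[1]], ev$idx[pick[2]], t)
          break
        }
      }
    } else if (u < r_coal + r_mig) {
      u <- u - r_coal
      s <- if (demes[1] > 1L && u < mig_eff[1] / 2 * n_sp[1]) 1L else 2L
      idx <- which(lin_sp == s)
      i <- idx[sample.int(length(idx), 1L)]
      cand <- setdiff(seq_len(demes[s]), lin_deme[i])
      lin_deme[i] <- cand[sample.int(length(cand), 1L)]
    } else {
      u <- u - r_coal - r_mig
      s <- if (u < m_between[1] / 2 * n_sp[1]) 1L else 2L
      idx <- which(lin_sp == s)
      i <- idx[sample.int(length(idx), 1L)]
      lin_sp[i] <- 3L - s
      lin_deme[i] <- sample.int(demes[3L - s], 1L)
    }
  }

  # Phase 2: one ancestral pool, until T_div.
  while (length(lin_node) >= 2L) {
    kk <- length(lin_node)
    dt <- stats::rexp(1, choose(kk, 2))
    if (t + dt >= T_div) break
    t <- t + dt
    pick <- sample.int(kk, 2L)
    merge_pair(pick[1], pick[2], t)
  }

  # Phase 3: outgroup lineage joins at T_div.
  t <- T_div
  lin_node <- c(lin_node, n1 + n2 + 1L)
  lin_sp <- c(lin_sp, 0L)
  lin_deme <- c(lin_deme, 1L)
  while (length(lin_node) >= 2L) {
    kk <- length(lin_node)
    t <- t + stats::rexp(1, choose(kk, 2))
    pick <- sample.int(kk, 2L)
    merge_pair(pick[1], pick[2], t)
  }

  list(tree = finish_genealogy(N, parent, node_time, children, n_tips = N),
       populations = populations)
}

#' Write simulated samples in ms-compatible text format
#'
#' Emits \code{segsites:} / \code{positions:} blocks so external tools can
#' consume replicates.
#'
#' @param samples A \code{simulated_sample} or list of them.
#' @param path Output file path.
#' @param header Command-style header line for the first row of the file.
#' @return Invisibly, \code{path}.
#' @export
write_ms <- function(samples, path, header = "popselscan coalsim") {
  if (inherits(samples, "simulated_sample")) samples <- list(samples)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, ""), con)
  for (s in samples) {
    writeLines("//", con)
    writeLines(paste("segsites:", ncol(s$mat)), con)
    if (ncol(s$mat) > 0) {
      writeLines(paste("positions:",
                       paste(sprintf("%.6f", s$positions), collapse = " ")),
                 con)
      writeLines(apply(s$mat, 1, paste, collapse = ""), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
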