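# Diversity statistics and differentiation.

test_that("watterson_theta matches hand computation", {
  expect_equal(watterson_theta(0, 10, 500), 0)
  expect_equal(watterson_theta(10, 5, 1000), 10 / ((1 + 1/2 + 1/3 + 1/4) * 1000))
  expect_equal(watterson_theta(10, 5, 1000), 0.0048)
  expect_equal(watterson_theta(5, 2, 100), 0.05)
  expect_error(watterson_theta(3, 1, 100), ">= 2")
})

test_that("pi matches simple cases and a brute-force pair oracle", {
  a <- make_aln(c(h1 = strrep("A", 100),
                  h2 = paste0("C", strrep("A", 99))), strrep("A", 100))
  expect_equal(pi_diversity(a), 0.01)

  a <- make_aln(c(h1 = "ACGT", h2 = "ACGT"), "ACGT")
  expect_equal(pi_diversity(a), 0)

  set.seed(5)
  bases <- c("A", "C", "G", "T")
  mat <- matrix(sample(bases, 4 * 10, replace = TRUE, prob = c(.7, .1, .1, .1)),
                nrow = 4)
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- paste0("h", 1:4)
  a <- make_aln(seqs, paste(sample(bases, 10, replace = TRUE), collapse = ""))
  expect_equal(pi_diversity(a), brute_pi(a$mat, 1:10, 10))
})

test_that("all statistics on a 5-haplotype toy match brute force", {
  set.seed(8)
  bases <- c("A", "C", "G", "T")
  L <- 30
  mat <- matrix("A", 5, L)
  for (j in seq_len(L))
    mat[, j] <- sample(bases, 5, replace = TRUE, prob = c(.8, .1, .05, .05))
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- paste0("h", 1:5)
  og <- sample(bases, L, replace = TRUE, prob = c(.9, .04, .03, .03))
  a <- make_aln(seqs, paste(og, collapse = ""))
  cl <- classify_sites(a)

  # S: columns with >1 allele among ingroup
  S_brute <- sum(apply(a$mat, 2, function(z) length(unique(z)) > 1))
  expect_equal(segregating_sites(a, cl), S_brute)
  # pi
  expect_equal(pi_diversity(a, cl), brute_pi(a$mat, 1:L, L))
  # theta_w
  expect_equal(watterson_theta(S_brute, 5, L),
               S_brute / (sum(1 / (1:4)) * L))
  # divergence: mean over haplotypes of per-site differences to outgroup
  div_brute <- mean(sapply(1:5, function(i) sum(a$mat[i, ] != og))) / L
  expect_equal(divergence_to_outgroup(a, cl), div_brute)
})

test_that("tajimas_d handles boundaries and matches the frozen oracle", {
  expect_true(is.na(tajimas_d(0, 10, 0)))
  # numerator identically zero
  S <- 12; n <- 8
  expect_equal(tajimas_d(S, n, S / a_n(n)), 0)
  # frozen value from an independent implementation (S=16, n=10, pi=35/9)
  expect_equal(tajimas_d(16, 10, 35 / 9), -1.446172076557919,
               tolerance = 1e-12)
})

test_that("divergence examples", {
  a <- make_aln(c(h1 = strrep("A", 100), h2 = strrep("A", 100)),
                strrep("A", 100))
  expect_equal(divergence_to_outgroup(a), 0)
  # 3 haplotypes at 2, 3, 4 diffs over 100 sites -> 0.03
  base <- strrep("A", 100)
  mk <- function(k) paste0(strrep("C", k), strrep("A", 100 - k))
  a <- make_aln(c(h1 = mk(2), h2 = mk(3), h3 = mk(4)), base)
  expect_equal(divergence_to_outgroup(a), 0.03)
})

test_that("silent class filter separates synonymous from replacement", {
  # GGT GGT | GGC GGT: third-position G->C in GGx is synonymous
  # second codon GGT -> GAT (pos 2) is nonsynonymous
  seqs <- c(h1 = "GGTGGT", h2 = "GGCGAT")
  a <- make_aln(seqs, "GGTGGT", exons = data.frame(start = 0, end = 6))
  cl <- classify_sites(a)
  expect_equal(segregating_sites(a, cl, "synonymous"), 1L)
  expect_equal(segregating_sites(a, cl, "nonsynonymous"), 1L)
  expect_equal(segregating_sites(a, cl, "silent"), 1L)
  expect_equal(segregating_sites(a, cl, "all"), 2L)
  # empty class filter errors
  expect_error(pi_diversity(a, cl, "noncoding"), "empty class filter")
})

test_that("FST is 1 for fixed differences and exactly 0 for identical pools", {
  seqs <- c(a1 = "AAAA", a2 = "AAAA", b1 = "CCCC", b2 = "CCCC")
  a <- make_aln(seqs, "AAAA", pops = c("pa", "pa", "pb", "pb"))
  expect_equal(hudson_fst(a)$fst, 1)

  # two populations with identical allele frequencies
  seqs <- c(a1 = "ACGT", a2 = "AGGA", b1 = "ACGT", b2 = "AGGA")
  a <- make_aln(seqs, "ACGT", pops = c("pa", "pa", "pb", "pb"))
  expect_equal(hudson_fst(a)$fst, 0)

  # no variation -> undefined
  seqs <- c(a1 = "AAAA", a2 = "AAAA", b1 = "AAAA", b2 = "AAAA")
  a <- make_aln(seqs, "AAAA", pops = c("pa", "pa", "pb", "pb"))
  expect_true(is.na(hudson_fst(a)$fst))
})

test_that("FST is invariant to relabeling within populations", {
  set.seed(3)
  seqs <- sapply(1:8, function(i)
    paste(sample(c("A", "C"), 20, replace = TRUE), collapse = ""))
  names(seqs) <- paste0("h", 1:8)
  pops <- rep(c("p1", "p2"), each = 4)
  a <- make_aln(seqs, seqs[[1]], pops = pops)
  f1 <- hudson_fst(a)$fst
  # permute sequence order within each population
  perm <- c(sample(1:4), sample(5:8))
  a2 <- make_aln(seqs[perm], seqs[[1]], pops = pops)
  expect_equal(hudson_fst(a2)$fst, f1)
})

test_that("FST permutation p-value respects bounds and determinism", {
  set.seed(14)
  seqs <- sapply(1:10, function(i)
    paste(sample(c("A", "G"), 30, replace = TRUE), collapse = ""))
  names(seqs) <- paste0("h", 1:10)
  pops <- rep(c("p1", "p2"), each = 5)
  a <- make_aln(seqs, seqs[[1]], pops = pops)
  p1 <- fst_permutation_test(a, n_perm = 200, seed = 7)
  p2 <- fst_permutation_test(a, n_perm = 200, seed = 7)
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 201)
  expect_lte(p1, 1)

  # strongly differentiated data: observed above all permuted values
  seqs <- c(a1 = "AAAA", a2 = "AAAA", a3 = "AAAA",
            b1 = "CCCC", b2 = "CCCC", b3 = "CCCC")
  a <- make_aln(seqs, "AAAA", pops = rep(c("pa", "pb"), each = 3))
  p <- fst_permutation_test(a, n_perm = 99, seed = 1)
  expect_lte(p, 0.15)
})

test_that("per-species summaries share site exclusions", {
  seqs <- c(s1a = "AC-TACGTA", s1b = "ACGTACGTA",
            s2a = "ACGTACTTA", s2b = "ACGTACTTA")
  a <- make_aln(seqs, "ACGTACGTA",
                species = c("sp1", "sp1", "sp2", "sp2"))
  cl <- classify_sites(a)
  d <- diversity_summary(a, cl)
  expect_equal(nrow(d), 2L)
  expect_equal(d$sites, c(8, 8))  # gap column excluded for both species
  expect_equal(d$S[d$species == "sp1"], 0L)
  expect_equal(d$S[d$species == "sp2"], 0L)
  # the G/T difference at col 7 is a fixed difference for sp2 only
  expect_gt(d$div[d$species == "sp2"], 0)
})

test_that("theta_w and pi agree in expectation on neutral simulations", {
  set.seed(21)
  reps <- 2000
  s <- simulate_summaries(12, "fixed_theta", 4, reps = reps)
  theta_hat <- s$S / a_n(12)
  dd <- theta_hat - s$pi
  # paired difference centered on 0
  expect_lt(abs(mean(dd)), 3 * sd(dd) / sqrt(reps))
  # mean theta_hat near generating theta
  expect_lt(abs(mean(theta_hat) - 4), 3 * sd(theta_hat) / sqrt(reps))
})
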