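# Poisson random field machinery and the hierarchical MCMC.

test_that("fixation factor: neutral limit, value, reflection identity", {
  expect_equal(prf_fixation_factor(0), 1)
  expect_lt(abs(prf_fixation_factor(1e-12) - 1), 1e-9)
  expect_equal(prf_fixation_factor(5), 10 / (1 - exp(-10)),
               tolerance = 1e-12)
  set.seed(2)
  g <- runif(20, -6, 6)
  expect_equal(prf_fixation_factor(g),
               exp(2 * g) * prf_fixation_factor(-g), tolerance = 1e-9)
})

test_that("polymorphism factor: neutral limit and quadrature accuracy", {
  expect_equal(prf_polymorphism_factor(0, 10), 1)
  expect_lt(abs(prf_polymorphism_factor(1e-10, 25) - 1), 1e-9)

  # brute-force midpoint Riemann oracle at (gamma = 2, n = 10)
  n <- 10; gamma <- 2
  q <- (seq_len(2e6) - 0.5) / 2e6
  f <- (1 - q^n - (1 - q)^n) *
    (1 - exp(-2 * gamma * (1 - q))) / ((1 - exp(-2 * gamma)) * q * (1 - q))
  oracle <- sum(f) / 2e6 / a_n(n)
  expect_equal(prf_polymorphism_factor(2, 10), oracle, tolerance = 1e-6)

  # neutral denominator identity: integral at gamma -> 0 equals a_n
  q <- (seq_len(1e6) - 0.5) / 1e6
  expect_equal(sum((1 - q^12 - (1 - q)^12) / q) / 1e6, a_n(12),
               tolerance = 1e-4)
})

test_that("selection depletes polymorphism relative to fixation", {
  # Under the PRF sojourn density, sampled polymorphism G grows slowly with
  # positive gamma (bounded by 2: selected variants sit at detectable
  # frequencies) while the fixation factor H grows linearly, so the
  # polymorphism-to-divergence ratio G/H falls monotonically; purifying
  # selection (gamma < 0) depletes polymorphism outright.
  grid <- c(0.5, 1, 2, 4, 8, 15)
  G <- sapply(grid, prf_polymorphism_factor, n = 20)
  H <- prf_fixation_factor(grid)
  expect_true(all(diff(G / H) < 0))
  expect_true(all(G / H < 1))
  expect_true(all(G > 1 & G < 2))   # bounded polymorphism excess
  Gneg <- sapply(-grid, prf_polymorphism_factor, n = 20)
  expect_true(all(diff(Gneg) < 0))  # monotone loss under purifying gamma
  expect_true(all(Gneg < 1))
})

test_that("interpolated G matches quadrature", {
  f <- popselscan:::prf_g_interpolator(40)
  g <- c(-9.7, -3.2, -0.01, 0.42, 2.3, 7.7)
  direct <- sapply(g, prf_polymorphism_factor, n = 40)
  expect_equal(f(g), direct, tolerance = 1e-4)
})

test_that("prf_loglik reduces correctly and matches hand evaluation", {
  tab <- data.frame(locus = "l1", Ps = 4, Pn = 2, Ds = 9, Dn = 3,
                    n = 10, class = "candidate")
  an <- a_n(10)
  hand <- dpois(4, 2 * an, log = TRUE) + dpois(9, 2 * 16, log = TRUE) +
    dpois(2, 1.5 * an, log = TRUE) + dpois(3, 1.5 * 16, log = TRUE)
  expect_equal(prf_loglik(tab, 2, 1.5, 0, 15), hand, tolerance = 1e-12)

  # gamma = 0 reduces replacement means to the silent functional form
  expect_equal(prf_loglik(tab, 2, 2, 0, 15),
               dpois(4, 2 * an, log = TRUE) + dpois(9, 32, log = TRUE) +
               dpois(2, 2 * an, log = TRUE) + dpois(3, 32, log = TRUE),
               tolerance = 1e-12)
})

test_that("build_mk_table partitions variant classes", {
  pol <- data.frame(
    status = c("polymorphic_sp1", "polymorphic_sp1", "polymorphic_sp1",
               "fixed_difference", "fixed_difference", "fixed_difference"),
    effect = c("synonymous", "noncoding", "nonsynonymous",
               "nonsynonymous", "nonsynonymous", NA))
  mk <- build_mk_table(pol, n = 12, locus_id = "x", class = "reference")
  expect_equal(mk$Ps, 2)   # synonymous + noncoding polymorphisms
  expect_equal(mk$Pn, 1)
  expect_equal(mk$Ds, 0)
  expect_equal(mk$Dn, 2)   # NA effect not counted
  expect_equal(mk$class, "reference")

  empty <- pol[0, ]
  mk0 <- build_mk_table(empty, n = 8)
  expect_equal(unlist(mk0[, c("Ps", "Pn", "Ds", "Dn")]),
               c(Ps = 0, Pn = 0, Ds = 0, Dn = 0))
})

test_that("mk table from a hand-classified toy alignment", {
  # codons: GGT GGT GGT; h2 carries syn change (pos 3), h3 nonsyn (pos 4);
  # outgroup fixed nonsyn difference at pos 8 (GGT -> GTT is Gly -> Val)
  seqs <- c(h1 = "GGTGGTGGT", h2 = "GGCGGTGGT", h3 = "GGTAGTGGT")
  a <- make_aln(seqs, "GGTGGTGTT", exons = data.frame(start = 0, end = 9))
  cl <- classify_sites(a)
  pol <- polarize_variants(a, cl)
  mk <- build_mk_table(pol, n = 3, locus_id = "toy")
  expect_equal(mk$Ps, 1)
  expect_equal(mk$Pn, 1)
  expect_equal(mk$Ds, 0)
  expect_equal(mk$Dn, 1)
})

test_that("mkprf chain is deterministic under a fixed seed", {
  tab <- simulate_mk_tables(theta_s = rep(4, 4), theta_r = rep(3, 4),
                            gamma = c(2, 0, 0, -1), n = rep(20, 4),
                            seed = 9)
  f1 <- run_mkprf(tab, cycles = 2000, burn_in = 200, thin = 5, seed = 31)
  f2 <- run_mkprf(tab, cycles = 2000, burn_in = 200, thin = 5, seed = 31)
  expect_identical(f1$gamma_samples, f2$gamma_samples)
  expect_identical(f1$summary, f2$summary)
  # interval sanity
  expect_true(all(f1$summary$gamma_q025 <= f1$summary$gamma_mean))
  expect_true(all(f1$summary$gamma_mean <= f1$summary$gamma_q975))
})

test_that("posterior recovers sign and magnitude of strong selection", {
  set.seed(101)
  tab <- simulate_mk_tables(theta_s = rep(6, 8), theta_r = rep(4, 8),
                            gamma = c(rep(2, 4), rep(-2, 4)),
                            n = rep(40, 8), tau = 15,
                            class = rep(c("candidate", "reference"),
                                        each = 4))
  fit <- run_mkprf(tab, cycles = 8000, burn_in = 1000, thin = 5, seed = 7)
  pos <- fit$summary$gamma_mean[1:4]
  neg <- fit$summary$gamma_mean[5:8]
  expect_true(all(pos > 0))
  expect_true(all(neg < 0))
})

test_that("hierarchical prior shrinks low-information loci to class mean", {
  # a tiny-count locus whose own evidence points weakly negative (some
  # replacement polymorphism, no fixation) joins a class of strongly
  # positive loci; its posterior must move from its solo estimate toward
  # (but not past) the class mean
  strong <- simulate_mk_tables(theta_s = rep(6, 5), theta_r = rep(4, 5),
                               gamma = rep(2, 5), n = rep(40, 5),
                               tau = 15, seed = 19)
  tiny <- data.frame(locus = "tiny", Ps = 1, Pn = 1, Ds = 3, Dn = 3,
                     n = 40, class = "candidate")
  tab <- rbind(tiny, strong[, names(tiny)])
  fit <- run_mkprf(tab, cycles = 20000, burn_in = 2000, thin = 5,
                   seed = 13)
  mu_hat <- mean(fit$mu_samples[, "candidate"])
  g_tiny <- fit$summary$gamma_mean[fit$summary$locus == "tiny"]
  # oracle: the tiny locus's own maximum-likelihood gamma from the
  # theta-integrated (marginal) replacement likelihood
  an <- a_n(40)
  marg <- function(g) {
    G <- sapply(g, prf_polymorphism_factor, n = 40)
    H <- prf_fixation_factor(g)
    tiny$Pn * log(an * G) + tiny$Dn * log(16 * H) -
      (tiny$Pn + tiny$Dn + 1) * log(an * G + 16 * H)
  }
  gs <- seq(-8, 5, by = 0.01)
  mle <- gs[which.max(marg(gs))]
  expect_gt(mu_hat, 1)          # class mean dominated by the strong loci
  expect_gt(g_tiny, mle + 0.1)  # pulled from its own MLE toward the mean
  expect_lt(g_tiny, mu_hat)     # but not past it
})
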