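# Synthetic data generator: determinism, validity, truth bookkeeping,
# structure behaviour.

small_cfg <- function(...) {
  generator_config(
    n_candidate = 2L, n_reference = 3L, n_chrom = c(10L, 8L),
    candidate_length = c(600L, 900L), reference_length = c(400L, 500L),
    demes = c(2L, 2L), mig = c(8, 8), ...)
}

test_that("unknown config fields and invalid rates are rejected", {
  expect_error(generator_config(bogus = 1), "unknown generator_config")
  expect_error(generator_config(k_candidate = 0), "k must be > 0")
})

test_that("fixed seed gives identical datasets; truth rows match loci", {
  d1 <- suppressWarnings(generate_dataset(small_cfg(), seed = 7))
  d2 <- suppressWarnings(generate_dataset(small_cfg(), seed = 7))
  expect_identical(lapply(d1$alignments, `[[`, "mat"),
                   lapply(d2$alignments, `[[`, "mat"))
  expect_identical(d1$truth, d2$truth)
  expect_equal(nrow(d1$truth), 5L)
  expect_setequal(d1$truth$locus, names(d1$alignments))
})

test_that("theta = 0 gives monomorphic loci identical to the outgroup", {
  cfg <- small_cfg(theta_sil = c(0, 0), rep_frac = 0)
  d <- suppressWarnings(generate_dataset(cfg, seed = 3))
  for (a in d$alignments) {
    expect_true(all(apply(a$mat, 2, function(z) length(unique(z)) == 1L)))
    expect_identical(unname(a$mat[1, ]), a$outgroup)
  }
})

test_that("emitted files pass seqdata validation and round-trip", {
  dir <- tempfile()
  d <- suppressWarnings(generate_dataset(small_cfg(), seed = 9, dir = dir))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  id <- names(d$alignments)[1]
  b <- read_locus_alignment(file.path(dir, paste0(id, ".fa")),
                            file.path(dir, paste0(id, ".meta.tsv")),
                            file.path(dir, paste0(id, ".exons.tsv")))
  expect_identical(b$mat, d$alignments[[id]]$mat)
  expect_identical(b$outgroup, d$alignments[[id]]$outgroup)
  expect_identical(b$meta, d$alignments[[id]]$meta)
  tr <- read.delim(file.path(dir, "truth.tsv"))
  expect_identical(tr$locus, d$truth$locus)
})

test_that("realized MK-style truth counts agree with pipeline counting", {
  # the generator's branch-classified counts must match what polarization
  # recovers from the emitted alignment (infinite-sites positions)
  d <- suppressWarnings(generate_dataset(small_cfg(), seed = 21))
  tr <- d$truth
  for (i in seq_len(nrow(tr))) {
    a <- d$alignments[[tr$locus[i]]]
    cl <- suppressWarnings(classify_sites(a))
    s1 <- subset_species(a, "sp1")
    pol <- polarize_variants(s1, cl)
    fixed <- pol$status == "fixed_difference"
    # all variant columns (any effect class) per species
    expect_equal(sum(!fixed), tr$P_sil_sp1[i] + tr$P_rep_sp1[i])
    expect_equal(sum(fixed), tr$D_sil_sp1[i] + tr$D_rep_sp1[i])
  }
})

test_that("silent diversity tracks the generating theta", {
  cfg <- generator_config(
    n_candidate = 0L, n_reference = 25L, n_chrom = c(12L, 8L),
    reference_length = c(500L, 700L), demes = c(2L, 2L), mig = c(10, 10))
  d <- suppressWarnings(generate_dataset(cfg, seed = 5))
  div <- do.call(rbind, lapply(d$alignments, function(a)
    suppressWarnings(diversity_summary(a))))
  x <- div$pi_sil[div$species == "sp1"]
  expect_lt(abs(mean(x) - 0.0034), 3 * sd(x) / sqrt(length(x)))
})

test_that("neutral candidate and reference theta estimates are exchangeable", {
  cfg <- generator_config(
    n_candidate = 12L, n_reference = 12L, n_chrom = c(10L, 8L),
    candidate_length = c(500L, 700L), reference_length = c(500L, 700L),
    demes = c(1L, 1L))
  d <- suppressWarnings(generate_dataset(cfg, seed = 13))
  div <- do.call(rbind, lapply(d$alignments, function(a)
    suppressWarnings(diversity_summary(a))))
  div <- div[div$species == "sp1", ]
  is_cand <- grepl("^cand", div$locus_id)
  ks <- suppressWarnings(ks.test(div$theta_w_sil[is_cand],
                                 div$theta_w_sil[!is_cand]))
  expect_gt(ks$p.value, 0.05)
})

test_that("FST rises as migration falls (3-point grid)", {
  fst_mean <- function(mig) {
    cfg <- generator_config(
      n_candidate = 0L, n_reference = 6L, n_chrom = c(16L, 8L),
      reference_length = c(500L, 600L), demes = c(4L, 1L),
      mig = c(mig, 1))
    d <- suppressWarnings(generate_dataset(cfg, seed = 77))
    mean(sapply(d$alignments, function(a) {
      s <- subset_species(a, "sp1")
      suppressWarnings(hudson_fst(s, "population",
                                  classify_sites(a))$fst)
    }), na.rm = TRUE)
  }
  f <- c(fst_mean(40), fst_mean(6), fst_mean(1))
  expect_true(all(diff(f) > 0))
})

test_that("diversity scaling k deepens within-species variation", {
  cfg_k <- function(k) generator_config(
    n_candidate = 8L, n_reference = 2L, n_chrom = c(12L, 8L),
    candidate_length = c(800L, 1000L), reference_length = c(400L, 500L),
    demes = c(1L, 1L), k_candidate = rep(k, 8L))
  d1 <- suppressWarnings(generate_dataset(cfg_k(1), seed = 4))
  d3 <- suppressWarnings(generate_dataset(cfg_k(3), seed = 4))
  pi_of <- function(d) {
    div <- do.call(rbind, lapply(d$alignments[1:8], function(a)
      suppressWarnings(diversity_summary(a))))
    mean(div$pi_sil[div$species == "sp1"])
  }
  expect_gt(pi_of(d3), 2 * pi_of(d1))
})

test_that("truth_vs_estimates_report joins and scores", {
  d <- suppressWarnings(generate_dataset(small_cfg(), seed = 2))
  est <- data.frame(locus = d$truth$locus,
                    k_hat = d$truth$k * c(1.1, 0.9, 1, 1, 1),
                    flagged = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  rep <- truth_vs_estimates_report(d$truth, est)
  expect_equal(nrow(rep$table), 5L)
  expect_true("k" %in% names(rep$metrics))
  expect_equal(unname(rep$metrics$flags["false_positive_rate"]), 0.2)
  expect_error(truth_vs_estimates_report(d$truth,
                                         data.frame(locus = "nope",
                                                    k_hat = 1)),
               "unknown locus")
})
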