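# Alignment container, site classification, Nei-Gojobori counting,
# polarization.

test_that("construction validates shape and metadata", {
  a <- make_aln(c(h1 = "ACGTACGTACGT", h2 = "ACGTACGTACGT",
                  h3 = "ACGAACGTACGT", h4 = "ACGTACGTACGT"),
                "ACGTACGTACGT")
  expect_s3_class(a, "locus_alignment")
  expect_equal(n_chromosomes(a), 4L)
  expect_equal(alignment_length(a), 12L)

  expect_error(make_aln(c(h1 = "ACGTACGTACG", h2 = "ACGTACGTACGT"),
                        "ACGTACGTACGT"), "unequal alignment length")
  expect_error(make_aln(c(h1 = "ACGT", h2 = "ACGT", h3 = "ACGT"),
                        "ACGT", species = c("sp1", "sp2", "sp3")),
               "more than two ingroup species")
  meta <- data.frame(haplotype_id = "h1", species = "sp1",
                     population = "p1")
  expect_error(
    locus_alignment("x", c(h1 = "ACGT", h2 = "ACGT"), "ACGT", meta),
    "no metadata row for haplotype id\\(s\\): h2")
})

test_that("exon annotation is validated", {
  expect_error(make_aln(c(h1 = "ACGTAC"), "ACGTAC",
                        exons = data.frame(start = 0, end = 4)),
               "not divisible by 3")
  expect_error(make_aln(c(h1 = "ACGTAC"), "ACGTAC",
                        exons = data.frame(start = c(0, 2), end = c(3, 5))),
               "overlapping")
  expect_error(make_aln(c(h1 = "ACGTAC"), "ACGTAC",
                        exons = data.frame(start = 0, end = 9)),
               "out of bounds")
})

test_that("minus-strand loci are reverse-complemented at load", {
  # coding strand CAT GCA lives on the minus strand of the stored sequence
  plus <- "TGCATG"
  a <- make_aln(c(h1 = plus, h2 = plus), plus,
                exons = data.frame(start = 0, end = 6), strand = "-")
  expect_equal(paste(a$mat[1, ], collapse = ""), "CATGCA")
  expect_equal(a$strand, "+")
  expect_equal(a$exons, data.frame(start = 0L, end = 6L))
})

test_that("file round-trip reproduces sequences, metadata and annotation", {
  a <- make_aln(c(x1 = "ACGTACGTAC", x2 = "ACGTACTTAC", x3 = "AAGTACGTAC"),
                "ACGTACGGAC", species = c("sp1", "sp1", "sp2"),
                pops = c("p1", "p2", "p3"),
                exons = data.frame(start = 1L, end = 7L), locus = "rt")
  dir <- tempfile()
  write_locus_alignment(a, dir)
  b <- read_locus_alignment(file.path(dir, "rt.fa"),
                            file.path(dir, "rt.meta.tsv"),
                            file.path(dir, "rt.exons.tsv"))
  expect_identical(a$mat, b$mat)
  expect_identical(a$outgroup, b$outgroup)
  expect_identical(a$meta, b$meta)
  expect_equal(a$exons$start, b$exons$start)
  expect_equal(a$exons$end, b$exons$end)
})

test_that("read_locus_alignment enforces outgroup and ingroup presence", {
  dir <- tempfile()
  dir.create(dir)
  writeLines(c(">a", "ACGT", ">b", "ACGT"), file.path(dir, "x.fa"))
  meta <- data.frame(haplotype_id = c("a", "b"), species = "sp1",
                     population = "p1", is_outgroup = c(FALSE, FALSE))
  mpath <- file.path(dir, "m.tsv")
  write.table(meta, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_locus_alignment(file.path(dir, "x.fa"), mpath),
               "exactly one outgroup")
  meta$is_outgroup <- c(TRUE, TRUE)
  write.table(meta, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_locus_alignment(file.path(dir, "x.fa"), mpath),
               "exactly one outgroup")
})

test_that("indel and ambiguity columns are excluded; classes partition", {
  seqs <- c(h1 = "AC-TACGTNA", h2 = "ACGTACGTAA")
  a <- make_aln(seqs, "ACGTAC-TAA")
  cl <- classify_sites(a)
  expect_equal(sum(cl$class == "excluded_indel"), 2L)  # cols 3 and 7
  expect_equal(sum(cl$class == "excluded_ambiguous"), 1L)  # col 9
  # partition invariant
  expect_equal(length(cl$class), alignment_length(a))
  expect_setequal(unique(cl$class),
                  c("excluded_indel", "excluded_ambiguous", "noncoding"))

  # gap-column count equals columns containing '-' in any row
  has_gap <- sapply(seq_len(ncol(a$mat)), function(j)
    any(a$mat[, j] == "-") || a$outgroup[j] == "-")
  expect_equal(sum(cl$class == "excluded_indel"), sum(has_gap))
})

test_that("Nei-Gojobori site counts match codon enumeration", {
  # TTT (Phe): only third-position TTC is synonymous -> 1/3 syn site
  a <- make_aln(c(h1 = "TTT", h2 = "TTT"), "TTT",
                exons = data.frame(start = 0, end = 3))
  cnt <- count_site_classes(a)
  expect_equal(unname(cnt["syn_sites"]), 1 / 3)
  expect_equal(unname(cnt["nonsyn_sites"]), 8 / 3)

  # ATG (Met): no synonymous single-base change
  a <- make_aln(c(h1 = "ATG", h2 = "ATG"), "ATG",
                exons = data.frame(start = 0, end = 3))
  expect_equal(unname(count_site_classes(a)["syn_sites"]), 0)

  # pure-intron locus
  a <- make_aln(c(h1 = strrep("A", 300), h2 = strrep("A", 300)),
                strrep("A", 300))
  expect_equal(unname(count_site_classes(a)),
               c(0, 0, 300))
})

test_that("syn + nonsyn site weights total 3 per intact codon", {
  set.seed(11)
  for (rep in 1:5) {
    a <- random_codon_aln(4, 20)
    cl <- classify_sites(a)
    cnt <- count_site_classes(a, cl)
    n_intact <- sum(cl$intact_codon)
    expect_equal(unname(cnt["syn_sites"] + cnt["nonsyn_sites"]),
                 3 * n_intact, tolerance = 1e-12)
  }
})

test_that("premature stop in reference frame skips codon with warning", {
  a <- make_aln(c(h1 = "TAAGGG", h2 = "TAAGGG"), "TAAGGG",
                exons = data.frame(start = 0, end = 6))
  expect_warning(cl <- classify_sites(a), "premature stop")
  expect_false(cl$intact_codon[1])
  expect_true(cl$intact_codon[2])
})

test_that("polarization distinguishes polymorphism from fixed differences", {
  # column 1: ingroup all A, outgroup G -> fixed difference
  # column 2: ingroup A/G, outgroup A -> polymorphic
  # column 3: sp1 segregates, sp2 monomorphic -> polymorphic_sp1
  seqs <- c(s1a = "AAA", s1b = "AGC", s2a = "AAG", s2b = "AAG")
  a <- make_aln(seqs, "GAG", species = c("sp1", "sp1", "sp2", "sp2"))
  pol <- polarize_variants(a)
  expect_equal(pol$status[pol$pos == 0], "fixed_difference")
  expect_equal(pol$status[pol$pos == 1], "polymorphic_sp1")
  expect_equal(pol$status[pol$pos == 2], "polymorphic_sp1")
  expect_true(all(pol$effect == "noncoding"))
})

test_that("tri-allelic columns count once, effect from commonest derived", {
  seqs <- c(h1 = "T", h2 = "C", h3 = "C", h4 = "G")
  a <- make_aln(seqs, "T")
  pol <- polarize_variants(a)
  expect_equal(nrow(pol), 1L)
  expect_equal(attr(pol, "multiallelic"), 0L)
  expect_equal(pol$alt_allele, "C")
})

test_that("variant effects match a brute-force translation oracle", {
  set.seed(42)
  code <- popselscan:::GENETIC_CODE_TABLE
  for (rep in 1:8) {
    a <- random_codon_aln(6, 30)
    cl <- classify_sites(a)
    pol <- polarize_variants(a, cl)
    for (r in seq_len(nrow(pol))) {
      j <- pol$pos[r] + 1L
      ci <- cl$codon_id[j]
      if (is.na(ci) || !cl$intact_codon[ci]) next
      cols <- cl$codon_map[ci, ]
      # oracle: translate the reference codon with each allele substituted
      cod_a <- cod_b <- a$mat[1, cols]
      p <- which(cols == j)
      alt <- pol$alt_allele[r]
      other <- if (pol$status[r] == "fixed_difference")
        pol$outgroup_allele[r]
      else {
        alleles <- unique(a$mat[, j])
        og <- a$outgroup[j]
        if (og %in% alleles) og else {
          rest <- table(factor(a$mat[, j], levels = setdiff(alleles, alt)))
          names(which.max(rest))
        }
      }
      cod_a[p] <- other
      cod_b[p] <- alt
      oracle <- if (identical(unname(code[paste(cod_a, collapse = "")]),
                              unname(code[paste(cod_b, collapse = "")])))
        "synonymous" else "nonsynonymous"
      expect_equal(pol$effect[r], oracle)
    }
  }
})
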