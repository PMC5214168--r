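# Small in-code fixtures shared across the suite.

# Build a locus_alignment from character sequence strings.
make_aln <- function(seqs, outgroup, species = NULL, pops = NULL,
                     exons = NULL, frame = 0L, locus = "toy",
                     strand = "+") {
  if (is.null(names(seqs))) names(seqs) <- paste0("h", seq_along(seqs))
  if (is.null(species)) species <- rep("sp1", length(seqs))
  if (is.null(pops)) pops <- rep("p1", length(seqs))
  meta <- data.frame(haplotype_id = names(seqs), species = species,
                     population = pops, stringsAsFactors = FALSE)
  locus_alignment(locus, seqs, outgroup, meta, exons = exons,
                  strand = strand, frame = frame)
}

# Random coding alignment of n haplotypes x ncodons codons with point
# mutations, used for the effect-classification oracle. Returns the
# alignment; every sequence differs from the first by sprinkled single-base
# substitutions.
random_codon_aln <- function(n, ncodons, mut_per_seq = 4L) {
  bases <- c("A", "C", "G", "T")
  repeat {
    ref <- sample(bases, 3L * ncodons, replace = TRUE)
    aa <- sapply(seq_len(ncodons), function(c)
      popselscan:::translate_codon(paste(ref[(3 * c - 2):(3 * c)],
                                         collapse = "")))
    if (!any(aa == "*")) break
  }
  L <- 3L * ncodons
  mat <- matrix(rep(ref, each = n), nrow = n)
  for (i in seq(2, n)) {
    pos <- sample.int(L, mut_per_seq)
    for (p in pos) mat[i, p] <- sample(setdiff(bases, ref[p]), 1L)
  }
  og <- ref
  ogpos <- sample.int(L, mut_per_seq)
  for (p in ogpos) og[p] <- sample(setdiff(bases, ref[p]), 1L)
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- paste0("h", seq_len(n))
  make_aln(seqs, paste(og, collapse = ""),
           exons = data.frame(start = 0L, end = L))
}

# Brute-force mean pairwise difference per site over given columns.
brute_pi <- function(mat, cols, L) {
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    tot <- tot + sum(mat[i, cols] != mat[j, cols])
  tot / choose(n, 2) / L
}
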