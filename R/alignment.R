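# Locus alignment container and I/O.
#
# A locus_alignment holds the phased ingroup haplotypes of one locus (one or
# two species, with population labels), exactly one outgroup sequence of the
# same length, and a lightweight exon annotation on alignment coordinates
# (0-based, half-open). All downstream statistics consume this object.

VALID_CHARS <- c("A", "C", "G", "T", "-", "N")

#' Construct a locus alignment
#'
#' @param locus_id Character scalar naming the locus.
#' @param seqs Named character vector of ingroup haplotype sequences
#'   (names are haplotype ids), or a character matrix with one row per
#'   haplotype. Alphabet \code{A,C,G,T,-,N}.
#' @param outgroup Single outgroup sequence string of the same length.
#' @param meta Data frame with columns \code{haplotype_id}, \code{species},
#'   \code{population}; one row per ingroup haplotype.
#' @param exons Data frame with integer columns \code{start}, \code{end}
#'   (0-based, half-open, on alignment coordinates), or \code{NULL} for a
#'   fully noncoding locus.
#' @param strand \code{"+"} or \code{"-"}. Minus-strand loci are
#'   reverse-complemented at construction so downstream code always sees the
#'   coding strand.
#' @param frame Integer 0, 1 or 2: offset of the first complete codon within
#'   the concatenated exon sequence.
#' @return An object of class \code{locus_alignment}.
#' @export
locus_alignment <- function(locus_id, seqs, outgroup, meta,
                            exons = NULL, strand = "+", frame = 0L) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (is.null(names(seqs))) stop("ingroup sequences must be named")
    lens <- nchar(seqs)
    if (length(unique(c(lens, nchar(outgroup)))) != 1L)
      stop("unequal alignment length in locus '", locus_id, "'")
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- names(seqs)
  }
  if (nrow(mat) < 1L) stop("locus '", locus_id, "': zero ingroup rows")
  og <- strsplit(toupper(outgroup), "")[[1]]
  if (length(og) != ncol(mat))
    stop("unequal alignment length in locus '", locus_id, "'")
  bad <- setdiff(unique(c(as.vector(mat), og)), VALID_CHARS)
  if (length(bad))
    stop("invalid characters in alignment: ", paste(bad, collapse = ", "))

  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("haplotype_id", "species", "population")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  missing_ids <- setdiff(rownames(mat), meta$haplotype_id)
  if (length(missing_ids))
    stop("no metadata row for haplotype id(s): ",
         paste(missing_ids, collapse = ", "))
  meta <- meta[match(rownames(mat), meta$haplotype_id), need, drop = FALSE]
  rownames(meta) <- NULL
  if (length(unique(meta$species)) > 2L)
    stop("more than two ingroup species in locus '", locus_id, "'")

  L <- ncol(mat)
  if (!is.null(exons) && nrow(as.data.frame(exons)) > 0L) {
    exons <- as.data.frame(exons)[, c("start", "end")]
    exons <- exons[order(exons$start), , drop = FALSE]
    if (any(exons$start < 0L) || any(exons$end > L) ||
        any(exons$end <= exons$start))
      stop("exon intervals out of bounds for locus '", locus_id, "'")
    if (nrow(exons) > 1L &&
        any(exons$start[-1L] < exons$end[-nrow(exons)]))
      stop("overlapping exon intervals in locus '", locus_id, "'")
    cds_len <- sum(exons$end - exons$start) - frame
    if (cds_len %% 3L != 0L)
      stop("exon length after frame offset not divisible by 3 in locus '",
           locus_id, "'")
  } else {
    exons <- data.frame(start = integer(0), end = integer(0))
  }
  rownames(exons) <- NULL

  aln <- structure(list(
    locus_id = locus_id, mat = mat, outgroup = og, meta = meta,
    exons = exons, strand = "+", frame = as.integer(frame)),
    class = "locus_alignment")
  if (identical(strand, "-")) aln <- revcomp_alignment(aln)
  aln
}

# Reverse-complement an alignment in place (sequences, outgroup, exon
# coordinates); used for minus-strand genes so exported objects are always
# on the coding strand.
revcomp_alignment <- function(aln) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", `-` = "-", N = "N")
  L <- ncol(aln$mat)
  aln$mat <- matrix(comp[aln$mat], nrow = nrow(aln$mat),
                    dimnames = dimnames(aln$mat))[, L:1, drop = FALSE]
  aln$outgroup <- unname(comp[aln$outgroup][L:1])
  if (nrow(aln$exons)) {
    new_start <- L - aln$exons$end
    new_end <- L - aln$exons$start
    aln$exons <- data.frame(start = new_start, end = new_end)
    aln$exons <- aln$exons[order(aln$exons$start), , drop = FALSE]
    rownames(aln$exons) <- NULL
  }
  aln
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("locus_alignment '", x$locus_id, "': ", nrow(x$mat),
      " ingroup haplotypes + 1 outgroup, length ", ncol(x$mat), " bp\n",
      sep = "")
  sp <- table(x$meta$species)
  cat("  species: ", paste(names(sp), sp, sep = " n=", collapse = "; "),
      "\n  exons: ", nrow(x$exons), " interval(s), frame ", x$frame, "\n",
      sep = "")
  invisible(x)
}

#' Number of ingroup chromosomes and alignment length
#' @param aln A \code{locus_alignment}.
#' @return Integer scalar.
#' @export
n_chromosomes <- function(aln) nrow(aln$mat)

#' @rdname n_chromosomes
#' @export
alignment_length <- function(aln) ncol(aln$mat)

#' Subset a locus alignment to one species
#'
#' Site classification and exclusion remain those of the full alignment,
#' so per-species statistics are computed over a shared set of sites.
#'
#' @param aln A \code{locus_alignment}.
#' @param species Species label to keep.
#' @return A \code{locus_alignment} with only that species' haplotypes.
#' @export
subset_species <- function(aln, species) {
  keep <- aln$meta$species == species
  if (!any(keep)) stop("no haplotypes for species '", species, "'")
  aln$mat <- aln$mat[keep, , drop = FALSE]
  aln$meta <- aln$meta[keep, , drop = FALSE]
  rownames(aln$meta) <- NULL
  aln
}

#' Read a locus alignment from FASTA + metadata + annotation
#'
#' @param fasta_path Path to a FASTA file holding all haplotypes of one
#'   locus, including the outgroup.
#' @param metadata A data frame or path to a TSV with columns
#'   \code{haplotype_id}, \code{species}, \code{population},
#'   \code{is_outgroup} (logical or 0/1). Exactly one row must be flagged
#'   as outgroup.
#' @param annotation A data frame with columns \code{start}, \code{end}
#'   (plus optional \code{strand}, \code{frame}), a path to such a TSV, a
#'   path to a GFF3 file whose \code{exon} features are used (converted
#'   from 1-based closed to 0-based half-open), or \code{NULL}.
#' @param locus_id Locus name; defaults to the FASTA file name minus
#'   extension.
#' @return A validated \code{locus_alignment}.
#' @export
read_locus_alignment <- function(fasta_path, metadata, annotation = NULL,
                                 locus_id = NULL) {
  if (is.null(locus_id))
    locus_id <- sub("\\.(fa|fasta|fna)$", "", basename(fasta_path))
  dss <- Biostrings::readBStringSet(fasta_path)
  seqs <- toupper(as.character(dss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (length(unique(nchar(seqs))) != 1L)
    stop("unequal alignment length in '", fasta_path, "'")

  if (is.character(metadata))
    metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  if (!"is_outgroup" %in% names(metadata))
    stop("metadata must have an is_outgroup column")
  metadata$is_outgroup <- as.logical(metadata$is_outgroup) |
    metadata$is_outgroup == 1
  missing_ids <- setdiff(names(seqs), metadata$haplotype_id)
  if (length(missing_ids))
    stop("no metadata row for haplotype id(s): ",
         paste(missing_ids, collapse = ", "))
  metadata <- metadata[metadata$haplotype_id %in% names(seqs), , drop = FALSE]
  og_ids <- metadata$haplotype_id[metadata$is_outgroup]
  if (length(og_ids) != 1L)
    stop("exactly one outgroup row required, found ", length(og_ids))
  ingroup_ids <- metadata$haplotype_id[!metadata$is_outgroup]
  if (length(ingroup_ids) == 0L) stop("zero ingroup rows")

  ann <- parse_annotation(annotation)
  locus_alignment(
    locus_id = locus_id,
    seqs = seqs[ingroup_ids],
    outgroup = seqs[[og_ids]],
    meta = metadata[!metadata$is_outgroup,
                    c("haplotype_id", "species", "population")],
    exons = ann$exons, strand = ann$strand, frame = ann$frame)
}

parse_annotation <- function(annotation) {
  if (is.null(annotation))
    return(list(exons = NULL, strand = "+", frame = 0L))
  if (is.character(annotation)) {
    first <- readLines(annotation, n = 1L)
    if (grepl("^##gff", first)) {
      gff <- utils::read.delim(annotation, header = FALSE, comment.char = "#",
                               stringsAsFactors = FALSE)
      gff <- gff[gff[[3]] == "exon", , drop = FALSE]
      return(list(
        exons = data.frame(start = gff[[4]] - 1L, end = gff[[5]]),
        strand = if (nrow(gff) && gff[[7]][1] == "-") "-" else "+",
        frame = if (nrow(gff) && gff[[8]][1] %in% c("0", "1", "2"))
          as.integer(gff[[8]][1]) else 0L))
    }
    annotation <- utils::read.delim(annotation, stringsAsFactors = FALSE)
  }
  annotation <- as.data.frame(annotation)
  strand <- if ("strand" %in% names(annotation) && nrow(annotation))
    annotation$strand[1] else "+"
  frame <- if ("frame" %in% names(annotation) && nrow(annotation))
    as.integer(annotation$frame[1]) else 0L
  list(exons = annotation[, c("start", "end"), drop = FALSE],
       strand = strand, frame = frame)
}

#' Write a locus alignment back to FASTA + metadata + annotation
#'
#' Emits \code{<locus>.fa}, \code{<locus>.meta.tsv} and
#' \code{<locus>.exons.tsv} under \code{dir}; reading these back with
#' \code{\link{read_locus_alignment}} reproduces the object.
#'
#' @param aln A \code{locus_alignment}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the FASTA path.
#' @export
write_locus_alignment <- function(aln, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, paste0(aln$locus_id, ".fa"))
  ids <- c(rownames(aln$mat), "outgroup")
  seqs <- c(apply(aln$mat, 1, paste, collapse = ""),
            paste(aln$outgroup, collapse = ""))
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), fa)
  meta <- rbind(
    cbind(aln$meta, is_outgroup = FALSE),
    data.frame(haplotype_id = "outgroup", species = "outgroup",
               population = "outgroup", is_outgroup = TRUE))
  utils::write.table(meta, file.path(dir, paste0(aln$locus_id, ".meta.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ex <- aln$exons
  ex$strand <- rep("+", nrow(ex))
  ex$frame <- rep(aln$frame, nrow(ex))
  utils::write.table(ex, file.path(dir, paste0(aln$locus_id, ".exons.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fa)
}
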