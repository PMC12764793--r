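#' @useDynLib haplobin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Canonical k-mer set
#'
#' A `KmerSet` holds the canonical k-mers of one or more DNA sequences with
#' their occurrence counts. A k-mer is stored in canonical form: the
#' lexicographically smaller of the k-mer and its reverse complement, the
#' convention used by k-mer counters such as KMC and Jellyfish. The `KmerSet`
#' is the unit of haplotype specificity: a k-mer present in one haplotype's
#' set and absent from the other's is a haplotype-specific k-mer.
#'
#' @param kmers character vector of canonical k-mers (all the same length,
#'   alphabet ACGT).
#' @param counts integer vector of occurrence counts (all >= 1).
#' @param k k-mer length; defaults to the length of the first k-mer.
#' @return An object of class `KmerSet` with fields `k`, `kmer`, `count`.
#' @examples
#' ks <- count_canonical("ACGTACGT", k = 3)
#' ks$kmer
#' @export
KmerSet <- function(kmers = character(), counts = integer(), k = NULL) {
  kmers <- as.character(kmers)
  counts <- as.integer(counts)
  if (length(kmers) != length(counts))
    stop("kmers and counts must have equal length")
  if (is.null(k)) {
    if (length(kmers) == 0L) stop("k must be given for an empty KmerSet")
    k <- nchar(kmers[[1L]])
  }
  k <- as.integer(k)
  if (length(kmers) > 0L) {
    if (any(nchar(kmers) != k)) stop("all k-mers must have length k")
    if (any(grepl("[^ACGT]", kmers))) stop("k-mers must be over {A,C,G,T}")
    if (any(counts < 1L)) stop("counts must be >= 1")
    if (anyDuplicated(kmers)) stop("duplicate k-mers in set")
  }
  structure(list(k = k, kmer = kmers, count = counts), class = "KmerSet")
}

#' @export
print.KmerSet <- function(x, ...) {
  cat(sprintf("KmerSet: %d canonical %d-mers (total count %s)\n",
              length(x$kmer), x$k, format(sum(as.numeric(x$count)))))
  invisible(x)
}

#' @export
length.KmerSet <- function(x) length(x$kmer)

#' Count canonical k-mers
#'
#' Counts every length-`k` window over `{A,C,G,T}` in the input sequences;
#' each window contributes one occurrence to its canonical k-mer (the
#' lexicographic minimum of the window and its reverse complement). Windows
#' containing any non-ACGT symbol (for example `N`) are skipped. Counting is
#' case-insensitive.
#'
#' @param sequences character vector or [Biostrings::DNAStringSet] of
#'   sequences.
#' @param k k-mer length, 1--32. For haplotype binning the workflow uses
#'   k = 21; for cross-haplome repeat coverage k = 27.
#' @return A [KmerSet].
#' @examples
#' count_canonical("ACGT", k = 3)  # ACG twice: CGT is canonicalized to ACG
#' @export
count_canonical <- function(sequences, k) {
  sequences <- as_sequence_vector(sequences)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  res <- cpp_count_canonical(sequences, k)
  KmerSet(res$kmer, res$count, k = k)
}

#' Subtract one k-mer set from another
#'
#' Returns the k-mers of `a` that are absent from `b`, keeping `a`'s counts.
#' Subtraction is by presence/absence -- the counts in `b` are ignored --
#' because haplotype specificity is a membership question: common k-mers
#' between haplotypes are removed from each set regardless of multiplicity.
#'
#' @param a,b [KmerSet] objects with equal `k`.
#' @return A [KmerSet] with `a`'s k, containing `setdiff(a, b)`.
#' @export
kmer_subtract <- function(a, b) {
  stopifnot(inherits(a, "KmerSet"), inherits(b, "KmerSet"))
  if (a$k != b$k) stop(sprintf("k mismatch: %d vs %d", a$k, b$k))
  keep <- !(a$kmer %in% b$kmer)
  KmerSet(a$kmer[keep], a$count[keep], k = a$k)
}

#' Haplotype-specific k-mers
#'
#' Extracts the k-mers unique to each haplotype: one canonical k-mer set is
#' counted per haplotype and the common k-mers are removed from each, leaving
#' two disjoint haplotype-specific sets. These are the binning signal used to
#' partition long reads or unitigs.
#'
#' @param hap1,hap2 sequences of the two haplotypes (character vector or
#'   `DNAStringSet`).
#' @param k k-mer length (default 21, the binning k).
#' @param min_count optional count floor applied to each haplotype's set
#'   before subtraction (default 1, i.e. no filtering).
#' @return A list with elements `set1` and `set2`, disjoint [KmerSet]s.
#' @export
haplotype_specific_kmers <- function(hap1, hap2, k = 21, min_count = 1L) {
  c1 <- count_canonical(hap1, k)
  c2 <- count_canonical(hap2, k)
  if (min_count > 1L) {
    keep1 <- c1$count >= min_count
    c1 <- KmerSet(c1$kmer[keep1], c1$count[keep1], k = c1$k)
    keep2 <- c2$count >= min_count
    c2 <- KmerSet(c2$kmer[keep2], c2$count[keep2], k = c2$k)
  }
  list(set1 = kmer_subtract(c1, c2), set2 = kmer_subtract(c2, c1))
}

#' Read/write a k-mer set as a two-column text table
#'
#' The on-disk format is the sorted two-column (k-mer, count) dump used by
#' k-mer counting tools.
#'
#' @param x a [KmerSet].
#' @param path file path.
#' @return `write_kmerset` returns `path` invisibly; `read_kmerset` a
#'   [KmerSet].
#' @export
write_kmerset <- function(x, path) {
  stopifnot(inherits(x, "KmerSet"))
  ord <- order(x$kmer)
  utils::write.table(
    data.frame(kmer = x$kmer[ord], count = x$count[ord]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_kmerset
#' @param k expected k-mer length (checked when the file is non-empty).
#' @export
read_kmerset <- function(path, k = NULL) {
  if (file.size(path) == 0)
    return(KmerSet(k = if (is.null(k)) stop("k needed for empty file") else k))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("kmer", "count"),
                           colClasses = c("character", "integer"))
  KmerSet(tab$kmer, tab$count, k = k)
}

# Coerce DNAStringSet / character to a plain named character vector.
as_sequence_vector <- function(x) {
  if (inherits(x, "DNAStringSet") || inherits(x, "XStringSet"))
    return(as.character(x))
  if (is.character(x)) return(x)
  stop("sequences must be a character vector or DNAStringSet")
}
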