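#' Classify sequences into haplotypes with haplotype-specific k-mers
#'
#' The trio-binning-style decision rule: count, for every sequence, the
#' occurrences of canonical k-mers belonging to each haplotype-specific set,
#' normalize each count by the size of its set (`score_i = hits_i /
#' |set_i|`, correcting for unequal haplotype divergence), and label the
#' sequence `hap1` or `hap2` by the larger score. Exactly equal scores
#' (including the no-hit case 0 == 0) give `unassigned` -- a conservative
#' tie rule matching the existence of an unassigned class.
#'
#' @param sequences named character vector (or `DNAStringSet`) of reads or
#'   unitigs.
#' @param set1,set2 disjoint [KmerSet]s of haplotype-specific k-mers with
#'   equal `k`.
#' @param min_hits minimum of `max(hits1, hits2)` required to assign (0 =
#'   no floor).
#' @return A `data.frame` of class `bin_results`: `seq_id`, `length`,
#'   `hits1`, `hits2`, `score1`, `score2`, `label`.
#' @export
classify_sequences <- function(sequences, set1, set2, min_hits = 0L) {
  stopifnot(inherits(set1, "KmerSet"), inherits(set2, "KmerSet"))
  if (set1$k != set2$k) stop("k mismatch between specific sets")
  sequences <- as_sequence_vector(sequences)
  if (is.null(names(sequences)) && length(sequences) > 0)
    names(sequences) <- paste0("seq", seq_along(sequences))
  if (anyDuplicated(names(sequences)))
    stop("duplicate sequence ids")
  hits <- cpp_kmer_hits(sequences, set1$k, set1$kmer, set2$kmer)
  n1 <- length(set1$kmer); n2 <- length(set2$kmer)
  score1 <- if (n1 > 0) hits[, 1] / n1 else rep(0, nrow(hits))
  score2 <- if (n2 > 0) hits[, 2] / n2 else rep(0, nrow(hits))
  label <- ifelse(score1 > score2, "hap1",
                  ifelse(score2 > score1, "hap2", "unassigned"))
  if (min_hits > 0)
    label[pmax(hits[, 1], hits[, 2]) < min_hits] <- "unassigned"
  out <- data.frame(seq_id = as.character(names(sequences)),
                    length = nchar(sequences),
                    hits1 = hits[, 1], hits2 = hits[, 2],
                    score1 = score1, score2 = score2, label = label,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("bin_results", "data.frame")
  out
}

#' @rdname classify_sequences
#' @param sequence a single sequence.
#' @export
classify_sequence <- function(sequence, set1, set2, min_hits = 0L) {
  classify_sequences(stats::setNames(sequence, "seq"), set1, set2, min_hits)
}

#' Partition reads or unitigs into three haplotype files
#'
#' Classifies every record of a FASTA/FASTQ file (or in-memory sequence set)
#' and splits the records into `hap1`, `hap2` and `unassigned` outputs.
#' Every record lands in exactly one partition; with
#' `unassigned_to_both = TRUE` the unassigned records are additionally
#' appended to both haplotype outputs (the treatment used before per-
#' haplotype read assembly, where unassigned reads join each haplotype set).
#'
#' @param fastx path to a FASTA/FASTQ file, or a named character vector.
#' @param set1,set2 haplotype-specific [KmerSet]s.
#' @param outdir output directory; `NULL` suppresses file output.
#' @param unassigned_to_both also append unassigned records to both
#'   haplotype outputs.
#' @param min_hits passed to [classify_sequences].
#' @param format output format, `"fasta"` or `"fastq"`.
#' @return A list with `table` (the [classify_sequences] result),
#'   `partitions` (list of id vectors per label) and, when `outdir` is
#'   given, `files`.
#' @export
partition_sequences <- function(fastx, set1, set2, outdir = NULL,
                                unassigned_to_both = FALSE, min_hits = 0L,
                                format = NULL) {
  if (is.character(fastx) && length(fastx) == 1L && file.exists(fastx) &&
      is.null(names(fastx))) {
    if (is.null(format))
      format <- if (grepl("\\.f(ast)?q(\\.gz)?$", fastx)) "fastq" else "fasta"
    seqs <- read_fastx(fastx, format = format)
  } else {
    seqs <- as_sequence_vector(fastx)
    if (is.null(format)) format <- "fasta"
  }
  tab <- classify_sequences(seqs, set1, set2, min_hits = min_hits)
  parts <- split(tab$seq_id, factor(tab$label,
                                    levels = c("hap1", "hap2", "unassigned")))
  out <- list(table = tab, partitions = parts)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    ext <- if (format == "fastq") "fastq" else "fasta"
    files <- file.path(outdir, paste0(c("hap1", "hap2", "unassigned"),
                                      ".", ext))
    names(files) <- c("hap1", "hap2", "unassigned")
    sel <- list(hap1 = parts$hap1, hap2 = parts$hap2,
                unassigned = parts$unassigned)
    if (unassigned_to_both) {
      sel$hap1 <- c(sel$hap1, parts$unassigned)
      sel$hap2 <- c(sel$hap2, parts$unassigned)
    }
    for (lab in names(files))
      write_atomic(files[[lab]], function(tmp)
        write_fastx(seqs[sel[[lab]]], tmp, format = format))
    out$files <- files
  }
  out
}

#' Extract ultra-long records
#'
#' Keeps exactly the records with length greater than or equal to
#' `min_length` (inclusive threshold; the ultra-long read cutoff of the
#' workflow is 50 kb), preserving order.
#'
#' @param fastx path or named character vector of sequences.
#' @param min_length minimum length in bases (default 50000).
#' @return Named character vector of retained sequences.
#' @export
filter_by_length <- function(fastx, min_length = 50000) {
  seqs <- if (is.character(fastx) && length(fastx) == 1L &&
              file.exists(fastx) && is.null(names(fastx)))
    read_fastx(fastx) else as_sequence_vector(fastx)
  seqs[nchar(seqs) >= min_length]
}

#' Summarize a binning table
#'
#' Per-label record counts, base totals and percentages of total bases
#' (and of total records); base percentages sum to 100 up to rounding.
#'
#' @param table a `bin_results` table from [classify_sequences].
#' @return A `data.frame` with one row per label.
#' @export
partition_report <- function(table) {
  if (nrow(table) == 0) stop("empty binning table")
  labs <- factor(table$label, levels = c("hap1", "hap2", "unassigned"))
  n <- tapply(rep(1L, nrow(table)), labs, sum, default = 0L)
  bases <- tapply(as.numeric(table$length), labs, sum, default = 0)
  data.frame(label = levels(labs), n = as.integer(n), bases = as.numeric(bases),
             pct_reads = 100 * as.integer(n) / nrow(table),
             pct_bases = 100 * as.numeric(bases) / sum(as.numeric(table$length)),
             stringsAsFactors = FALSE, row.names = NULL)
}
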