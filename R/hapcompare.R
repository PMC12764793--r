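#' Per-position cross-haplome k-mer coverage
#'
#' For every target position with a valid (ACGT-only) k-mer starting there,
#' the coverage is the occurrence count of that canonical k-mer in the
#' source sequences' k-mer multiset (KAT sect-style start-position counts).
#' The trailing k-1 positions of a sequence, and positions whose window is
#' interrupted, inherit the last valid start's count; positions inside N
#' runs get 0. With `source = target` the track flags self-repeats
#' (coverage >= 2); with the other haplome as source it flags cross-haplome
#' repeats.
#'
#' @param target named character vector (or `DNAStringSet`) to annotate.
#' @param source sequences whose k-mer multiset provides the counts.
#' @param k k-mer length (default 27, the repeat-coverage k).
#' @return Named list of integer coverage vectors, one per target sequence.
#' @export
kmer_position_coverage <- function(target, source, k = 27) {
  target <- as_sequence_vector(target)
  src <- count_canonical(source, k)
  cov <- cpp_position_coverage(target, as.integer(k), src$kmer, src$count)
  names(cov) <- names(target)
  cov
}

#' Mask repetitive regions by k-mer coverage
#'
#' Positions whose coverage reaches `min_cov` (default 2) are replaced by
#' `N`. Returns the masked sequences together with BED intervals (0-based
#' half-open) of the masked (repetitive) runs and of the remaining
#' unmasked, non-N (nonrepetitive) runs, plus the extracted nonrepetitive
#' sequences named `chrom:start-end`.
#'
#' @param sequences named character vector.
#' @param coverage coverage track from [kmer_position_coverage] (aligned to
#'   `sequences`).
#' @param min_cov minimum coverage to call a position repetitive
#'   (inclusive, default 2).
#' @return A list: `masked`, `repeat_bed`, `nonrepetitive_bed`,
#'   `nonrepetitive_seqs`.
#' @export
mask_repetitive <- function(sequences, coverage, min_cov = 2) {
  sequences <- as_sequence_vector(sequences)
  stopifnot(length(sequences) == length(coverage))
  masked <- character(length(sequences))
  names(masked) <- names(sequences)
  rep_bed <- list(); nonrep_bed <- list()
  nonrep_seqs <- character(0)
  bed_rows <- function(ch, runs) {
    if (length(runs) == 0) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(runs) - 1L,
               end = IRanges::end(runs), stringsAsFactors = FALSE)
  }
  for (i in seq_along(sequences)) {
    ch <- names(sequences)[i]
    seq <- sequences[[i]]
    cov <- coverage[[i]]
    if (nchar(seq) != length(cov))
      stop("coverage track not aligned to sequence ", ch)
    is_rep <- cov >= min_cov
    if (any(is_rep)) {
      v <- strsplit(seq, "", fixed = TRUE)[[1]]
      v[is_rep] <- "N"
      masked[i] <- paste(v, collapse = "")
    } else masked[i] <- seq
    is_n <- strsplit(masked[i], "", fixed = TRUE)[[1]] == "N"
    rep_runs <- IRanges::reduce(IRanges::IRanges(which(is_rep), width = 1L))
    nonrep_runs <- IRanges::reduce(IRanges::IRanges(which(!is_n & !is_rep),
                                                    width = 1L))
    rep_bed[[i]] <- bed_rows(ch, rep_runs)
    nonrep_bed[[i]] <- bed_rows(ch, nonrep_runs)
    if (length(nonrep_runs) > 0) {
      pieces <- substring(seq, IRanges::start(nonrep_runs),
                          IRanges::end(nonrep_runs))
      names(pieces) <- sprintf("%s:%d-%d", ch,
                               IRanges::start(nonrep_runs) - 1L,
                               IRanges::end(nonrep_runs))
      nonrep_seqs <- c(nonrep_seqs, pieces)
    }
  }
  empty_bed <- data.frame(chrom = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  bind <- function(x) { x <- x[!vapply(x, is.null, logical(1))]
    if (length(x) == 0) empty_bed else do.call(rbind, x) }
  list(masked = masked, repeat_bed = bind(rep_bed),
       nonrepetitive_bed = bind(nonrep_bed),
       nonrepetitive_seqs = nonrep_seqs)
}

#' Filter alignment records by length, mapping quality and primary status
#'
#' Alignment length is the query span (`qend - qstart`), used uniformly.
#' Presets bundle the thresholds of the workflow's three uses:
#' `synteny` (length >= 2 kb, MQ >= 60), `dotplot` (length >= 2 kb,
#' MQ > 0, strict) and `unitig` (length >= 100 bp, MQ >= 50).
#'
#' @param records an [alignment_records] table.
#' @param min_len minimum query span (inclusive).
#' @param min_mapq mapping-quality threshold.
#' @param mapq_strict require MQ strictly greater than `min_mapq` (the
#'   dot-plot rule MQ > 0) instead of `>=`.
#' @param primary_only keep primary alignments only (default `TRUE`).
#' @param preset optional `"synteny"`, `"dotplot"` or `"unitig"`; overrides
#'   the threshold arguments.
#' @return The filtered records.
#' @export
filter_alignments <- function(records, min_len = 0, min_mapq = 0,
                              mapq_strict = FALSE, primary_only = TRUE,
                              preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("synteny", "dotplot", "unitig"))
    th <- switch(preset,
                 synteny = list(len = 2000, mq = 60, strict = FALSE),
                 dotplot = list(len = 2000, mq = 0, strict = TRUE),
                 unitig = list(len = 100, mq = 50, strict = FALSE))
    min_len <- th$len; min_mapq <- th$mq; mapq_strict <- th$strict
  }
  len <- records$qend - records$qstart
  mq_ok <- if (mapq_strict) records$mapq > min_mapq else
    records$mapq >= min_mapq
  keep <- len >= min_len & mq_ok
  if (primary_only) keep <- keep & records$primary
  records[keep, , drop = FALSE]
}

#' Decompose an extended CIGAR into variation categories
#'
#' Parses `=`/`X`/`I`/`D`/`S` operations and classifies each run:
#' `=` is matched sequence; `X` single-nucleotide variation; `I`/`D` runs
#' shorter than `sv_cutoff` (50 bp) are INDELs and runs at or above it are
#' PAVs; soft-clips (`S`) are tallied once as soft-clipped bases and, when
#' >= `sv_cutoff`, additionally counted as PAV events (without
#' double-counting their bases). Identity is matched bases over the total
#' alignment length (matches + mismatches + insertions + deletions +
#' soft-clips). Ambiguous `M` operations are rejected: alignments must be
#' produced with extended CIGARs (e.g. minimap2 `--eqx`). Hard-clips are
#' ignored.
#'
#' @param cigar character vector of extended CIGAR strings (or an
#'   [alignment_records] table, whose `query`/`target` ids are carried
#'   through).
#' @param sv_cutoff structural-variant length cutoff in bases (default 50).
#' @return A `data.frame` with one row per alignment: `match_len`,
#'   `snv_count`, `snv_len`, `indel_count`, `indel_len`, `pav_count`,
#'   `pav_len`, `pav_internal_len`, `sc_len`, `total_len`, `identity`.
#' @export
parse_cigar_variation <- function(cigar, sv_cutoff = 50) {
  ids <- NULL
  if (is.data.frame(cigar)) {
    ids <- cigar[, intersect(c("query", "target"), names(cigar)),
                 drop = FALSE]
    cigar <- cigar$cigar
  }
  if (any(is.na(cigar))) stop("missing CIGAR string")
  ops_l <- GenomicAlignments::explodeCigarOps(cigar)
  lens_l <- GenomicAlignments::explodeCigarOpLengths(cigar)
  one <- function(ops, lens) {
    if (any(ops == "M"))
      stop("ambiguous 'M' CIGAR operation: re-align with extended CIGARs (--eqx)")
    bad <- setdiff(unique(ops), c("=", "X", "I", "D", "S", "H"))
    if (length(bad) > 0)
      stop("unsupported CIGAR operation: ", paste(bad, collapse = ", "))
    keep <- ops != "H"
    ops <- ops[keep]; lens <- lens[keep]
    indel <- ops %in% c("I", "D")
    sc <- ops == "S"
    big <- lens >= sv_cutoff
    match_len <- sum(lens[ops == "="])
    snv_len <- sum(lens[ops == "X"])
    indel_len <- sum(lens[indel & !big])
    pav_internal <- sum(lens[indel & big])
    sc_len <- sum(lens[sc])
    total <- match_len + snv_len + indel_len + pav_internal + sc_len
    c(match_len = match_len,
      snv_count = snv_len,  # every mismatched base is one SNV
      snv_len = snv_len,
      indel_count = sum(indel & !big), indel_len = indel_len,
      pav_count = sum(indel & big) + sum(sc & big),
      pav_len = pav_internal + sum(lens[sc & big]),
      pav_internal_len = pav_internal, sc_len = sc_len,
      total_len = total,
      identity = if (total > 0) match_len / total else NA_real_)
  }
  rows <- mapply(one, ops_l, lens_l, SIMPLIFY = TRUE)
  out <- as.data.frame(t(rows), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(ids)) out <- cbind(ids, out)
  out
}

#' Identity summary per group
#'
#' Summarizes [parse_cigar_variation] breakdowns by a grouping column
#' (default the target chromosome): number of alignments, median and
#' quartile identity, and the aggregate proportion of bases in each
#' variation category (match, SNV, INDEL, internal PAV, soft-clip).
#'
#' @param breakdowns output of [parse_cigar_variation] (with id columns).
#' @param group_by grouping column name, or `NULL` for a single group.
#' @return A `data.frame` with one row per group.
#' @export
identity_summary <- function(breakdowns, group_by = "target") {
  if (nrow(breakdowns) == 0) stop("no alignments to summarize")
  grp <- if (!is.null(group_by) && group_by %in% names(breakdowns))
    breakdowns[[group_by]] else rep("all", nrow(breakdowns))
  pieces <- split(breakdowns, grp)
  do.call(rbind, Map(function(g, b) {
    tot <- sum(b$total_len)
    data.frame(group = g,
               n = nrow(b),
               median_identity = stats::median(b$identity),
               q1_identity = unname(stats::quantile(b$identity, 0.25)),
               q3_identity = unname(stats::quantile(b$identity, 0.75)),
               prop_match = sum(b$match_len) / tot,
               prop_snv = sum(b$snv_len) / tot,
               prop_indel = sum(b$indel_len) / tot,
               prop_pav = sum(b$pav_internal_len) / tot,
               prop_sc = sum(b$sc_len) / tot,
               stringsAsFactors = FALSE, row.names = NULL)
  }, names(pieces), pieces))
}

#' Repetitive/nonrepetitive base counts per window
#'
#' For every fixed-origin window, counts the bases covered by the repeat
#' BED, by the nonrepetitive BED, and the remaining (N/gap) bases; the
#' three counts sum to the window length.
#'
#' @param repeat_bed,nonrepetitive_bed disjoint BED data frames (0-based
#'   half-open).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window_size window in bases (default 1e6).
#' @return Data frame: `chrom`, `start`, `end`, `repetitive`,
#'   `nonrepetitive`, `n_bases`.
#' @export
windowed_category_coverage <- function(repeat_bed, nonrepetitive_bed,
                                       chrom_lengths, window_size = 1e6) {
  as_ir <- function(bed, ch) {
    b <- bed[bed$chrom == ch, , drop = FALSE]
    IRanges::IRanges(start = b$start + 1L, end = b$end)
  }
  out <- list()
  for (ch in names(chrom_lengths)) {
    rir <- as_ir(repeat_bed, ch)
    nir <- as_ir(nonrepetitive_bed, ch)
    if (length(IRanges::intersect(rir, nir)) > 0)
      stop("repeat and nonrepetitive BEDs overlap on ", ch)
    L <- chrom_lengths[[ch]]
    starts <- seq(0L, max(0L, L - 1L), by = window_size)
    ends <- pmin(starts + window_size, L)
    wir <- IRanges::IRanges(start = starts + 1L, end = ends)
    rep_per_win <- int_bases_per_window(wir, rir)
    non_per_win <- int_bases_per_window(wir, nir)
    out[[ch]] <- data.frame(
      chrom = ch, start = starts, end = ends,
      repetitive = rep_per_win, nonrepetitive = non_per_win,
      n_bases = (ends - starts) - rep_per_win - non_per_win,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# total intersected bases of `ir` within each window of `wir`
int_bases_per_window <- function(wir, ir) {
  if (length(ir) == 0) return(integer(length(wir)))
  hits <- IRanges::findOverlaps(wir, ir)
  if (length(hits) == 0) return(integer(length(wir)))
  pw <- IRanges::pintersect(wir[S4Vectors::queryHits(hits)],
                            ir[S4Vectors::subjectHits(hits)])
  out <- integer(length(wir))
  agg <- tapply(IRanges::width(pw), S4Vectors::queryHits(hits), sum)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}
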