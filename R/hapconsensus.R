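# Substitute alleles into one sequence. `pos` are 1-based positions on
# `seq`, `ref` must match the sequence, events must be sorted and
# non-overlapping. Coordinate shifts from indels are handled by building the
# output from inter-variant segments, which is equivalent to applying the
# events left to right with a running offset.
substitute_alleles <- function(seq, pos, ref, alt, chrom = "?") {
  if (length(pos) == 0) return(seq)
  o <- order(pos)
  pos <- pos[o]; ref <- ref[o]; alt <- alt[o]
  ref_end <- pos + nchar(ref) - 1L
  if (any(pos[-1] <= ref_end[-length(pos)]))
    stop(sprintf("overlapping variants on %s near position %d", chrom,
                 pos[which(pos[-1] <= ref_end[-length(pos)])[1] + 1L]))
  observed <- substring(seq, pos, ref_end)
  bad <- which(observed != ref)
  if (length(bad) > 0)
    stop(sprintf("ref allele mismatch on %s at position %d: expected %s, found %s",
                 chrom, pos[bad[1]], ref[bad[1]], observed[bad[1]]))
  seg_start <- c(1L, ref_end + 1L)
  seg_end <- c(pos - 1L, nchar(seq))
  segments <- substring(seq, seg_start, seg_end)
  paste0(paste0(segments[-length(segments)], alt, collapse = ""),
         segments[length(segments)])
}

#' Select heterozygous sites for consensus construction
#'
#' Keeps exactly the heterozygous, biallelic, phased records meeting the
#' mapping-quality and depth thresholds (both inclusive, the defaults being
#' MQ >= 20 and depth >= 10). Records lacking the annotations are rejected
#' with a warning rather than crashing. Order is preserved.
#'
#' @param variants a [phased_variants] table.
#' @param min_mapq minimum site mapping quality (inclusive).
#' @param min_depth minimum site depth (inclusive).
#' @return The filtered [phased_variants] table.
#' @export
select_heterozygous <- function(variants, min_mapq = 20, min_depth = 10) {
  missing_ann <- is.na(variants$mapq) | is.na(variants$depth)
  if (any(missing_ann))
    warning(sprintf("%d record(s) lack MQ/DP annotations and were rejected",
                    sum(missing_ann)))
  het <- !is.na(variants$gt1) & !is.na(variants$gt2) &
    variants$gt1 != variants$gt2
  biallelic <- !grepl(",", variants$alt, fixed = TRUE) &
    variants$gt1 <= 1L & variants$gt2 <= 1L
  keep <- !missing_ann & het & biallelic & variants$phased &
    variants$mapq >= min_mapq & variants$depth >= min_depth
  variants[keep, , drop = FALSE]
}

#' Build one haplotype consensus from a reference and phased variants
#'
#' Substitutes, for every applied variant, the allele carried by the chosen
#' haplotype into the reference, shifting coordinates through indels left to
#' right. Only records belonging to the designated chromosome-level phase set
#' are applied (by default the phase set with the most sites per chromosome,
#' mirroring the rule that only the longest phase block per pseudo-chromosome
#' carries the long-range phase); the number of skipped records in other
#' (small residual) blocks is reported as an attribute.
#'
#' @param reference named character vector of reference sequences.
#' @param variants a [phased_variants] table (already het-filtered).
#' @param haplotype_index 1 or 2.
#' @param include_indels apply indel records too (default `FALSE`:
#'   SNV-only consensus).
#' @param main_phase_set `"auto"` (largest block per chromosome) or a named
#'   vector of phase-set ids per chromosome.
#' @return Named character vector of haplotype sequences, with attributes
#'   `n_applied` and `n_skipped_other_ps`.
#' @export
apply_haplotype <- function(reference, variants, haplotype_index,
                            include_indels = FALSE,
                            main_phase_set = "auto") {
  stopifnot(haplotype_index %in% 1:2)
  gt_col <- if (haplotype_index == 1L) "gt1" else "gt2"
  v <- variants
  if (!include_indels)
    v <- v[nchar(v$ref) == 1L & nchar(v$alt) == 1L, , drop = FALSE]
  n_skipped <- 0L
  out <- reference
  for (ch in names(reference)) {
    cv <- v[v$chrom == ch, , drop = FALSE]
    if (nrow(cv) > 0) {
      if (identical(main_phase_set, "auto")) {
        ps_sizes <- table(cv$ps)
        main_ps <- names(ps_sizes)[which.max(ps_sizes)]
      } else main_ps <- main_phase_set[[ch]]
      n_skipped <- n_skipped + sum(cv$ps != main_ps)
      cv <- cv[cv$ps == main_ps, , drop = FALSE]
    }
    allele <- ifelse(cv[[gt_col]] == 1L, cv$alt, cv$ref)
    changed <- allele != cv$ref
    out[ch] <- substitute_alleles(reference[[ch]], cv$pos[changed],
                                  cv$ref[changed], allele[changed],
                                  chrom = ch)
  }
  attr(out, "n_applied") <- nrow(v) - n_skipped
  attr(out, "n_skipped_other_ps") <- n_skipped
  out
}

#' Both haplotype consensus sequences at once
#'
#' @inheritParams apply_haplotype
#' @return A list with `hap1` and `hap2`.
#' @export
consensus_haplotypes <- function(reference, variants, include_indels = FALSE,
                                 main_phase_set = "auto") {
  list(hap1 = apply_haplotype(reference, variants, 1L, include_indels,
                              main_phase_set),
       hap2 = apply_haplotype(reference, variants, 2L, include_indels,
                              main_phase_set))
}

# Left-align an anchored indel against the sequence it was called on,
# VCF-normalization style; SNVs pass through unchanged.
left_align_variant <- function(seq, pos, ref, alt) {
  repeat {
    rn <- nchar(ref); an <- nchar(alt)
    if (rn > 1L && an > 1L &&
        substr(ref, rn, rn) == substr(alt, an, an)) {
      ref <- substr(ref, 1L, rn - 1L)
      alt <- substr(alt, 1L, an - 1L)
      next
    }
    if ((rn == 1L || an == 1L) && rn != an && pos > 1L &&
        substr(ref, rn, rn) == substr(alt, an, an)) {
      prev <- substr(seq, pos - 1L, pos - 1L)
      ref <- paste0(prev, substr(ref, 1L, rn - 1L))
      alt <- paste0(prev, substr(alt, 1L, an - 1L))
      pos <- pos - 1L
      next
    }
    break
  }
  # strip shared prefix beyond the anchor base
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &&
         substr(ref, 2L, 2L) == substr(alt, 2L, 2L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

normalize_variant_table <- function(seq, df) {
  if (nrow(df) == 0) return(df)
  for (i in seq_len(nrow(df))) {
    n <- left_align_variant(seq, df$pos[i], df$ref[i], df$alt[i])
    df$pos[i] <- n$pos; df$ref[i] <- n$ref; df$alt[i] <- n$alt
  }
  df[order(df$pos), , drop = FALSE]
}

#' Round-trip validation of consensus construction
#'
#' Re-derives the differences between the two consensus haplotypes by an
#' alignment-free coordinate walk and compares them, chromosome by
#' chromosome, with the heterozygous variants that were applied. For
#' SNV-only inputs the recovery is exact; with indels both sides are
#' left-normalized before comparison. Expected differences are expressed in
#' haplotype-1 coordinates by walking the applied variants with a running
#' offset.
#'
#' @param hap1,hap2 consensus sequences from [apply_haplotype].
#' @param variants the [phased_variants] table that was applied (het sites).
#' @return A list of class `roundtrip_report`: `n_expected`, `n_observed`,
#'   `n_matched`, and `discrepancies` (data frame of unmatched records with a
#'   `side` column).
#' @export
roundtrip_check <- function(hap1, hap2, variants) {
  disc <- list()
  n_exp <- n_obs <- n_match <- 0L
  for (ch in names(hap1)) {
    cv <- variants[variants$chrom == ch & variants$gt1 != variants$gt2, ,
                   drop = FALSE]
    cv <- cv[order(cv$pos), , drop = FALSE]
    # expected diff in hap1 coordinates: allele1 -> allele2 at shifted pos
    a1 <- ifelse(cv$gt1 == 1L, cv$alt, cv$ref)
    a2 <- ifelse(cv$gt2 == 1L, cv$alt, cv$ref)
    delta1 <- nchar(a1) - nchar(cv$ref)
    off <- c(0L, cumsum(delta1))[seq_len(nrow(cv))]
    expected <- data.frame(pos = cv$pos + off, ref = a1, alt = a2,
                           stringsAsFactors = FALSE)
    expected <- expected[expected$ref != expected$alt, , drop = FALSE]
    observed <- cpp_diff_sequences(hap1[[ch]], hap2[[ch]])
    expected <- normalize_variant_table(hap1[[ch]], expected)
    observed <- normalize_variant_table(hap1[[ch]], observed)
    key_e <- paste(expected$pos, expected$ref, expected$alt)
    key_o <- paste(observed$pos, observed$ref, observed$alt)
    n_exp <- n_exp + nrow(expected)
    n_obs <- n_obs + nrow(observed)
    n_match <- n_match + length(intersect(key_e, key_o))
    miss_e <- expected[!(key_e %in% key_o), , drop = FALSE]
    miss_o <- observed[!(key_o %in% key_e), , drop = FALSE]
    if (nrow(miss_e) > 0)
      disc[[length(disc) + 1L]] <- cbind(chrom = ch, miss_e,
                                         side = "expected_only")
    if (nrow(miss_o) > 0)
      disc[[length(disc) + 1L]] <- cbind(chrom = ch, miss_o,
                                         side = "observed_only")
  }
  discrepancies <- if (length(disc) > 0) do.call(rbind, disc) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), side = character(),
               stringsAsFactors = FALSE)
  structure(list(n_expected = n_exp, n_observed = n_obs,
                 n_matched = n_match, discrepancies = discrepancies),
            class = "roundtrip_report")
}

#' @export
print.roundtrip_report <- function(x, ...) {
  cat(sprintf("roundtrip: %d expected, %d observed, %d matched, %d discrepant\n",
              x$n_expected, x$n_observed, x$n_matched,
              nrow(x$discrepancies)))
  invisible(x)
}
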