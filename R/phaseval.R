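#' Non-reference allele ratio per window
#'
#' Tiles each chromosome with fixed-origin windows (default 1 Mb) and
#' computes, per window with at least one phased site, the fraction of sites
#' at which the chosen haplotype carries the non-reference allele. Against a
#' haploid reference derived from one haplotype this ratio tracks phasing
#' accuracy: near 0 (or near 1 after a chromosome-level orientation flip)
#' means consistent phasing; intermediate values flag phase switches.
#'
#' @param variants a [phased_variants] table (phased, sorted).
#' @param haplotype_index which haplotype's alleles to count (1 or 2).
#' @param window_size window size in bases (default 1e6).
#' @param chrom_lengths optional named lengths; when given, empty windows
#'   are emitted with `n_sites = 0` and `nonref_ratio = NA` (undefined).
#' @return Data frame: `chrom`, `start`, `end` (0-based half-open),
#'   `n_sites`, `nonref_ratio`.
#' @export
window_nonref_ratio <- function(variants, haplotype_index = 1L,
                                window_size = 1e6, chrom_lengths = NULL) {
  stopifnot(haplotype_index %in% 1:2)
  if (any(!variants$phased | is.na(variants$gt1) | is.na(variants$gt2)))
    stop("unphased genotype encountered")
  gt <- if (haplotype_index == 1L) variants$gt1 else variants$gt2
  win <- (variants$pos - 1L) %/% as.integer(window_size)
  key <- paste(variants$chrom, win, sep = "\r")
  agg_n <- tapply(gt, key, length)
  agg_alt <- tapply(gt, key, function(x) sum(x == 1L))
  parts <- strsplit(names(agg_n), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[[`, character(1), 1),
    start = as.integer(vapply(parts, `[[`, character(1), 2)) *
      as.integer(window_size),
    n_sites = as.integer(agg_n),
    nonref_ratio = as.numeric(agg_alt) / as.numeric(agg_n),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(chrom_lengths)) {
    tiles <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
      starts <- seq(0L, max(0L, chrom_lengths[[ch]] - 1L), by = window_size)
      data.frame(chrom = ch, start = as.integer(starts),
                 stringsAsFactors = FALSE)
    }))
    out <- merge(tiles, out, by = c("chrom", "start"), all.x = TRUE)
    out$n_sites[is.na(out$n_sites)] <- 0L
  }
  out$end <- out$start + as.integer(window_size)
  if (!is.null(chrom_lengths))
    out$end <- pmin(out$end, as.integer(chrom_lengths[out$chrom]))
  out <- out[order(out$chrom, out$start),
             c("chrom", "start", "end", "n_sites", "nonref_ratio")]
  rownames(out) <- NULL
  out
}

#' Phase-switch-rate estimate from window ratios
#'
#' The median, over windows with at least one site, of the non-reference
#' allele ratio -- by default folded as `min(r, 1 - r)` so the estimate is
#' agnostic of the chromosome-level orientation of the haplotype relative to
#' the reference. Restrict `chroms` to chromosomes free of recombination and
#' large homozygous runs, where the ratio purely reflects switch errors.
#'
#' @param ratios output of [window_nonref_ratio].
#' @param chroms optional chromosome subset.
#' @param fold fold ratios about 0.5 (default `TRUE`).
#' @return The median switch-rate estimate (scalar).
#' @export
switch_rate <- function(ratios, chroms = NULL, fold = TRUE) {
  r <- ratios
  if (!is.null(chroms)) r <- r[r$chrom %in% chroms, , drop = FALSE]
  x <- r$nonref_ratio[r$n_sites > 0 & !is.na(r$nonref_ratio)]
  if (length(x) == 0) stop("no windows with phased sites")
  if (fold) x <- pmin(x, 1 - x)
  stats::median(x)
}

#' Phase-block statistics
#'
#' Groups phased sites by their phase-set (PS) tag per chromosome and
#' reports, per block, its first and last site positions, site count and
#' span, and per chromosome the number of blocks, the largest block span and
#' the fraction of phased sites in the largest block.
#'
#' @param variants a [phased_variants] table with PS tags.
#' @return A list with `blocks` and `per_chrom` data frames.
#' @export
phase_block_stats <- function(variants) {
  key <- paste(variants$chrom, variants$ps, sep = "\r")
  first <- tapply(variants$pos, key, min)
  last <- tapply(variants$pos, key, max)
  n <- tapply(variants$pos, key, length)
  parts <- strsplit(names(first), "\r", fixed = TRUE)
  blocks <- data.frame(
    chrom = vapply(parts, `[[`, character(1), 1),
    ps = vapply(parts, `[[`, character(1), 2),
    first = as.integer(first), last = as.integer(last),
    n_sites = as.integer(n), span = as.integer(last - first),
    stringsAsFactors = FALSE, row.names = NULL)
  blocks <- blocks[order(blocks$chrom, blocks$first), ]
  rownames(blocks) <- NULL
  per_chrom <- do.call(rbind, lapply(split(blocks, blocks$chrom), function(b) {
    big <- which.max(b$span)
    data.frame(chrom = b$chrom[1], n_blocks = nrow(b),
               largest_span = b$span[big],
               largest_n_sites = b$n_sites[big],
               frac_sites_in_largest = b$n_sites[big] / sum(b$n_sites),
               stringsAsFactors = FALSE)
  }))
  rownames(per_chrom) <- NULL
  list(blocks = blocks, per_chrom = per_chrom)
}

#' Select the longest phase block per chromosome
#'
#' Returns only the sites of the block with the greatest span on each
#' chromosome (the block providing the chromosome-level long-range phase).
#' Ties are broken by site count, then by smallest PS value.
#'
#' @param variants a [phased_variants] table with PS tags.
#' @return The subset of `variants` in the selected blocks.
#' @export
select_longest_block <- function(variants) {
  stats <- phase_block_stats(variants)$blocks
  keep <- do.call(rbind, lapply(split(stats, stats$chrom), function(b) {
    ord <- order(-b$span, -b$n_sites, b$ps)
    b[ord[1], c("chrom", "ps")]
  }))
  sel <- paste(variants$chrom, variants$ps, sep = "\r") %in%
    paste(keep$chrom, keep$ps, sep = "\r")
  variants[sel, , drop = FALSE]
}

#' Discordance between two phasings of the same sites
#'
#' Matches sites of two phased variant sets by (chrom, pos, ref, alt),
#' globally orients the second to the first per chromosome (choosing the
#' orientation minimizing mismatches, so a whole-chromosome phase flip is
#' not discordance), and counts the sites whose haplotype-1 allele still
#' differs -- the allele-difference statistic used to compare two phasings
#' or a phasing against a linkage map.
#'
#' @param a,b [phased_variants] tables phased against the same reference.
#' @param window_size window for per-window counts (default 1e6).
#' @return A list: `n_shared`, `n_discordant`, `percent`, `orientation`
#'   (per-chromosome flip flags), `per_window` (data frame).
#' @export
compare_phasings <- function(a, b, window_size = 1e6) {
  key_a <- paste(a$chrom, a$pos, a$ref, a$alt)
  key_b <- paste(b$chrom, b$pos, b$ref, b$alt)
  shared <- intersect(key_a, key_b)
  if (length(shared) == 0) stop("no shared sites between the two phasings")
  ia <- match(shared, key_a); ib <- match(shared, key_b)
  chrom <- a$chrom[ia]; pos <- a$pos[ia]
  g_a <- a$gt1[ia]; g_b <- b$gt1[ib]
  flip <- vapply(split(seq_along(shared), chrom), function(idx) {
    mism <- sum(g_a[idx] != g_b[idx])
    mism_f <- sum(g_a[idx] != (1L - g_b[idx]))
    mism_f < mism
  }, logical(1))
  g_b_oriented <- ifelse(flip[chrom], 1L - g_b, g_b)
  disc <- g_a != g_b_oriented
  win <- (pos - 1L) %/% as.integer(window_size)
  per_window <- stats::aggregate(
    data.frame(n_sites = rep(1L, length(disc)), n_discordant = as.integer(disc)),
    by = list(chrom = chrom, start = win * as.integer(window_size)), FUN = sum)
  per_window <- per_window[order(per_window$chrom, per_window$start), ]
  rownames(per_window) <- NULL
  list(n_shared = length(shared), n_discordant = sum(disc),
       percent = 100 * sum(disc) / length(shared),
       orientation = flip, per_window = per_window)
}
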