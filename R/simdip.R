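DNA_BASES <- c("A", "C", "G", "T")

#' Configuration for the synthetic diploid simulator
#'
#' Defines the study conditions the simulator emulates: a diploid genome with
#' heterozygous SNVs, small indels (< 50 bp) and presence/absence variants
#' (PAVs, >= 50 bp, present in one haplotype and absent in the other), plus
#' planted multicopy repeats that are identical between haplotypes and free
#' of heterozygous variation (emulating the het-poor repeat space where k-mer
#' binning has no signal).
#'
#' The default SNV rate of 0.05/bp reflects the 1-SNP-per-20-bp divergence
#' typical of highly heterozygous allogamous grasses; `heterozygosity_preset`
#' scales the SNV rate to the overall heterozygosity estimates of the two
#' genotypes the workflow was developed on (2.21% and 3.49%).
#'
#' @param n_chromosomes number of chromosome pairs (default 7, matching a
#'   2n = 2x = 14 karyotype).
#' @param chrom_length chromosome length in bases.
#' @param snv_rate heterozygous SNVs per base (default 0.05 = 1 per 20 bp).
#' @param indel_rate heterozygous small indels per base.
#' @param indel_max_len maximum indel length in bases (must be < 50 so the
#'   simulated variant classes respect the 50 bp SV cutoff).
#' @param pav_rate PAV events per base.
#' @param pav_len_range length range of PAV events (minimum >= 50).
#' @param repeat_fraction proportion of each chromosome occupied by planted
#'   multicopy repeat arrays.
#' @param seed integer seed; identical seed and config give byte-identical
#'   output.
#' @return A list of class `diploid_sim_config`.
#' @export
diploid_sim_config <- function(n_chromosomes = 7L, chrom_length = 1e6,
                               snv_rate = 0.05, indel_rate = 0,
                               indel_max_len = 10L, pav_rate = 0,
                               pav_len_range = c(50L, 500L),
                               repeat_fraction = 0.15, seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              snv_rate = snv_rate, indel_rate = indel_rate,
              indel_max_len = as.integer(indel_max_len),
              pav_rate = pav_rate,
              pav_len_range = as.integer(pav_len_range),
              repeat_fraction = repeat_fraction, seed = as.integer(seed))
  stopifnot(cfg$n_chromosomes >= 1L, cfg$chrom_length >= 1L)
  if (cfg$snv_rate < 0 || cfg$indel_rate < 0 || cfg$pav_rate < 0)
    stop("all rates must be >= 0")
  if (cfg$indel_max_len >= 50L) stop("indel_max_len must be < 50 bp")
  if (length(cfg$pav_len_range) != 2L || cfg$pav_len_range[1] < 50L)
    stop("pav_len_range minimum must be >= 50 bp")
  if (cfg$repeat_fraction < 0 || cfg$repeat_fraction >= 1)
    stop("repeat_fraction must be in [0, 1)")
  class(cfg) <- "diploid_sim_config"
  cfg
}

#' @rdname diploid_sim_config
#' @param preset `"lp"` (Lolium perenne-like, heterozygosity 2.21%) or
#'   `"lm"` (L. multiflorum-like, heterozygosity 3.49%). The preset sets the
#'   SNV rate to heterozygosity/100; other fields can be overridden via
#'   `...`.
#' @param ... overrides passed to [diploid_sim_config].
#' @export
heterozygosity_preset <- function(preset = c("lp", "lm"), ...) {
  preset <- match.arg(preset)
  rate <- switch(preset, lp = 0.0221, lm = 0.0349)
  args <- list(...)
  args$snv_rate <- rate
  do.call(diploid_sim_config, args)
}

#' Ground truth of a simulated diploid
#'
#' Holds everything downstream modules are checked against: the sampled
#' heterozygous variants (`variants`; `pos` is the 1-based position on
#' haplotype 1, `ref_pos`/`ref_hap` locate the site on the emitted
#' reference), the per-read source haplotypes (`read_labels`), deliberately
#' flipped phased sites (`switch_points`), the haplotype blocks of the mosaic
#' reference (`mosaic_blocks`, 0-based half-open reference coordinates) and
#' the planted repeat footprints (`repeats`, 0-based half-open haplotype-1
#' coordinates).
#'
#' @param variants,read_labels,switch_points,mosaic_blocks,repeats component
#'   data frames (see Details).
#' @return A list of class `truth_set`.
#' @export
truth_set <- function(variants, read_labels = NULL, switch_points = NULL,
                      mosaic_blocks = NULL, repeats = NULL) {
  empty <- function(...) {
    cols <- list(...)
    as.data.frame(cols, stringsAsFactors = FALSE)
  }
  if (is.null(read_labels))
    read_labels <- empty(read_id = character(), haplotype = integer())
  if (is.null(switch_points))
    switch_points <- empty(chrom = character(), pos = integer())
  if (is.null(mosaic_blocks))
    mosaic_blocks <- empty(chrom = character(), start = integer(),
                           end = integer(), haplotype = integer())
  if (is.null(repeats))
    repeats <- empty(chrom = character(), start = integer(), end = integer())
  ts <- list(variants = variants, read_labels = read_labels,
             switch_points = switch_points, mosaic_blocks = mosaic_blocks,
             repeats = repeats)
  class(ts) <- "truth_set"
  validate_truth_set(ts)
  ts
}

validate_truth_set <- function(ts) {
  v <- ts$variants
  if (nrow(v) > 0) {
    if (any(!nzchar(v$ref)) || any(!nzchar(v$alt)))
      stop("truth variants must have non-empty alleles")
    snv <- v$class == "SNV"
    if (any(nchar(v$ref[snv]) != 1L) || any(nchar(v$alt[snv]) != 1L))
      stop("SNV alleles must have length 1")
    for (ch in unique(v$chrom)) {
      p <- v$pos[v$chrom == ch]
      if (any(diff(p) <= 0))
        stop("variant positions must be strictly increasing per chromosome")
    }
  }
  if (anyDuplicated(ts$read_labels$read_id))
    stop("duplicate read ids in read_labels")
  invisible(ts)
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf(
    "truth_set: %d variants (%s), %d reads, %d switch points, %d mosaic blocks\n",
    nrow(x$variants),
    paste(names(table(x$variants$class)), table(x$variants$class),
          sep = "=", collapse = " "),
    nrow(x$read_labels), nrow(x$switch_points), nrow(x$mosaic_blocks)))
  invisible(x)
}

# Plant multicopy repeat arrays into base vector `v`; two identical copies of
# each array, never overlapping previously occupied positions.
plant_repeats <- function(v, occupied, repeat_fraction) {
  L <- length(v)
  placed <- data.frame(start = integer(), end = integer())
  target <- floor(repeat_fraction * L)
  if (target < 100) return(list(v = v, occupied = occupied, placed = placed))
  amin <- max(100L, min(5000L, L %/% 20L))
  amax <- max(amin, min(40000L, L %/% 6L))
  planted <- 0L
  tries <- 0L
  while (planted < target && tries < 200L) {
    tries <- tries + 1L
    alen <- sample(amin:amax, 1L)
    if (2L * alen > target - planted + amax) alen <- max(amin, (target - planted) %/% 2L)
    content <- sample(DNA_BASES, alen, replace = TRUE)
    spots <- integer(0)
    for (copy in 1:2) {
      ok <- FALSE
      for (att in 1:50) {
        s <- sample.int(L - alen + 1L, 1L)
        idx <- s:(s + alen - 1L)
        if (!any(occupied[idx])) { ok <- TRUE; break }
      }
      if (!ok) break
      occupied[idx] <- TRUE
      v[idx] <- content
      spots <- c(spots, s)
    }
    if (length(spots) > 0) {
      placed <- rbind(placed, data.frame(start = spots - 1L,
                                         end = spots - 1L + alen))
      planted <- planted + length(spots) * alen
    }
  }
  list(v = v, occupied = occupied, placed = placed)
}

#' Simulate a synthetic heterozygous diploid genome
#'
#' Generates haplotype 1 as random sequence with planted multicopy repeats,
#' samples non-overlapping heterozygous variants (rejection sampling keeps
#' event footprints disjoint and outside repeat arrays, so the truth is
#' unambiguous), and derives haplotype 2 by applying the variants. All
#' variants carry their alternate allele on haplotype 2.
#'
#' @param config a [diploid_sim_config].
#' @return A list with `hap1`, `hap2` (named character vectors of chromosome
#'   sequences) and `truth` (a [truth_set]).
#' @export
simulate_diploid <- function(config) {
  stopifnot(inherits(config, "diploid_sim_config"))
  set.seed(config$seed)
  L <- config$chrom_length
  if (config$pav_rate > 0 && L < config$pav_len_range[2] + 10L)
    stop(sprintf("chromosome length %d too short for PAV lengths up to %d",
                 L, config$pav_len_range[2]))
  hap1 <- hap2 <- character(config$n_chromosomes)
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  all_vars <- list()
  all_reps <- list()
  for (ci in seq_len(config$n_chromosomes)) {
    v <- sample(DNA_BASES, L, replace = TRUE)
    occupied <- logical(L)
    occupied[1L] <- TRUE  # keep position 1 anchored for VCF-style events
    occupied[L] <- TRUE
    rep_out <- plant_repeats(v, occupied, config$repeat_fraction)
    v <- rep_out$v; occupied <- rep_out$occupied
    if (nrow(rep_out$placed) > 0)
      all_reps[[ci]] <- data.frame(chrom = chrom_names[ci], rep_out$placed,
                                   stringsAsFactors = FALSE)
    pos <- integer(0); ref <- character(0); alt <- character(0)
    cls <- character(0)
    pad <- 25L  # clean flank around indel/PAV events keeps the truth
                # recoverable by coordinate-walk re-derivation
    add_indel_like <- function(len, class) {
      insertion <- stats::runif(1) < 0.5
      flen <- if (insertion) 1L else len
      if (L <= flen + 2L * (pad + 2L)) return(FALSE)
      p <- NA_integer_
      for (att in 1:100) {
        cand <- sample(seq.int(pad + 2L, L - flen - pad - 1L), 1L)
        idx <- (cand - pad):(cand + flen + pad)
        if (!any(occupied[idx])) { p <- cand; break }
      }
      if (is.na(p)) return(FALSE)
      occupied[(p - pad):(p + flen + pad)] <<- TRUE
      anchor <- v[p]
      if (insertion) {
        pos <<- c(pos, p); ref <<- c(ref, anchor)
        alt <<- c(alt, paste(c(anchor, sample(DNA_BASES, len, TRUE)),
                             collapse = ""))
      } else {
        pos <<- c(pos, p)
        ref <<- c(ref, paste(v[p:(p + len)], collapse = ""))
        alt <<- c(alt, anchor)
      }
      cls <<- c(cls, class)
      TRUE
    }
    n_pav <- stats::rbinom(1L, L, config$pav_rate)
    for (i in seq_len(n_pav))
      add_indel_like(sample(config$pav_len_range[1]:config$pav_len_range[2], 1L),
                     "PAV")
    n_ind <- stats::rbinom(1L, L, config$indel_rate)
    for (i in seq_len(n_ind))
      add_indel_like(sample.int(config$indel_max_len, 1L), "INDEL")
    n_snv <- stats::rbinom(1L, L, config$snv_rate)
    free <- which(!occupied)
    if (n_snv > length(free)) n_snv <- length(free)
    if (n_snv > 0) {
      p_snv <- sort(sample(free, n_snv))
      refb <- v[p_snv]
      altb <- vapply(refb, function(b) sample(setdiff(DNA_BASES, b), 1L),
                     character(1), USE.NAMES = FALSE)
      pos <- c(pos, p_snv); ref <- c(ref, refb); alt <- c(alt, altb)
      cls <- c(cls, rep("SNV", n_snv))
    }
    ord <- order(pos)
    pos <- pos[ord]; ref <- ref[ord]; alt <- alt[ord]; cls <- cls[ord]
    hap1[ci] <- paste(v, collapse = "")
    hap2[ci] <- substitute_alleles(hap1[ci], pos, ref, alt)
    if (length(pos) > 0)
      all_vars[[ci]] <- data.frame(chrom = chrom_names[ci], pos = pos,
                                   ref = ref, alt = alt, class = cls,
                                   hap_alt = 2L, stringsAsFactors = FALSE)
  }
  names(hap1) <- names(hap2) <- chrom_names
  variants <- if (length(all_vars) > 0) do.call(rbind, all_vars) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), class = character(), hap_alt = integer(),
               stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  variants$ref_pos <- variants$pos   # reference defaults to haplotype 1
  variants$ref_hap <- rep(1L, nrow(variants))
  repeats <- if (length(all_reps) > 0) do.call(rbind, all_reps) else NULL
  mosaic <- data.frame(chrom = chrom_names, start = 0L,
                       end = nchar(hap1), haplotype = 1L,
                       stringsAsFactors = FALSE)
  list(hap1 = hap1, hap2 = hap2,
       truth = truth_set(variants, mosaic_blocks = mosaic, repeats = repeats))
}

#' Build a mosaic haploid reference
#'
#' Concatenates alternating blocks of the two haplotypes into one haploid
#' reference per chromosome, emulating an unphased haploid assembly whose
#' alleles alternate between haplotypes. Block boundaries are drawn outside
#' variant footprints, so no boundary ever splits an allele (in particular no
#' PAV allele). With `n_switches_per_chrom = 0` the reference is haplotype 1
#' verbatim.
#'
#' @param hap1,hap2 haplotype sequences from [simulate_diploid].
#' @param truth the matching [truth_set].
#' @param n_switches_per_chrom number of haplotype switches per chromosome.
#' @param seed optional seed for breakpoint sampling.
#' @return A list with `reference` (named character vector) and `truth` (the
#'   updated [truth_set]: `mosaic_blocks` filled, variant `ref_pos`/`ref_hap`
#'   mapped onto the reference).
#' @export
make_mosaic_reference <- function(hap1, hap2, truth, n_switches_per_chrom = 0L,
                                  seed = NULL) {
  stopifnot(inherits(truth, "truth_set"))
  if (!is.null(seed)) set.seed(seed)
  n_switches_per_chrom <- as.integer(n_switches_per_chrom)
  chroms <- names(hap1)
  reference <- character(length(chroms))
  names(reference) <- chroms
  blocks_out <- list()
  vars <- truth$variants
  for (ch in chroms) {
    sel <- which(vars$chrom == ch)
    cv <- vars[sel, , drop = FALSE]
    L1 <- nchar(hap1[[ch]])
    delta <- nchar(cv$alt) - nchar(cv$ref)
    foot_end <- cv$pos + nchar(cv$ref) - 1L
    # hap1 -> hap2 coordinate offset for a breakpoint after position x
    off_at <- function(x) if (nrow(cv) == 0) 0L else
      sum(delta[foot_end <= x])
    if (n_switches_per_chrom > 0) {
      blocked <- logical(L1)
      for (i in seq_len(nrow(cv)))
        blocked[max(1L, cv$pos[i] - 1L):min(L1, foot_end[i] + 1L)] <- TRUE
      blocked[L1] <- TRUE
      cand <- which(!blocked)
      bp <- sort(sample(cand, min(n_switches_per_chrom, length(cand))))
    } else bp <- integer(0)
    bounds <- c(0L, bp, L1)
    haps <- rep(c(1L, 2L), length.out = length(bounds) - 1L)
    pieces <- character(length(haps))
    ref_cursor <- 0L
    blk <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), haplotype = integer(0))
    for (j in seq_along(haps)) {
      s <- bounds[j]; e <- bounds[j + 1L]
      if (haps[j] == 1L) {
        pieces[j] <- substr(hap1[[ch]], s + 1L, e)
      } else {
        s2 <- s + off_at(s); e2 <- e + off_at(e)
        pieces[j] <- substr(hap2[[ch]], s2 + 1L, e2)
      }
      plen <- nchar(pieces[j])
      blk <- rbind(blk, data.frame(chrom = ch, start = ref_cursor,
                                   end = ref_cursor + plen,
                                   haplotype = haps[j],
                                   stringsAsFactors = FALSE))
      # map variants inside this block onto reference coordinates
      inside <- which(cv$pos > s & cv$pos <= e)
      if (length(inside) > 0) {
        if (haps[j] == 1L) {
          vars$ref_pos[sel[inside]] <- ref_cursor + (cv$pos[inside] - s)
        } else {
          prev_off <- vapply(inside, function(i)
            if (i == 1L) 0L else sum(delta[seq_len(i - 1L)]), integer(1))
          p2 <- cv$pos[inside] + prev_off
          vars$ref_pos[sel[inside]] <- ref_cursor + (p2 - (s + off_at(s)))
        }
        vars$ref_hap[sel[inside]] <- haps[j]
      }
      ref_cursor <- ref_cursor + plen
    }
    reference[ch] <- paste(pieces, collapse = "")
    blocks_out[[ch]] <- blk
  }
  truth$variants <- vars
  truth$mosaic_blocks <- do.call(rbind, blocks_out)
  rownames(truth$mosaic_blocks) <- NULL
  list(reference = reference, truth = truth)
}

#' Emit a phased VCF from the simulated truth
#'
#' Expresses every simulated heterozygous variant against the (possibly
#' mosaic) reference: inside haplotype-1 reference blocks the record is
#' `REF/ALT` with genotype `0|1`; inside haplotype-2 blocks the alleles are
#' swapped and the genotype is `1|0`. With probability `switch_error_rate`
#' the phase of a site is flipped and the flip position is appended to the
#' truth's `switch_points`. One phase set per chromosome (the position of its
#' first site) is emitted.
#'
#' @param truth a [truth_set] whose variants carry `ref_pos`/`ref_hap`.
#' @param path optional output VCF path.
#' @param switch_error_rate per-site probability of flipping the phase.
#' @param seed optional seed for the flips.
#' @param mapq,depth site annotations written to INFO.
#' @param contig_lengths optional named lengths for the VCF header.
#' @return A list with `variants` (a [phased_variants] table) and `truth`
#'   (with updated `switch_points`).
#' @export
emit_phased_vcf <- function(truth, path = NULL, switch_error_rate = 0,
                            seed = NULL, mapq = 60, depth = 30,
                            contig_lengths = NULL) {
  stopifnot(inherits(truth, "truth_set"))
  if (!is.null(seed)) set.seed(seed)
  v <- truth$variants
  v <- v[order(v$chrom, v$ref_pos), , drop = FALSE]
  on_h1 <- v$ref_hap == 1L
  ref_allele <- ifelse(on_h1, v$ref, v$alt)
  alt_allele <- ifelse(on_h1, v$alt, v$ref)
  gt1 <- ifelse(on_h1, 0L, 1L)
  flip <- stats::runif(nrow(v)) < switch_error_rate
  gt1[flip] <- 1L - gt1[flip]
  ps <- stats::ave(v$ref_pos, v$chrom, FUN = min)
  out <- phased_variants(chrom = v$chrom, pos = v$ref_pos, ref = ref_allele,
                         alt = alt_allele, gt1 = gt1, gt2 = 1L - gt1,
                         phased = TRUE, ps = paste0(v$chrom, ":", ps),
                         mapq = mapq, depth = depth)
  if (any(flip)) {
    truth$switch_points <- rbind(
      truth$switch_points,
      data.frame(chrom = v$chrom[flip], pos = v$ref_pos[flip],
                 stringsAsFactors = FALSE))
  }
  if (!is.null(path))
    write_atomic(path, function(tmp)
      write_phased_vcf(out, tmp, contig_lengths = contig_lengths))
  list(variants = out, truth = truth)
}

# Apply a flat error profile (substitutions:insertions:deletions = 60:20:20)
# to one read given as a character vector of bases.
inject_read_errors <- function(bases, error_rate) {
  n <- length(bases)
  n_err <- stats::rbinom(1L, n, error_rate)
  if (n_err == 0L) return(paste(bases, collapse = ""))
  at <- sample.int(n, n_err)
  type <- sample(c("S", "I", "D"), n_err, replace = TRUE,
                 prob = c(0.6, 0.2, 0.2))
  subs <- at[type == "S"]
  if (length(subs) > 0) {
    cur <- bases[subs]
    repl <- sample(DNA_BASES, length(subs), replace = TRUE)
    clash <- repl == cur
    while (any(clash)) {
      repl[clash] <- sample(DNA_BASES, sum(clash), replace = TRUE)
      clash <- repl == cur
    }
    bases[subs] <- repl
  }
  ins <- character(n)
  ins_at <- at[type == "I"]
  if (length(ins_at) > 0)
    ins[ins_at] <- sample(DNA_BASES, length(ins_at), replace = TRUE)
  keep <- rep(TRUE, n)
  keep[at[type == "D"]] <- FALSE
  bases[!keep] <- ""
  paste(paste0(bases, ins), collapse = "")
}

#' Simulate error-bearing long reads with truth labels
#'
#' Samples reads evenly from both haplotypes and both strands, with
#' log-normally distributed lengths, and applies a flat per-base error rate
#' (substitutions, insertions and deletions at 60:20:20). An ONT-like profile
#' corresponds to `error_rate` around 0.1 (QV 10); a HiFi-like profile to
#' around 0.0005 (QV 33).
#'
#' @param hap1,hap2 haplotype sequences (named character vectors).
#' @param n_reads number of reads, or `NULL` to derive from `depth`.
#' @param depth haploid sequencing depth; total read bases will approximate
#'   `depth` times the (mean) haploid genome size.
#' @param read_length_mean,read_length_sdlog log-normal length parameters
#'   (mean on the natural scale; `sdlog` the log-scale standard deviation).
#' @param read_length_min,read_length_max length clamp in bases.
#' @param error_rate per-base error probability in `[0, 1)`.
#' @param seed optional seed.
#' @return A list with `reads` (named character vector), `qualities`
#'   (flat quality char per read) and `labels` (data frame: `read_id`,
#'   `haplotype`, `chrom`, `start` 0-based, `end`, `strand`).
#' @export
simulate_reads <- function(hap1, hap2, n_reads = NULL, depth = NULL,
                           read_length_mean = 20000,
                           read_length_sdlog = 0.3,
                           read_length_min = 1000,
                           read_length_max = NULL,
                           error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  haps <- list(hap1, hap2)
  lens <- lapply(haps, nchar)
  if (read_length_min > min(unlist(lens)))
    stop(sprintf("requested read length %d exceeds shortest chromosome (%d)",
                 as.integer(read_length_min), min(unlist(lens))))
  G <- (sum(lens[[1]]) + sum(lens[[2]])) / 2
  meanlog <- log(read_length_mean) - read_length_sdlog^2 / 2
  draw_len <- function(n) {
    x <- round(stats::rlnorm(n, meanlog, read_length_sdlog))
    x <- pmax(x, read_length_min)
    if (!is.null(read_length_max)) x <- pmin(x, read_length_max)
    x
  }
  if (is.null(n_reads)) {
    if (is.null(depth)) stop("give n_reads or depth")
    target <- depth * G
    rl <- draw_len(ceiling(target / read_length_mean * 1.3) + 10)
    n_reads <- which(cumsum(rl) >= target)[1]
    if (is.na(n_reads)) n_reads <- length(rl)
    rl <- rl[seq_len(n_reads)]
  } else {
    rl <- draw_len(n_reads)
  }
  hap_of <- sample(1:2, n_reads, replace = TRUE)
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  reads <- character(n_reads)
  lab_chrom <- character(n_reads)
  lab_start <- integer(n_reads)
  for (i in seq_len(n_reads)) {
    h <- haps[[hap_of[i]]]
    hl <- lens[[hap_of[i]]]
    ci <- sample.int(length(h), 1L, prob = hl)
    li <- min(rl[i], hl[ci])
    s <- sample.int(hl[ci] - li + 1L, 1L)
    reads[i] <- substr(h[[ci]], s, s + li - 1L)
    lab_chrom[i] <- names(h)[ci]
    lab_start[i] <- s - 1L
  }
  minus <- which(strand == "-")
  if (length(minus) > 0)
    reads[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[minus])))
  if (error_rate > 0) {
    split <- strsplit(reads, "", fixed = TRUE)
    reads <- vapply(split, inject_read_errors, character(1),
                    error_rate = error_rate)
  }
  ids <- sprintf("read%06d", seq_len(n_reads))
  names(reads) <- ids
  labels <- data.frame(read_id = ids, haplotype = hap_of, chrom = lab_chrom,
                       start = lab_start,
                       end = lab_start + rl, strand = strand,
                       stringsAsFactors = FALSE)
  q <- if (error_rate > 0)
    rawToChar(as.raw(33L + min(93L, round(-10 * log10(error_rate))))) else "I"
  list(reads = reads, qualities = q, labels = labels)
}

#' Write the truth tables of a simulation as TSV
#'
#' @param truth a [truth_set].
#' @param prefix output path prefix; writes `<prefix>.variants.tsv`,
#'   `.read_labels.tsv`, `.switch_points.tsv`, `.mosaic_blocks.tsv`,
#'   `.repeats.tsv`.
#' @return The written paths, invisibly.
#' @export
write_truth_tsv <- function(truth, prefix) {
  stopifnot(inherits(truth, "truth_set"))
  parts <- c("variants", "read_labels", "switch_points", "mosaic_blocks",
             "repeats")
  paths <- paste0(prefix, ".", parts, ".tsv")
  for (i in seq_along(parts))
    utils::write.table(truth[[parts[i]]], paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(paths)
}
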