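#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper over [Biostrings::readDNAStringSet] returning a plain named
#' character vector (the package's working representation for desk-scale
#' sequence sets). The format is taken from the file extension unless given.
#'
#' @param path input file.
#' @param format `"fasta"`, `"fastq"` or `NULL` to guess from the extension.
#' @return Named character vector of sequences.
#' @export
read_fastx <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  out <- as.character(x)
  # keep only the id token, as aligners do
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA or FASTQ
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param format `"fasta"` (default) or `"fastq"`. FASTQ qualities are flat
#'   (the simulator models a flat error rate, not per-base qualities).
#' @param quality_char quality symbol used for FASTQ output.
#' @return `path`, invisibly.
#' @export
write_fastx <- function(seqs, path, format = c("fasta", "fastq"),
                        quality_char = "I") {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  if (format == "fastq") {
    qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
      strrep(quality_char, n), character(1)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}

#' Phased-variant table
#'
#' The package's working representation of phased heterozygous variants is a
#' data frame with one row per site and columns: `chrom`, `pos` (1-based
#' reference position), `ref`, `alt`, `gt1`/`gt2` (allele index carried by
#' haplotype 1/2; 0 = ref, 1 = alt), `phased` (logical; `TRUE` for
#' pipe-separated genotypes), `ps` (phase-set identifier), `mapq` and `depth`
#' (site annotations used by the heterozygous-SNP filter; may be `NA`).
#'
#' @param chrom,pos,ref,alt,gt1,gt2 site fields (recycled to equal length).
#' @param phased logical; defaults to `TRUE`.
#' @param ps phase-set identifier (defaults to one block per chromosome).
#' @param mapq,depth optional site annotations.
#' @return A `data.frame` of class `phased_variants`.
#' @export
phased_variants <- function(chrom, pos, ref, alt, gt1, gt2,
                            phased = TRUE, ps = NULL, mapq = NA_real_,
                            depth = NA_real_) {
  n <- length(pos)
  if (is.null(ps)) ps <- stats::ave(pos, chrom, FUN = min)
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   gt1 = as.integer(gt1), gt2 = as.integer(gt2),
                   phased = rep_len(phased, n), ps = rep_len(ps, n),
                   mapq = rep_len(as.numeric(mapq), n),
                   depth = rep_len(as.numeric(depth), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("phased_variants", "data.frame")
  df
}

#' Read a phased VCF into a phased-variant table
#'
#' Parses a (possibly gzipped) VCF with `vcfR` and extracts the first
#' sample's genotype, phase-set (`PS`) and per-site `MQ`/`DP` annotations
#' (FORMAT `DP` is preferred; INFO `MQ`/`DP` are the fallback).
#' Multiallelic records are kept in the table (with `alt` holding the full
#' comma-separated string); downstream selection rejects them.
#'
#' @param path VCF file.
#' @return A [phased_variants] data frame.
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT", convertNA = FALSE)[, 1]
  ps <- tryCatch(vcfR::extract.gt(v, element = "PS", convertNA = FALSE)[, 1],
                 error = function(e) rep(NA_character_, length(gt_raw)))
  dp <- tryCatch(as.numeric(vcfR::extract.gt(v, element = "DP")[, 1]),
                 error = function(e) rep(NA_real_, length(gt_raw)))
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  }
  mq <- info_num("MQ")
  if (all(is.na(dp))) dp <- info_num("DP")
  phased <- grepl("|", gt_raw, fixed = TRUE)
  a <- sub("^([0-9.]+)[|/].*$", "\\1", gt_raw)
  b <- sub("^[0-9.]+[|/]([0-9.]+).*$", "\\1", gt_raw)
  df <- phased_variants(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT, gt1 = suppressWarnings(as.integer(a)),
    gt2 = suppressWarnings(as.integer(b)), phased = phased,
    ps = ifelse(is.na(ps), paste0(fix$CHROM, ":1"), ps),
    mapq = mq, depth = dp)
  df[order(df$chrom, df$pos), , drop = FALSE]
}

#' Write a phased-variant table as VCF
#'
#' Emits a minimal VCF 4.2 file with `GT:PS` genotypes for one sample and
#' `MQ`/`DP` in INFO.
#'
#' @param variants a [phased_variants] data frame.
#' @param path output file.
#' @param contig_lengths optional named vector of contig lengths for the
#'   header.
#' @param sample sample name.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(variants, path, contig_lengths = NULL,
                             sample = "sample") {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=haplobin",
           '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">',
           '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=PS,Number=1,Type=String,Description="Phase set">')
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample, sep = "\t"))
  sep <- ifelse(variants$phased, "|", "/")
  info <- sprintf("MQ=%g;DP=%g",
                  ifelse(is.na(variants$mapq), 60, variants$mapq),
                  ifelse(is.na(variants$depth), 30, variants$depth))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", "PASS", info, "GT:PS",
                paste0(variants$gt1, sep, variants$gt2, ":", variants$ps),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Alignment-record table
#'
#' Working representation of pairwise alignments (from PAF or SAM): one row
#' per alignment with `query`, `qlen`, `qstart`, `qend` (0-based half-open),
#' `target`, `tlen`, `tstart`, `tend`, `strand`, `mapq`, `primary` and
#' `cigar` (extended CIGAR with `=`/`X`, or `NA` when absent).
#'
#' @param ... fields as named above.
#' @return A `data.frame` of class `alignment_records`.
#' @export
alignment_records <- function(query, qlen, qstart, qend, target, tlen,
                              tstart, tend, strand = "+", mapq = 60L,
                              primary = TRUE, cigar = NA_character_) {
  n <- length(query)
  df <- data.frame(query = as.character(query), qlen = as.integer(qlen),
                   qstart = as.integer(qstart), qend = as.integer(qend),
                   target = as.character(target), tlen = as.integer(tlen),
                   tstart = as.integer(tstart), tend = as.integer(tend),
                   strand = rep_len(strand, n), mapq = rep_len(as.integer(mapq), n),
                   primary = rep_len(primary, n),
                   cigar = rep_len(as.character(cigar), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("alignment_records", "data.frame")
  df
}

#' Read a PAF alignment file
#'
#' Parses the 12 mandatory PAF columns plus the `cg:Z` (extended CIGAR) and
#' `tp:A` (alignment type; `P` = primary) tags when present. There is no
#' installed PAF reader in the supporting libraries, so the (simple,
#' tab-separated) format is parsed here directly.
#'
#' @param path PAF file.
#' @return An [alignment_records] data frame.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(alignment_records(character(), integer(), integer(), integer(),
                             character(), integer(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 12L)
  if (length(bad) > 0)
    stop(sprintf("malformed PAF record at line %d: fewer than 12 fields",
                 bad[1]))
  get <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(i) suppressWarnings(as.integer(get(i)))
  core <- num(2)
  if (anyNA(core) || anyNA(num(3)) || anyNA(num(4)))
    stop(sprintf("malformed PAF record at line %d: non-numeric coordinate",
                 which(is.na(core) | is.na(num(3)) | is.na(num(4)))[1]))
  tag <- function(prefix) {
    vapply(fields, function(f) {
      hit <- f[startsWith(f, prefix)]
      if (length(hit) == 0) NA_character_ else sub(prefix, "", hit[[1]], fixed = TRUE)
    }, character(1))
  }
  tp <- tag("tp:A:")
  alignment_records(
    query = get(1), qlen = num(2), qstart = num(3), qend = num(4),
    target = get(6), tlen = num(7), tstart = num(8), tend = num(9),
    strand = get(5), mapq = num(12),
    primary = is.na(tp) | tp == "P", cigar = tag("cg:Z:"))
}

#' Read SAM-format alignments
#'
#' Parses plain-text SAM records into the same [alignment_records] table as
#' [read_paf] (query coordinates are derived from the CIGAR; soft-clips stay
#' part of the query span context via the CIGAR itself).
#'
#' @param path SAM file (plain text).
#' @return An [alignment_records] data frame (unmapped records dropped).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (length(lines) == 0)
    return(alignment_records(character(), integer(), integer(), integer(),
                             character(), integer(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- as.integer(get(2))
  cig <- get(6)
  mapped <- get(3) != "*" & cig != "*"
  fields <- fields[mapped]; flag <- flag[mapped]; cig <- cig[mapped]
  get <- function(i) vapply(fields, `[[`, character(1), i)
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  qcons <- mapply(function(o, l) sum(l[o %in% c("M", "I", "S", "=", "X")]),
                  ops, lens)
  lead_s <- mapply(function(o, l) if (length(o) > 0 && o[1] == "S") l[1] else 0L,
                   ops, lens)
  tail_s <- mapply(function(o, l) {
    n <- length(o); if (n > 0 && o[n] == "S") l[n] else 0L
  }, ops, lens)
  tcons <- mapply(function(o, l) sum(l[o %in% c("M", "D", "N", "=", "X")]),
                  ops, lens)
  pos <- as.integer(get(4))
  alignment_records(
    query = get(1), qlen = as.integer(qcons),
    qstart = as.integer(lead_s), qend = as.integer(qcons - tail_s),
    target = get(3), tlen = NA_integer_,
    tstart = pos - 1L, tend = pos - 1L + as.integer(tcons),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapq = as.integer(get(5)),
    primary = bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L,
    cigar = cig)
}

#' Read/write BED intervals (0-based half-open)
#'
#' @param path BED file.
#' @return `read_bed`: data frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  data.frame(chrom = as.character(tab[[1]]), start = as.integer(tab[[2]]),
             end = as.integer(tab[[3]]), stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @param bed data frame with `chrom`, `start`, `end`.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-placement table
#'
#' Tab-separated table with columns `gene_id`, `contig`, `start`, `end`,
#' `strand`, `category` (`transcript` or `marker`), emulating mapped
#' transcripts and single-copy ortholog (BUSCO-like) detections.
#'
#' @param path TSV file (with header).
#' @return Data frame with those six columns.
#' @export
read_gene_placements <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "contig", "start", "end", "strand", "category")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("gene placement table lacks columns: ", paste(miss, collapse = ", "))
  tab[, need]
}

# Atomic write helper: run `writer(tmp)` then rename into place.
write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}
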