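# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's compiled paths: plain string manipulation only.

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# String-enumeration canonical k-mer counter.
oracle_count_canonical <- function(seqs, k) {
  tallies <- list()
  for (s in seqs) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) next
    w <- substring(s, 1:(n - k + 1), k:n)
    w <- w[!grepl("[^ACGT]", w)]
    if (length(w) == 0) next
    rc <- vapply(w, oracle_revcomp, character(1), USE.NAMES = FALSE)
    canon <- ifelse(w <= rc, w, rc)
    tallies[[length(tallies) + 1L]] <- canon
  }
  if (length(tallies) == 0) return(integer(0))
  tab <- table(unlist(tallies))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

kmerset_as_named <- function(ks) {
  out <- ks$count
  names(out) <- ks$kmer
  out[order(names(out))]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Per-character CIGAR expansion oracle: expand runs to single-op characters,
# re-derive runs with rle(), and tally categories directly.
oracle_cigar_breakdown <- function(cigar, sv_cutoff = 50) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  expanded <- rep(ops, lens)
  runs <- rle(expanded)
  match_len <- snv_len <- indel_len <- pav_internal <- sc_len <- 0L
  indel_count <- pav_count <- 0L
  for (i in seq_along(runs$values)) {
    op <- runs$values[i]; l <- runs$lengths[i]
    if (op == "=") match_len <- match_len + l
    else if (op == "X") snv_len <- snv_len + l
    else if (op %in% c("I", "D")) {
      if (l >= sv_cutoff) { pav_internal <- pav_internal + l
        pav_count <- pav_count + 1L
      } else { indel_len <- indel_len + l; indel_count <- indel_count + 1L }
    } else if (op == "S") {
      sc_len <- sc_len + l
      if (l >= sv_cutoff) pav_count <- pav_count + 1L
    }
  }
  total <- match_len + snv_len + indel_len + pav_internal + sc_len
  list(match_len = match_len, snv_len = snv_len, indel_len = indel_len,
       indel_count = indel_count, pav_count = pav_count,
       pav_internal_len = pav_internal, sc_len = sc_len, total_len = total,
       identity = match_len / total)
}

random_cigar <- function(n_ops = 8, allow_clip = TRUE) {
  ops <- character(n_ops)
  for (i in seq_len(n_ops)) {  # canonical CIGARs never repeat an op
    repeat {
      o <- sample(c("=", "X", "I", "D"), 1, prob = c(0.5, 0.2, 0.15, 0.15))
      if (i == 1 || o != ops[i - 1]) break
    }
    ops[i] <- o
  }
  lens <- sample(1:120, n_ops, replace = TRUE)
  # runs of '=' must separate other ops to keep rle comparable
  body <- paste0(lens, ops, collapse = "")
  if (allow_clip && runif(1) < 0.5)
    body <- paste0(sample(1:120, 1), "S", body)
  if (allow_clip && runif(1) < 0.5)
    body <- paste0(body, sample(1:120, 1), "S")
  body
}

# Brute-force connected components by breadth-first search.
oracle_components <- function(node_ids, edges) {
  adj <- stats::setNames(vector("list", length(node_ids)), node_ids)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$from[i]]] <- c(adj[[edges$from[i]]], edges$to[i])
    adj[[edges$to[i]]] <- c(adj[[edges$to[i]]], edges$from[i])
  }
  comp <- stats::setNames(integer(length(node_ids)), node_ids)
  cid <- 0L
  for (start in node_ids) {
    if (comp[[start]] != 0L) next
    cid <- cid + 1L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[[v]] != 0L) next
      comp[[v]] <- cid
      queue <- c(queue, setdiff(adj[[v]], names(comp)[comp != 0L]))
    }
  }
  comp
}

# Small standard diploid simulation shared by several tests.
small_sim <- function(seed = 11, chrom_length = 40000, n_chromosomes = 2,
                      snv_rate = 0.01, ...) {
  simulate_diploid(diploid_sim_config(
    n_chromosomes = n_chromosomes, chrom_length = chrom_length,
    snv_rate = snv_rate, seed = seed, ...))
}
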