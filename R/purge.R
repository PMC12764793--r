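#' Pair allelic contigs by micro-synteny
#'
#' Two contigs are called an allelic pair when they share more than
#' `min_shared_genes` transcript-mapped genes lying in one collinear run
#' (strictly greater than, i.e. the default requires at least six shared
#' genes). A run is collinear when the gene order is preserved, or fully
#' reversed, between the two contigs, allowing up to `collinearity_window`
#' intervening genes between consecutive shared genes on the partner contig.
#'
#' @param placements gene-placement table (see [read_gene_placements]); only
#'   `category == "transcript"` rows are used.
#' @param min_shared_genes collinear shared-gene count that must be exceeded
#'   (default 5).
#' @param collinearity_window maximum number of intervening genes tolerated
#'   within a run (default 5).
#' @return Edge table: `from`, `to`, `evidence = "synteny"`, `weight`
#'   (collinear shared-gene count).
#' @export
pair_by_synteny <- function(placements, min_shared_genes = 5,
                            collinearity_window = 5) {
  p <- placements[placements$category == "transcript", , drop = FALSE]
  empty <- data.frame(from = character(), to = character(),
                      evidence = character(), weight = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(p) == 0) return(empty)
  # rank of each gene along its contig
  p <- p[order(p$contig, p$start), , drop = FALSE]
  p$rank <- stats::ave(seq_len(nrow(p)), p$contig, FUN = seq_along)
  contigs_of <- split(p$contig, p$gene_id)
  shared_pairs <- unique(do.call(rbind, lapply(contigs_of, function(cs) {
    cs <- unique(cs)
    if (length(cs) < 2) return(NULL)
    t(utils::combn(sort(cs), 2))
  })))
  if (is.null(shared_pairs) || nrow(shared_pairs) == 0) return(empty)
  edges <- empty
  for (i in seq_len(nrow(shared_pairs))) {
    a <- shared_pairs[i, 1]; b <- shared_pairs[i, 2]
    pa <- p[p$contig == a, ]; pb <- p[p$contig == b, ]
    shared <- intersect(pa$gene_id, pb$gene_id)
    if (length(shared) <= min_shared_genes) next
    pa <- pa[match(shared, pa$gene_id), ]
    ord <- order(pa$rank)
    genes_in_a_order <- shared[ord]
    rank_b <- pb$rank[match(genes_in_a_order, pb$gene_id)]
    run <- best_collinear_run(rank_b, collinearity_window)
    if (run > min_shared_genes)
      edges <- rbind(edges, data.frame(from = a, to = b,
                                       evidence = "synteny",
                                       weight = run,
                                       stringsAsFactors = FALSE))
  }
  edges
}

# Longest run of a sequence of partner ranks that is monotone (either
# direction) with consecutive rank gaps <= window + 1.
best_collinear_run <- function(rank_b, window) {
  n <- length(rank_b)
  if (n <= 1) return(n)
  best <- 1L
  for (dir in c(1L, -1L)) {
    len <- 1L
    for (i in 2:n) {
      step <- dir * (rank_b[i] - rank_b[i - 1L])
      if (step >= 1L && step <= window + 1L) len <- len + 1L else len <- 1L
      if (len > best) best <- len
    }
  }
  best
}

#' Pair allelic contigs by shared single-copy markers
#'
#' Two contigs form an allelic pair when they share at least `min_shared`
#' marker genes (single-copy orthologs standing in for BUSCO genes; default
#' 1, inclusive).
#'
#' @param placements gene-placement table; only `category == "marker"` rows
#'   are used.
#' @param min_shared minimum shared marker count (inclusive).
#' @return Edge table: `from`, `to`, `evidence = "marker"`, `weight`.
#' @export
pair_by_marker <- function(placements, min_shared = 1) {
  p <- placements[placements$category == "marker", , drop = FALSE]
  empty <- data.frame(from = character(), to = character(),
                      evidence = character(), weight = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(p) == 0) return(empty)
  pairs <- do.call(rbind, lapply(split(p$contig, p$gene_id), function(cs) {
    cs <- unique(cs)
    if (length(cs) < 2) return(NULL)
    t(utils::combn(sort(cs), 2))
  }))
  if (is.null(pairs) || nrow(pairs) == 0) return(empty)
  key <- paste(pairs[, 1], pairs[, 2], sep = "\r")
  cnt <- table(key)
  keep <- cnt >= min_shared
  if (!any(keep)) return(empty)
  parts <- strsplit(names(cnt)[keep], "\r", fixed = TRUE)
  data.frame(from = vapply(parts, `[[`, character(1), 1),
             to = vapply(parts, `[[`, character(1), 2),
             evidence = "marker", weight = as.numeric(cnt[keep]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pair allelic contigs by all-vs-all alignment coverage
#'
#' For every aligned contig pair, the alignment intervals on the shorter
#' contig are merged (interval union) and the covered fraction of the
#' shorter contig is computed; pairs at or above `min_coverage_fraction`
#' become edges with that fraction as weight.
#'
#' @param paf an [alignment_records] table (e.g. from [read_paf]) of
#'   contig-vs-contig alignments; self-alignments are ignored.
#' @param min_coverage_fraction minimum covered fraction of the shorter
#'   contig (default 0.7).
#' @return Edge table: `from`, `to`, `evidence = "alignment"`, `weight`.
#' @export
pair_by_alignment <- function(paf, min_coverage_fraction = 0.7) {
  empty <- data.frame(from = character(), to = character(),
                      evidence = character(), weight = numeric(),
                      stringsAsFactors = FALSE)
  paf <- paf[paf$query != paf$target, , drop = FALSE]
  if (nrow(paf) == 0) return(empty)
  a <- pmin(paf$query, paf$target)
  b <- pmax(paf$query, paf$target)
  edges <- empty
  for (key in unique(paste(a, b, sep = "\r"))) {
    rows <- paf[paste(a, b, sep = "\r") == key, , drop = FALSE]
    pq <- strsplit(key, "\r", fixed = TRUE)[[1]]
    lens <- c(rows$qlen[match(pq[1], rows$query)],
              rows$tlen[match(pq[1], rows$target)],
              rows$qlen[match(pq[2], rows$query)],
              rows$tlen[match(pq[2], rows$target)])
    len1 <- max(lens[1:2], na.rm = TRUE)
    len2 <- max(lens[3:4], na.rm = TRUE)
    short <- if (len1 <= len2) pq[1] else pq[2]
    short_len <- min(len1, len2)
    iv_q <- rows[rows$query == short, c("qstart", "qend"), drop = FALSE]
    iv_t <- rows[rows$target == short, c("tstart", "tend"), drop = FALSE]
    starts <- c(iv_q$qstart, iv_t$tstart)
    ends <- c(iv_q$qend, iv_t$tend)
    ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
    frac <- sum(IRanges::width(ir)) / short_len
    if (frac >= min_coverage_fraction)
      edges <- rbind(edges, data.frame(from = pq[1], to = pq[2],
                                       evidence = "alignment",
                                       weight = frac,
                                       stringsAsFactors = FALSE))
  }
  edges
}

#' Assemble an allelic-evidence graph
#'
#' Contigs are nodes; allelic-pair calls from the three evidence lines
#' (alignment, synteny, marker) are typed edges. Any single evidence type
#' suffices to form an edge by default; `require_n_evidences` keeps only
#' pairs supported by at least that many distinct evidence types.
#'
#' @param nodes data frame with `contig` and `length`.
#' @param ... edge tables from [pair_by_synteny], [pair_by_marker],
#'   [pair_by_alignment].
#' @param require_n_evidences minimum number of distinct evidence types per
#'   contig pair (default 1).
#' @return A list of class `allelic_evidence_graph` with `nodes` and
#'   `edges`.
#' @export
allelic_evidence_graph <- function(nodes, ..., require_n_evidences = 1L) {
  edges <- do.call(rbind, list(...))
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        evidence = character(), weight = numeric(),
                        stringsAsFactors = FALSE)
  if (any(edges$from == edges$to)) stop("self-edges are not allowed")
  unknown <- setdiff(c(edges$from, edges$to), nodes$contig)
  if (length(unknown) > 0)
    stop("edges reference contigs absent from the node table: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  if (require_n_evidences > 1L && nrow(edges) > 0) {
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    n_ev <- tapply(edges$evidence, key, function(e) length(unique(e)))
    edges <- edges[n_ev[key] >= require_n_evidences, , drop = FALSE]
  }
  structure(list(nodes = nodes, edges = edges),
            class = "allelic_evidence_graph")
}

#' Purge redundant allelic contigs
#'
#' Within every connected component of the evidence graph exactly one contig
#' is kept -- by default the longest, with ties broken lexicographically by
#' id (multi-way components are thereby resolved in one auditable sweep).
#' Isolated contigs are always kept. The decision log records each purged
#' contig, the contig kept in its place, and the evidence edges supporting
#' the component.
#'
#' @param graph an [allelic_evidence_graph].
#' @param retained_policy `"longest"` (default) or a function
#'   `f(component_nodes_df)` returning the id to keep.
#' @return A list: `kept` and `purged` (character vectors of contig ids) and
#'   `log` (data frame: `purged`, `kept`, `component`, `n_evidence_edges`).
#' @export
purge_redundant <- function(graph, retained_policy = "longest") {
  stopifnot(inherits(graph, "allelic_evidence_graph"))
  nodes <- graph$nodes
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to"), drop = FALSE], directed = FALSE,
    vertices = nodes$contig)
  comp <- igraph::components(g)
  membership <- comp$membership[nodes$contig]
  kept <- character(0); purged <- character(0)
  log <- data.frame(purged = character(), kept = character(),
                    component = integer(), n_evidence_edges = integer(),
                    stringsAsFactors = FALSE)
  edge_key <- paste(pmin(graph$edges$from, graph$edges$to),
                    pmax(graph$edges$from, graph$edges$to))
  for (cid in seq_len(comp$no)) {
    members <- nodes[membership == cid, , drop = FALSE]
    if (nrow(members) == 1L) { kept <- c(kept, members$contig); next }
    winner <- if (is.function(retained_policy)) retained_policy(members) else {
      ord <- order(-members$length, members$contig)
      members$contig[ord[1]]
    }
    losers <- setdiff(members$contig, winner)
    kept <- c(kept, winner)
    purged <- c(purged, losers)
    in_comp <- graph$edges$from %in% members$contig |
      graph$edges$to %in% members$contig
    log <- rbind(log, data.frame(purged = losers, kept = winner,
                                 component = cid,
                                 n_evidence_edges = sum(in_comp),
                                 stringsAsFactors = FALSE))
  }
  list(kept = sort(kept), purged = sort(purged), log = log)
}

#' Marker duplication and loss metrics of a purge
#'
#' Computes, from marker (single-copy ortholog) placements, the percentage
#' of distinct markers retained after purging and the percentage of retained
#' markers still present on more than one kept contig. A purge is flagged
#' successful iff the duplicated-marker rate is strictly below 10% and the
#' marker loss strictly below 5%.
#'
#' @param contigs_before character vector of contig ids before purging.
#' @param contigs_after contig ids kept after purging.
#' @param placements gene-placement table (marker rows used).
#' @param max_duplicated success threshold on the duplicated rate (strict).
#' @param max_loss success threshold on marker loss (strict).
#' @return A list: `n_markers_before`, `n_markers_after`,
#'   `retention_pct`, `loss_pct`, `duplicated_pct`, `success`.
#' @export
duplication_metrics <- function(contigs_before, contigs_after, placements,
                                max_duplicated = 10, max_loss = 5) {
  m <- placements[placements$category == "marker", , drop = FALSE]
  before <- m[m$contig %in% contigs_before, , drop = FALSE]
  after <- m[m$contig %in% contigs_after, , drop = FALSE]
  n_before <- length(unique(before$gene_id))
  n_after <- length(unique(after$gene_id))
  if (n_before == 0) stop("no markers found on the pre-purge contigs")
  per_marker <- tapply(after$contig, after$gene_id,
                       function(x) length(unique(x)))
  dup_pct <- if (n_after > 0) 100 * sum(per_marker > 1L) / n_after else 0
  retention <- 100 * n_after / n_before
  loss <- 100 - retention
  list(n_markers_before = n_before, n_markers_after = n_after,
       retention_pct = retention, loss_pct = loss,
       duplicated_pct = dup_pct,
       success = dup_pct < max_duplicated && loss < max_loss)
}
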