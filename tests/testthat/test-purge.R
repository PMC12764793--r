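# Build a transcript placement table putting `genes` on `contig` in the
# given order (one gene every 1 kb).
place_genes <- function(contig, genes, category = "transcript",
                        reversed = FALSE) {
  if (reversed) genes <- rev(genes)
  data.frame(gene_id = genes, contig = contig,
             start = seq_along(genes) * 1000L,
             end = seq_along(genes) * 1000L + 500L,
             strand = "+", category = category, stringsAsFactors = FALSE)
}

test_that("synteny pairing requires strictly more than five collinear genes", {
  g6 <- paste0("g", 1:6)
  p6 <- rbind(place_genes("A", g6), place_genes("B", g6))
  expect_equal(nrow(pair_by_synteny(p6)), 1L)
  expect_equal(pair_by_synteny(p6)$weight, 6)
  g5 <- paste0("g", 1:5)
  p5 <- rbind(place_genes("A", g5), place_genes("B", g5))
  expect_equal(nrow(pair_by_synteny(p5)), 0L)
  # fully reversed order still counts as collinear
  p6r <- rbind(place_genes("A", g6), place_genes("B", g6, reversed = TRUE))
  expect_equal(nrow(pair_by_synteny(p6r)), 1L)
  # shared genes scattered out of order are not collinear
  set.seed(61)
  scramble <- sample(paste0("g", 1:8))
  ps <- rbind(place_genes("A", paste0("g", 1:8)), place_genes("B", scramble))
  run <- pair_by_synteny(ps)
  if (nrow(run) > 0) expect_lt(run$weight, 8)
  # unrelated gene sets give no edges
  p0 <- rbind(place_genes("A", paste0("a", 1:10)),
              place_genes("B", paste0("b", 1:10)))
  expect_equal(nrow(pair_by_synteny(p0)), 0L)
})

test_that("marker pairing is inclusive at one shared marker", {
  m1 <- rbind(place_genes("A", "bus1", category = "marker"),
              place_genes("B", "bus1", category = "marker"))
  e <- pair_by_marker(m1)
  expect_equal(nrow(e), 1L)
  expect_equal(e$weight, 1)
  none <- rbind(place_genes("A", "bus1", category = "marker"),
                place_genes("B", "bus2", category = "marker"))
  expect_equal(nrow(pair_by_marker(none)), 0L)
  # three contigs sharing one marker yield all three pairwise edges
  m3 <- do.call(rbind, lapply(c("A", "B", "C"), place_genes, genes = "bus1",
                              category = "marker"))
  expect_equal(nrow(pair_by_marker(m3)), 3L)
})

test_that("alignment pairing merges intervals before computing coverage", {
  # contig S (length 1000) fully contained in L
  paf <- alignment_records(query = "S", qlen = 1000, qstart = 0, qend = 1000,
                           target = "L", tlen = 5000, tstart = 100,
                           tend = 1100)
  e <- pair_by_alignment(paf, min_coverage_fraction = 0.9)
  expect_equal(nrow(e), 1L)
  expect_equal(e$weight, 1.0)
  # three intervals on the shorter contig: union [150,500) + [600,700) = 450
  paf3 <- alignment_records(query = rep("S", 3), qlen = 1000,
                            qstart = c(150, 300, 600), qend = c(400, 500, 700),
                            target = "L", tlen = 5000,
                            tstart = c(0, 0, 0), tend = c(250, 200, 100))
  e3 <- pair_by_alignment(paf3, min_coverage_fraction = 0.1)
  expect_equal(e3$weight, 450 / 1000)
  expect_equal(nrow(pair_by_alignment(paf3[0, ])), 0L)
})

test_that("purging keeps the longest contig per component", {
  nodes <- data.frame(contig = c("A", "B"), length = c(100000, 60000),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = "A", to = "B", evidence = "marker", weight = 1,
                      stringsAsFactors = FALSE)
  res <- purge_redundant(allelic_evidence_graph(nodes, edges))
  expect_equal(res$kept, "A")
  expect_equal(res$purged, "B")
  expect_equal(res$log$kept, "A")
  # no edges: everything kept
  res0 <- purge_redundant(allelic_evidence_graph(nodes))
  expect_setequal(res0$kept, c("A", "B"))
  # chain A-B, B-C collapses to one kept contig
  nodes3 <- data.frame(contig = c("A", "B", "C"),
                       length = c(50, 80, 60), stringsAsFactors = FALSE)
  edges3 <- data.frame(from = c("A", "B"), to = c("B", "C"),
                       evidence = "marker", weight = 1,
                       stringsAsFactors = FALSE)
  res3 <- purge_redundant(allelic_evidence_graph(nodes3, edges3))
  expect_equal(res3$kept, "B")
  expect_setequal(res3$purged, c("A", "C"))
})

test_that("purging matches a brute-force component oracle on random graphs", {
  set.seed(62)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    ids <- sprintf("c%02d", seq_len(n))
    nodes <- data.frame(contig = ids,
                        length = sample(1000:100000, n, replace = TRUE),
                        stringsAsFactors = FALSE)
    m <- sample(0:(2 * n), 1)
    edges <- data.frame(from = sample(ids, m, TRUE),
                        to = sample(ids, m, TRUE),
                        evidence = "marker", weight = 1,
                        stringsAsFactors = FALSE)
    edges <- edges[edges$from != edges$to, , drop = FALSE]
    res <- purge_redundant(allelic_evidence_graph(nodes, edges))
    comp <- oracle_components(ids, edges)
    expected_kept <- vapply(split(nodes, comp[nodes$contig]), function(b) {
      b$contig[order(-b$length, b$contig)][1]
    }, character(1))
    expect_setequal(res$kept, unname(expected_kept))
    expect_setequal(c(res$kept, res$purged), ids)
    expect_length(intersect(res$kept, res$purged), 0)
    # idempotence: purging the kept set again changes nothing
    nodes2 <- nodes[nodes$contig %in% res$kept, , drop = FALSE]
    edges2 <- edges[edges$from %in% res$kept & edges$to %in% res$kept, ,
                    drop = FALSE]
    res2 <- purge_redundant(allelic_evidence_graph(nodes2, edges2))
    expect_setequal(res2$kept, res$kept)
  }
})

test_that("evidence intersection mode drops single-evidence pairs", {
  nodes <- data.frame(contig = c("A", "B", "C"), length = c(3, 2, 1),
                      stringsAsFactors = FALSE)
  e1 <- data.frame(from = c("A", "A"), to = c("B", "C"),
                   evidence = c("marker", "marker"), weight = 1,
                   stringsAsFactors = FALSE)
  e2 <- data.frame(from = "A", to = "B", evidence = "synteny", weight = 6,
                   stringsAsFactors = FALSE)
  g <- allelic_evidence_graph(nodes, e1, e2, require_n_evidences = 2)
  expect_setequal(unique(paste(g$edges$from, g$edges$to)), "A B")
  expect_error(allelic_evidence_graph(
    nodes, data.frame(from = "A", to = "A", evidence = "marker", weight = 1)),
    "self-edges")
})

test_that("duplication metrics apply strict success thresholds", {
  # 10 markers, each on one kept contig: clean purge
  pl <- data.frame(gene_id = paste0("m", 1:10),
                   contig = rep(c("K1", "K2"), 5),
                   start = 0L, end = 10L, strand = "+", category = "marker",
                   stringsAsFactors = FALSE)
  dup_copy <- transform(pl[1:10, ], contig = "P1")
  metrics <- duplication_metrics(c("K1", "K2", "P1"), c("K1", "K2"),
                                 rbind(pl, dup_copy))
  expect_equal(metrics$duplicated_pct, 0)
  expect_equal(metrics$loss_pct, 0)
  expect_true(metrics$success)
  # duplicated rate of exactly 10% fails ("lower than 10%")
  pl2 <- rbind(pl, transform(pl[1, ], contig = "K2"))
  m2 <- duplication_metrics(c("K1", "K2"), c("K1", "K2"), pl2)
  expect_equal(m2$duplicated_pct, 10)
  expect_false(m2$success)
  m3 <- duplication_metrics(c("K1", "K2"), "K1", pl)  # K2 markers lost
  expect_equal(m3$loss_pct, 50)
  expect_false(m3$success)
})

test_that("known 30% duplication yields hand-computed metrics", {
  # 20 markers on hap1 contigs; 6 also on hap2 contigs (30% duplicated input)
  h1 <- data.frame(gene_id = paste0("m", 1:20),
                   contig = paste0("h1_", rep(1:4, each = 5)),
                   start = 0L, end = 1L, strand = "+", category = "marker",
                   stringsAsFactors = FALSE)
  h2 <- transform(h1[1:6, ], contig = paste0("h2_", rep(1:2, each = 3)))
  pl <- rbind(h1, h2)
  all_contigs <- unique(pl$contig)
  before <- duplication_metrics(all_contigs, all_contigs, pl)
  expect_equal(before$duplicated_pct, 30)
  after <- duplication_metrics(all_contigs, unique(h1$contig), pl)
  expect_equal(after$duplicated_pct, 0)
  expect_equal(after$loss_pct, 0)
  expect_true(after$success)
})
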