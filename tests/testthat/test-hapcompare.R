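test_that("position coverage reflects source multiset counts", {
  set.seed(81)
  s <- random_dna(400)
  cov <- kmer_position_coverage(c(t = s), c(s = s), k = 27)[[1]]
  expect_length(cov, 400)
  expect_true(all(cov == 1))  # unique self k-mers everywhere
  # source absent: zero coverage
  cov0 <- kmer_position_coverage(c(t = s), character(0), k = 27)[[1]]
  expect_true(all(cov0 == 0))
  # a duplicated 200 bp segment doubles coverage across its k-mer starts
  seg <- random_dna(200)
  target <- paste0(random_dna(150), seg, random_dna(150))
  source <- paste0(random_dna(100), seg, random_dna(80), seg, random_dna(60))
  cov2 <- kmer_position_coverage(c(t = target), c(s = source), k = 27)[[1]]
  expect_true(all(cov2[151:(150 + 200 - 26)] >= 2))
  # brute-force check on a handful of positions
  src_counts <- oracle_count_canonical(source, 27)
  for (p in c(1, 151, 200, 320)) {
    w <- substr(target, p, p + 26)
    rc <- oracle_revcomp(w)
    canon <- min(w, rc)
    expected <- if (canon %in% names(src_counts)) src_counts[[canon]] else 0L
    expect_equal(cov2[p], expected, info = paste("pos", p))
  }
  # N positions get zero
  covn <- kmer_position_coverage(c(t = paste0("NNNN", s)), c(s = s), 27)[[1]]
  expect_true(all(covn[1:4] == 0))
})

test_that("masking produces complementary BEDs and is idempotent", {
  set.seed(82)
  seg <- random_dna(200)
  chrom <- paste0(random_dna(300), seg, random_dna(250), seg, random_dna(300))
  seqs <- c(chr = chrom)
  cov <- kmer_position_coverage(seqs, seqs, k = 27)
  m <- mask_repetitive(seqs, cov, min_cov = 2)
  # both planted copies masked within k-1 bases of their true spans
  expect_equal(nrow(m$repeat_bed), 2L)
  got1 <- m$repeat_bed[1, ]
  expect_lte(abs(got1$start - 300), 26)
  expect_lte(abs(got1$end - 500), 26)
  expect_gte(got1$end - got1$start, 200 - 26)
  # masked positions really are N
  v <- strsplit(m$masked[[1]], "")[[1]]
  expect_true(all(v[(got1$start + 1):got1$end] == "N"))
  # BEDs partition the non-N space
  expect_equal(sum(m$repeat_bed$end - m$repeat_bed$start) +
                 sum(m$nonrepetitive_bed$end - m$nonrepetitive_bed$start),
               nchar(chrom))
  # idempotence
  m2 <- mask_repetitive(m$masked, cov, min_cov = 2)
  expect_identical(m2$masked, m$masked)
  # no repeat: untouched
  u <- c(u = random_dna(300))
  covu <- kmer_position_coverage(u, c(x = random_dna(50)), 27)
  mu <- mask_repetitive(u, covu)
  expect_identical(mu$masked[["u"]], u[["u"]])
  expect_equal(nrow(mu$repeat_bed), 0L)
  # nonrepetitive sequence ids carry their coordinates
  expect_match(names(m$nonrepetitive_seqs)[1], "^chr:[0-9]+-[0-9]+$")
})

test_that("alignment filters implement the three preset threshold sets", {
  rec <- alignment_records(
    query = paste0("q", 1:6), qlen = 10000,
    qstart = 0, qend = c(2000, 1999, 2000, 100, 99, 5000),
    target = "t", tlen = 10000, tstart = 0, tend = 100,
    mapq = c(60, 60, 59, 50, 50, 0), primary = TRUE)
  expect_equal(filter_alignments(rec, preset = "synteny")$query, "q1")
  expect_setequal(filter_alignments(rec, preset = "unitig")$query,
                  c("q1", "q2", "q3", "q4"))
  # dotplot: MQ strictly greater than zero
  expect_false("q6" %in% filter_alignments(rec, preset = "dotplot")$query)
  expect_setequal(filter_alignments(rec, preset = "dotplot")$query,
                  c("q1", "q3"))  # q2 is 1999 bp, below the 2 kb cutoff
  # secondary alignments dropped by default
  rec2 <- rec; rec2$primary[1] <- FALSE
  expect_false("q1" %in% filter_alignments(rec2, preset = "synteny")$query)
  # random records match the brute-force filter
  set.seed(83)
  rnd <- alignment_records(query = paste0("r", 1:200), qlen = 10000,
                           qstart = sample(0:5000, 200, TRUE),
                           qend = sample(5001:10000, 200, TRUE),
                           target = "t", tlen = 1000, tstart = 0, tend = 10,
                           mapq = sample(0:60, 200, TRUE),
                           primary = sample(c(TRUE, FALSE), 200, TRUE))
  got <- filter_alignments(rnd, min_len = 3000, min_mapq = 30)
  brute <- rnd[(rnd$qend - rnd$qstart) >= 3000 & rnd$mapq >= 30 &
                 rnd$primary, ]
  expect_equal(got$query, brute$query)
})

test_that("hand-worked CIGAR decompositions are exact", {
  b1 <- parse_cigar_variation("10=1X9=")
  expect_equal(b1$match_len, 19)
  expect_equal(b1$snv_count, 1)
  expect_equal(b1$total_len, 20)
  expect_equal(b1$identity, 0.95)
  b2 <- parse_cigar_variation("20=60I20=")
  expect_equal(b2$match_len, 40)
  expect_equal(b2$pav_count, 1)
  expect_equal(b2$pav_len, 60)
  expect_equal(b2$total_len, 100)
  expect_equal(b2$identity, 0.40)
  b3 <- parse_cigar_variation("5S20=")
  expect_equal(b3$match_len, 20)
  expect_equal(b3$sc_len, 5)
  expect_equal(b3$total_len, 25)
  expect_equal(b3$identity, 0.80)
  expect_equal(b3$pav_count, 0)
  b4 <- parse_cigar_variation("55S20=")
  expect_equal(b4$pav_count, 1)   # long soft-clip also counts as PAV
  expect_equal(b4$sc_len, 55)
  expect_equal(b4$total_len, 75)  # clip bases counted once
  expect_error(parse_cigar_variation("10M5I"), "--eqx")
})

test_that("CIGAR parsing conserves bases and matches the expansion oracle", {
  set.seed(84)
  cigars <- vapply(1:300, function(i) random_cigar(sample(3:12, 1)),
                   character(1))
  got <- parse_cigar_variation(cigars)
  # conservation on every record
  expect_equal(got$match_len + got$snv_len + got$indel_len +
                 got$pav_internal_len + got$sc_len, got$total_len)
  expect_equal(got$identity, got$match_len / got$total_len)
  for (i in seq_along(cigars)) {
    o <- oracle_cigar_breakdown(cigars[i])
    for (f in names(o))
      expect_equal(got[[f]][i], o[[f]],
                   info = paste(cigars[i], f))
  }
})

test_that("identity summaries aggregate per group", {
  b <- parse_cigar_variation(
    alignment_records(query = c("a", "b", "c"), qlen = 100, qstart = 0,
                      qend = 100, target = c("t1", "t1", "t2"), tlen = 1000,
                      tstart = 0, tend = 100,
                      cigar = c("90=10X", "80=20X", "100=")))
  s <- identity_summary(b)
  expect_equal(s$median_identity[s$group == "t1"], 0.85)
  expect_equal(s$median_identity[s$group == "t2"], 1.0)
  expect_equal(s$n, c(2L, 1L))
  one <- identity_summary(b[2, , drop = FALSE])
  expect_equal(one$median_identity, 0.8)
  expect_equal(identity_summary(
    data.frame(identity = c(0.9, 0.8, 1.0), total_len = 10, match_len = 9,
               snv_len = 1, indel_len = 0, pav_internal_len = 0, sc_len = 0),
    group_by = NULL)$median_identity, 0.9)
})

test_that("windowed category coverage conserves window length", {
  rep_bed <- data.frame(chrom = "c", start = c(0L, 1500000L),
                        end = c(500000L, 2000000L))
  nonrep_bed <- data.frame(chrom = "c", start = c(500000L, 2200000L),
                           end = c(1400000L, 3000000L))
  w <- windowed_category_coverage(rep_bed, nonrep_bed, c(c = 3000000L))
  expect_equal(nrow(w), 3L)
  expect_equal(w$repetitive, c(500000L, 500000L, 0L))
  expect_equal(w$nonrepetitive, c(500000L, 400000L, 800000L))
  expect_true(all(w$repetitive + w$nonrepetitive + w$n_bases ==
                    w$end - w$start))
  # fully nonrepetitive chromosome: zero repetitive bases everywhere
  w0 <- windowed_category_coverage(rep_bed[0, ],
                                   data.frame(chrom = "c", start = 0L,
                                              end = 3000000L),
                                   c(c = 3000000L))
  expect_true(all(w0$repetitive == 0))
  expect_true(all(w0$n_bases == 0))
  # overlapping BEDs are rejected
  expect_error(windowed_category_coverage(
    data.frame(chrom = "c", start = 0L, end = 10L),
    data.frame(chrom = "c", start = 5L, end = 15L), c(c = 100L)),
    "overlap")
})

test_that("repeat fraction of masked genome rises with planted repeats", {
  masked_fraction <- function(rf, seed) {
    sim <- simulate_diploid(diploid_sim_config(
      n_chromosomes = 1, chrom_length = 40000, snv_rate = 0.01,
      repeat_fraction = rf, seed = seed))
    cov <- kmer_position_coverage(sim$hap1, sim$hap1, k = 27)
    m <- mask_repetitive(sim$hap1, cov, min_cov = 2)
    sum(m$repeat_bed$end - m$repeat_bed$start) / 40000
  }
  f0 <- masked_fraction(0, 85)
  f2 <- masked_fraction(0.2, 85)
  f4 <- masked_fraction(0.4, 85)
  expect_lt(f0, 0.01)
  expect_gt(f2, f0)
  expect_gt(f4, f2)
})
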