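test_that("config invariants are enforced", {
  expect_error(diploid_sim_config(snv_rate = -1), "rates")
  expect_error(diploid_sim_config(indel_max_len = 50), "indel_max_len")
  expect_error(diploid_sim_config(pav_len_range = c(10, 100)), "pav_len_range")
  expect_equal(heterozygosity_preset("lp")$snv_rate, 0.0221)
  expect_equal(heterozygosity_preset("lm")$snv_rate, 0.0349)
})

test_that("all-zero rates give identical haplotypes and no variants", {
  sim <- simulate_diploid(diploid_sim_config(
    n_chromosomes = 2, chrom_length = 5000, snv_rate = 0, seed = 1))
  expect_identical(sim$hap1, sim$hap2)
  expect_equal(nrow(sim$truth$variants), 0L)
})

test_that("SNV density converges to the configured rate", {
  sim <- simulate_diploid(diploid_sim_config(
    n_chromosomes = 1, chrom_length = 100000, snv_rate = 0.05, seed = 5))
  n <- nrow(sim$truth$variants)
  expected <- 100000 * 0.05
  sd3 <- 3 * sqrt(100000 * 0.05 * 0.95)
  expect_gt(n, expected - sd3)
  expect_lt(n, expected + sd3)
})

test_that("identical seed and config reproduce byte-identical output", {
  cfg <- diploid_sim_config(n_chromosomes = 2, chrom_length = 20000,
                            snv_rate = 0.02, indel_rate = 0.002,
                            pav_rate = 5e-5, repeat_fraction = 0.1, seed = 99)
  a <- simulate_diploid(cfg)
  b <- simulate_diploid(cfg)
  expect_identical(a$hap1, b$hap1)
  expect_identical(a$hap2, b$hap2)
  expect_identical(a$truth$variants, b$truth$variants)
})

test_that("chromosomes too short for requested PAVs are rejected", {
  expect_error(simulate_diploid(diploid_sim_config(
    chrom_length = 300, pav_rate = 1e-3, pav_len_range = c(300, 400))),
    "too short")
})

test_that("exact diff of the two haplotypes recovers the planted truth", {
  sim <- small_sim(seed = 21, chrom_length = 30000, n_chromosomes = 1,
                   snv_rate = 0.005, indel_rate = 5e-4, pav_rate = 3e-5)
  d <- haplobin:::cpp_diff_sequences(sim$hap1[[1]], sim$hap2[[1]])
  tv <- sim$truth$variants
  d <- haplobin:::normalize_variant_table(sim$hap1[[1]], d)
  tvn <- haplobin:::normalize_variant_table(
    sim$hap1[[1]], tv[, c("pos", "ref", "alt")])
  expect_equal(paste(d$pos, d$ref, d$alt), paste(tvn$pos, tvn$ref, tvn$alt))
})

test_that("mosaic reference with zero switches is haplotype 1 verbatim", {
  sim <- small_sim(seed = 2)
  mos <- make_mosaic_reference(sim$hap1, sim$hap2, sim$truth, 0)
  expect_identical(mos$reference, sim$hap1)
  expect_equal(nrow(mos$truth$mosaic_blocks), 2L)  # one block per chromosome
})

test_that("one switch per chromosome gives exactly two blocks, and block
           boundaries never split an allele", {
  sim <- small_sim(seed = 3, snv_rate = 0.01, indel_rate = 1e-3,
                   pav_rate = 5e-5)
  mos <- make_mosaic_reference(sim$hap1, sim$hap2, sim$truth, 1, seed = 4)
  blocks <- mos$truth$mosaic_blocks
  expect_equal(as.integer(table(blocks$chrom)), rep(2L, 2))
  # every variant's reference allele must match the mosaic reference
  v <- mos$truth$variants
  allele <- ifelse(v$ref_hap == 1L, v$ref, v$alt)
  for (i in seq_len(nrow(v))) {
    seen <- substr(mos$reference[[v$chrom[i]]], v$ref_pos[i],
                   v$ref_pos[i] + nchar(allele[i]) - 1L)
    expect_identical(seen, allele[i])
  }
})

test_that("phased VCF orientation and switch-error injection behave", {
  sim <- small_sim(seed = 6, chrom_length = 60000, snv_rate = 0.02)
  # no mosaic: reference is hap1, truth orientation is 0|1 everywhere
  clean <- emit_phased_vcf(sim$truth, switch_error_rate = 0)
  expect_true(all(clean$variants$gt1 == 0L))
  expect_true(all(clean$variants$gt2 == 1L))
  flipped <- emit_phased_vcf(sim$truth, switch_error_rate = 1, seed = 1)
  expect_true(all(flipped$variants$gt1 == 1L))
  expect_equal(nrow(flipped$truth$switch_points), nrow(sim$truth$variants))
  part <- emit_phased_vcf(sim$truth, switch_error_rate = 0.02, seed = 2)
  n <- nrow(part$variants)
  expect_gte(n, 1000)
  frac <- nrow(part$truth$switch_points) / n
  sd3 <- 3 * sqrt(0.02 * 0.98 / n)
  expect_lt(abs(frac - 0.02), sd3)
})

test_that("emitted VCF file round-trips through the VCF reader", {
  sim <- small_sim(seed = 8, chrom_length = 20000, snv_rate = 0.01,
                   indel_rate = 1e-3)
  path <- withr::local_tempfile(fileext = ".vcf")
  out <- emit_phased_vcf(sim$truth, path = path,
                         contig_lengths = nchar(sim$hap1))
  back <- read_phased_vcf(path)
  expect_equal(nrow(back), nrow(out$variants))
  expect_equal(back$pos, out$variants$pos)
  expect_equal(back$ref, out$variants$ref)
  expect_equal(back$gt1, out$variants$gt1)
  expect_true(all(back$phased))
  expect_equal(unique(back$mapq), 60)
  expect_equal(unique(back$depth), 30)
})

test_that("error-free reads are exact substrings of their source haplotype", {
  sim <- small_sim(seed = 9, chrom_length = 20000)
  rd <- simulate_reads(sim$hap1, sim$hap2, n_reads = 60,
                       read_length_mean = 3000, read_length_min = 500,
                       error_rate = 0, seed = 10)
  haps <- list(sim$hap1, sim$hap2)
  for (i in seq_len(nrow(rd$labels))) {
    lab <- rd$labels[i, ]
    chrom_seq <- haps[[lab$haplotype]][[lab$chrom]]
    r <- rd$reads[[lab$read_id]]
    if (lab$strand == "-") r <- oracle_revcomp(r)
    expect_identical(substr(chrom_seq, lab$start + 1, lab$start + nchar(r)), r)
  }
})

test_that("depth parameter controls total bases and labels cover all reads", {
  sim <- small_sim(seed = 12, chrom_length = 30000)
  rd <- simulate_reads(sim$hap1, sim$hap2, depth = 4,
                       read_length_mean = 2000, read_length_min = 500,
                       seed = 13)
  G <- sum(nchar(sim$hap1))
  total <- sum(nchar(rd$reads))
  expect_lt(abs(total - 4 * G) / (4 * G), 0.05)
  expect_setequal(rd$labels$read_id, names(rd$reads))
  expect_false(anyDuplicated(rd$labels$read_id) > 0)
})

test_that("strand use is balanced and seeds decorrelate read sets", {
  sim <- small_sim(seed = 14, chrom_length = 30000)
  rd <- simulate_reads(sim$hap1, sim$hap2, n_reads = 400,
                       read_length_mean = 2000, read_length_min = 500,
                       seed = 15)
  frac_minus <- mean(rd$labels$strand == "-")
  expect_lt(abs(frac_minus - 0.5), 3 * sqrt(0.25 / 400))
  rd2 <- simulate_reads(sim$hap1, sim$hap2, n_reads = 400,
                        read_length_mean = 2000, read_length_min = 500,
                        seed = 16)
  expect_false(identical(rd$reads, rd2$reads))
  expect_error(simulate_reads(sim$hap1, sim$hap2, n_reads = 5,
                              read_length_min = 1e6), "read length")
})
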