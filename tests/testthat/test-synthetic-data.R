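# Synthetic-data generators: determinism, CpG ground truth, planted
# duplications, intensity/WGBS sampling models, file round-trips.

test_that("generators are byte-identical under a fixed seed", {
  cfg <- tiny_config(seed = 7)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$seq, g2$seq)
  f1 <- tempfile(fileext = ".fa")
  f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g1, f1)
  write_genome_fasta(g2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(simulate_wgbs_counts(g1, cfg), simulate_wgbs_counts(g2, cfg))
  m1 <- simulate_manifest(g1, cfg)
  m2 <- simulate_manifest(g2, cfg)
  expect_identical(m1$manifest$probes, m2$manifest$probes)
})

test_that("every emitted CpG position carries CG in the sequence", {
  g <- world1()$genome
  for (chrom in names(g$seq)) {
    pos <- g$cpg$pos[g$cpg$chrom == chrom]
    dinucs <- substring(g$seq[[chrom]], pos + 1L, pos + 2L)
    expect_true(all(dinucs == "CG"))
  }
  # and CpG density inside islands is near the configured rate
  isl <- g$islands
  n_in <- sum(r_coverage_oracle(isl, g$cpg))
  rate <- n_in / sum(isl$end - isl$start)
  expect_gt(rate, 0.5 * g$config$island_cpg_rate)
})

test_that("planted duplications copy footprints at the configured identity", {
  g <- world1()$genome
  dup <- g$duplications
  expect_equal(nrow(dup), g$config$n_duplicated_segments)
  for (i in seq_len(nrow(dup))) {
    src <- substr(g$seq[[dup$chrom[i]]], dup$src_start[i] + 1L, dup$src_end[i])
    dst <- substr(g$seq[[dup$chrom[i]]], dup$dst_start[i] + 1L, dup$dst_end[i])
    mism <- sum(strsplit(src, "")[[1]] != strsplit(dst, "")[[1]])
    expect_equal(mism, dup$n_mismatches[i])
  }
})

test_that("a no-duplication genome has no off-target homology >= 47", {
  cfg <- tiny_config(seed = 3, n_duplicated_segments = 0L)
  g <- simulate_genome(cfg)
  man <- simulate_manifest(g, cfg)
  genomes <- build_converted_genomes(g)
  hits <- scan_manifest(man$manifest, genomes, min_count = 47L, method = "brute")
  expect_true(all(hits$is_target))
  expect_length(man$ground_truth$planted_crossreactive_probe_ids, 0L)
})

test_that("intensity model tracks the true beta", {
  cfg <- sim_config(seed = 5, sigma_m = 0)
  w <- world1()
  man <- w$manifest
  n <- nrow(man$probes)
  tb <- matrix(0.5, n, 2)
  si <- simulate_intensities(cfg, man, true_beta = tb)
  bm <- compute_beta(si)
  expect_gt(mean(bm$beta), 0.45)
  expect_lt(mean(bm$beta), 0.55)
  # beta bound: true_beta = 1 without noise stays strictly below 1
  si1 <- simulate_intensities(cfg, man, true_beta = matrix(1, n, 2))
  bm1 <- compute_beta(si1)
  expect_true(all(bm1$beta < 1))
  # null probes: group difference centred at zero
  g1 <- rowMeans(bm$beta[, si$samples$group == "group1"])
  g2 <- rowMeans(bm$beta[, si$samples$group == "group2"])
  expect_lt(abs(mean(g2 - g1)), 0.01)
})

test_that("WGBS counts follow the Poisson/binomial sampling model", {
  cfg <- sim_config(seed = 2, wgbs_mean_coverage = 20L)
  g <- world1()$genome
  zero <- simulate_wgbs_counts(g, cfg, true_m = 0)
  expect_true(all(zero$methylated_count == 0L))
  cnt <- simulate_wgbs_counts(g, cfg, true_m = 0.5, label = "tailcheck")
  frac_ge10 <- mean(cnt$total_count >= 10L)
  expect_lt(abs(frac_ge10 - stats::ppois(9, 20, lower.tail = FALSE)), 0.02)
  expect_true(all(cnt$methylated_count <= cnt$total_count))
})

test_that("generated files are valid and round-trip through the readers", {
  w <- world1()
  dir <- tempfile()
  dir.create(dir)
  man_path <- file.path(dir, "manifest.csv")
  write_manifest(w$manifest, man_path)
  man2 <- read_manifest(man_path, "synthetic")
  expect_equal(man2$probes, w$manifest$probes)
  # FASTA
  fa <- file.path(dir, "g.fa")
  write_genome_fasta(w$genome, fa)
  ss <- Biostrings::readDNAStringSet(fa)
  expect_identical(setNames(as.character(ss), names(ss)), w$genome$seq)
  # WGBS table
  tsv <- file.path(dir, "w.tsv")
  write_cpg_counts(w$wgbs[[1]], tsv)
  expect_equal(read_cpg_counts(tsv), w$wgbs[[1]])
  # VCF parses and the MAF fold matches the emitted frequencies
  vcf <- file.path(dir, "v.vcf")
  writeLines(w$variants$vcf_lines, vcf)
  vars <- read_variants(vcf, maf_threshold = 0)
  expect_equal(nrow(vars), nrow(w$variants$variants))
})

test_that("infeasible layouts raise configuration errors", {
  expect_error(sim_config(genome_length_bp = 5000), class = "epicqc_config_error")
  expect_error(sim_config(duplication_identity = 0.93),
               class = "epicqc_config_error")
  expect_error(sim_config(island_cpg_rate = 1.2), class = "epicqc_config_error")
  expect_error(sim_config(n_samples_per_group = 1), class = "epicqc_config_error")
  # probe demand beyond the CpG supply
  cfg <- tiny_config(seed = 1)
  cfg$n_probes_type2 <- 100000L
  g <- simulate_genome(cfg)
  expect_error(simulate_manifest(g, cfg), class = "epicqc_config_error")
})
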