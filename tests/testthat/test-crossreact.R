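# In-silico conversion, homology scanning and cross-reactivity calls.

test_that("conversion rules are applied per genome variant", {
  expect_equal(convert_sequence("ACGT", "plus_unmethylated"), "ATGT")
  expect_equal(convert_sequence("ACGT", "plus_cpg_methylated"), "ACGT")
  expect_equal(convert_sequence("ACGT", "minus_unmethylated"), "ACAT")
  expect_equal(convert_sequence("ACGT", "minus_cpg_methylated"), "ACGT")
  expect_equal(convert_sequence("CCGC", "plus_cpg_methylated"), "TCGT")
  # genome without C: plus variants are fixed points
  expect_equal(convert_sequence("AGTTGA", "plus_unmethylated"), "AGTTGA")
  # N passes through; other characters are rejected
  expect_equal(convert_sequence("ANCGT", "plus_unmethylated"), "ANTGT")
  expect_error(convert_sequence("ACXGT", "plus_unmethylated"),
               class = "epicqc_format_error")
})

test_that("every probe finds its own footprint with 50 matches", {
  w <- world1()
  genomes <- build_converted_genomes(w$genome)
  hits <- scan_manifest(w$manifest, genomes, min_count = 50L)
  tgt <- hits[hits$is_target & hits$match_count == 50L, ]
  cg <- w$manifest$probes[w$manifest$probes$probe_class == "cg", ]
  expect_setequal(unique(tgt$probe_id), cg$probe_id)
  # and the self-hit locus is exactly the stored footprint
  i <- match(tgt$probe_id, cg$probe_id)
  expect_true(all(tgt$start == cg$fp_start[i]))
})

test_that("seeded scanner agrees with the independent R oracle", {
  set.seed(42)
  for (rep in 1:3) {
    gseq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
    genomes <- build_converted_genomes(c(chrT = gseq))
    # queries: one real substring (with an R planted), one random
    q1 <- substr(genomes$genomes$plus_unmethylated[["chrT"]], 101, 150)
    substr(q1, 25, 25) <- "R"
    q2 <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
    # brute method at a low floor (the seeded scanner only guarantees
    # completeness at >= 47; its equivalence there is tested separately)
    hits <- scan_sequences(c(a = q1, b = q2), genomes, min_count = 30L,
                           method = "brute")
    for (gid in names(genomes$genomes)) {
      for (qn in c("a", "b")) {
        for (ori in c("fwd", "rev")) {
          q <- if (ori == "fwd") c(a = q1, b = q2)[[qn]] else revcomp(c(a = q1, b = q2)[[qn]])
          oracle <- r_scan_oracle(q, genomes$genomes[[gid]][["chrT"]], 30L)
          got <- hits[hits$query == qn & hits$genome_id == gid &
                        hits$orientation == ori, ]
          got <- got[order(got$start), ]
          expect_equal(got$start, oracle$start)
          expect_equal(got$match_count, oracle$count)
        }
      }
    }
  }
})

test_that("exact duplications yield two perfect hits, one on target", {
  cfg <- tiny_config(seed = 9, duplication_identity = 1.0)
  g <- simulate_genome(cfg)
  man <- simulate_manifest(g, cfg)
  genomes <- build_converted_genomes(g)
  planted <- man$ground_truth$planted_crossreactive_probe_ids
  for (pid in planted) {
    probe <- man$manifest$probes[man$manifest$probes$probe_id == pid, ]
    hits <- scan_probe(probe, genomes, min_count = 50L)
    hits <- hits[hits$allele == "u" | probe$infinium_type == "II", ]
    expect_gte(nrow(hits), 2L)
    expect_true(any(hits$is_target))
    expect_true(any(!hits$is_target & hits$match_count == 50L))
  }
})

test_that("planted 47/50 duplications are called at 47 but not above", {
  w <- world1()
  genomes <- build_converted_genomes(w$genome)
  calls <- call_crossreactive(w$manifest, genomes, threshold = 47L)
  planted <- w$ground_truth$planted_crossreactive_probe_ids
  expect_setequal(calls$probe_id[calls$flagged], planted)
  expect_true(all(calls$best_match_count[calls$flagged] == 47L))
  expect_equal(sum(call_crossreactive(w$manifest, genomes, threshold = 48L)$flagged), 0L)
  expect_equal(sum(call_crossreactive(w$manifest, genomes, threshold = 51L)$flagged), 0L)
  # Type II planted probes match both minus genomes equally: a tie
  t2 <- w$manifest$probes$probe_id[w$manifest$probes$infinium_type == "II"]
  expect_true(all(calls$tie[calls$flagged & calls$probe_id %in% t2]))
})

test_that("flag set is invariant to probe and chromosome order", {
  w <- world1()
  genomes <- build_converted_genomes(w$genome)
  calls <- call_crossreactive(w$manifest, genomes)
  man_shuf <- w$manifest
  set.seed(1)
  man_shuf$probes <- man_shuf$probes[sample.int(nrow(man_shuf$probes)), ]
  genomes_rev <- genomes
  genomes_rev$genomes <- lapply(genomes$genomes, rev)
  calls_shuf <- call_crossreactive(man_shuf, genomes_rev)
  expect_equal(calls_shuf, calls)
})

test_that("validation against a reference counts TP/FP/FN correctly", {
  calls <- data.frame(probe_id = paste0("cg", 1:10), chrom = "chr1",
                      start = (1:10) * 100L, stringsAsFactors = FALSE)
  expect_error(validate_against_reference(calls, calls[0, ]),
               class = "epicqc_integrity_error")
  v <- validate_against_reference(calls, calls)
  expect_equal(c(v$precision, v$recall), c(1, 1))
  # one extra reference pair: recall (n-1)/n... here n = 11
  ref <- rbind(calls, data.frame(probe_id = "cg99", chrom = "chr1", start = 5L))
  v2 <- validate_against_reference(calls, ref)
  expect_equal(v2$recall, 10 / 11)
  expect_equal(v2$precision, 1)
  # perturbed reference: drop 2, add 3 bogus pairs
  ref3 <- rbind(calls[-(1:2), ],
                data.frame(probe_id = paste0("x", 1:3), chrom = "chr2",
                           start = 1:3))
  v3 <- validate_against_reference(calls, ref3)
  expect_equal(v3$tp, 8)
  expect_equal(v3$fp, 2)   # calls 1:2 match nothing
  expect_equal(v3$fn, 3)   # the bogus pairs are never called
  expect_equal(v3$precision, 8 / 10)
  expect_equal(v3$recall, 8 / 11)
  # positional tolerance
  shifted <- calls
  shifted$start <- shifted$start + 3L
  expect_equal(validate_against_reference(shifted, calls, tolerance = 5L)$recall, 1)
  expect_equal(validate_against_reference(shifted, calls, tolerance = 0L)$recall, 0)
})
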