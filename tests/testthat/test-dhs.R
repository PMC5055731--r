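# Region-level methylation, chromatin association and platform concordance.

fixture_counts <- function(pos, meth, total, chrom = "chr1") {
  data.frame(chrom = chrom, start = pos, end = pos + 2L,
             methylated_count = meth, total_count = total,
             stringsAsFactors = FALSE)
}

test_that("region selection honours the CpG minimum", {
  regions <- data.frame(chrom = "chr1", start = c(0L, 100L),
                        end = c(50L, 200L), region_id = c("r1", "r2"))
  cpgs <- data.frame(chrom = "chr1", pos = c(5L, 10L, 110L, 120L, 130L))
  expect_equal(select_regions(regions, cpgs, 3L)$region_id, "r2")
  expect_equal(select_regions(regions, cpgs, 0L)$region_id, c("r1", "r2"))
})

test_that("WGBS region methylation is the pooled ratio", {
  regions <- data.frame(chrom = "chr1", start = 0L, end = 100L,
                        region_id = "r1")
  rm <- region_methylation_wgbs(fixture_counts(c(10L, 20L), c(3L, 1L), c(4L, 4L)),
                                regions, min_region_cov = 5L)
  expect_equal(rm$mean_beta, 0.5)   # (3+1)/(4+4), not mean(3/4, 1/4)
  expect_true(rm$informative)
  all_meth <- region_methylation_wgbs(fixture_counts(c(10L, 20L), c(30L, 30L), c(30L, 30L)),
                                      regions, min_region_cov = 50L)
  expect_equal(all_meth$mean_beta, 1)
  expect_equal(all_meth$status, "high")
  # zero observations: non-informative, no division by zero
  empty <- region_methylation_wgbs(fixture_counts(10L, 0L, 0L), regions)
  expect_false(empty$informative)
  expect_true(is.na(empty$mean_beta))
})

test_that("pooled ratio equals the coverage-weighted mean of per-CpG ratios", {
  set.seed(6)
  for (rep in 1:5) {
    n <- 20L
    total <- sample(1:60, n, replace = TRUE)
    meth <- rbinom(n, total, runif(1))
    regions <- data.frame(chrom = "chr1", start = 0L, end = 10000L,
                          region_id = "r")
    rm <- region_methylation_wgbs(fixture_counts(seq(10L, by = 100L, length.out = n),
                                                 meth, total), regions)
    weighted <- sum((meth / total) * total) / sum(total)
    expect_equal(rm$mean_beta, weighted)
  }
})

test_that("raising the coverage rule never grows the informative set", {
  w <- world1()
  regions <- select_regions(w$annotation$dhs_distal,
                            data.frame(chrom = w$genome$cpg$chrom,
                                       pos = w$genome$cpg$pos))
  counts <- w$wgbs[[1]]
  prev <- rep(TRUE, nrow(regions))
  for (cov in c(10L, 50L, 100L, 200L)) {
    inf <- region_methylation_wgbs(counts, regions, min_region_cov = cov)$informative
    expect_true(all(inf <= prev))
    prev <- inf
  }
})

test_that("array region methylation averages passing probes", {
  man <- make_manifest(data.frame(
    probe_id = c("cg1", "cg2"), infinium_type = "II", chrom = "chr1",
    target_pos = c(100L, 140L), strand = "+"))
  regions <- data.frame(chrom = "chr1", start = 90L, end = 200L,
                        region_id = "r1")
  b <- matrix(c(0.25, NA), 2, 1, dimnames = list(c("cg1", "cg2"), "s1"))
  rm1 <- region_methylation_array(make_beta_matrix(b), man, regions, "s1")
  expect_equal(rm1$mean_beta, 0.25)
  expect_equal(rm1$status, "low")
  b2 <- matrix(c(0.2, 0.8), 2, 1, dimnames = list(c("cg1", "cg2"), "s1"))
  rm2 <- region_methylation_array(make_beta_matrix(b2), man, regions, "s1")
  expect_equal(rm2$mean_beta, 0.5)
  expect_equal(rm2$status, "mid")
})

test_that("methylation/DHS association recovers the expected direction", {
  # hand-built 2x2 (90, 10, 20, 80): log OR = ln(36)
  ids <- paste0("r", 1:200)
  beta <- c(rep(0.1, 90), rep(0.9, 10), rep(0.1, 20), rep(0.9, 80))
  pres <- setNames(c(rep(TRUE, 100), rep(FALSE, 100)), ids)
  mv <- methylation_vs_dhs(make_region_meth(ids, beta), pres)
  expect_equal(mv$log_or, log(36), tolerance = 1e-12)
  expect_equal(unname(mv$table[1, ]), c(90, 10))
  # independence: CI straddles zero
  set.seed(7)
  beta_i <- sample(c(0.1, 0.9), 400, replace = TRUE)
  pres_i <- setNames(sample(c(TRUE, FALSE), 400, replace = TRUE),
                     paste0("q", 1:400))
  mv_i <- methylation_vs_dhs(make_region_meth(paste0("q", 1:400), beta_i), pres_i)
  expect_true(mv_i$ci_lo < 0 && mv_i$ci_hi > 0)
})

test_that("cross-platform concordance and disagreement flags", {
  ids <- paste0("r", 1:20)
  set.seed(9)
  beta <- runif(20)
  w <- make_region_meth(ids, beta)
  a <- make_region_meth(ids, beta, platform = "array")
  cc <- cross_platform_concordance(w, a)
  expect_equal(cc$spearman_rho, 1)
  expect_equal(cc$frac_lt_05, 1)
  expect_equal(nrow(cc$disagreements), 0L)
  # one region low in WGBS, high on the array
  a2 <- a
  a2$mean_beta[1] <- 0.9
  w2 <- w
  w2$mean_beta[1] <- 0.1
  cc2 <- cross_platform_concordance(w2, a2)
  expect_equal(cc2$disagreements$region_id, "r1")
  expect_true(cc2$frac_lt_05 <= cc2$frac_lt_10 &&
                cc2$frac_lt_10 <= cc2$frac_lt_20)
  expect_error(cross_platform_concordance(w[1:2, ], a[1:2, ]),
               class = "epicqc_integrity_error")
})

test_that("disagreement typing distinguishes positioning from artifacts", {
  regions <- data.frame(chrom = "chr1", start = c(0L, 1000L, 2000L),
                        end = c(500L, 1500L, 2500L),
                        region_id = c("rPos", "rArt", "rNoCov"))
  man <- make_manifest(data.frame(
    probe_id = c("cg1", "cg2", "cg3"), infinium_type = "II", chrom = "chr1",
    target_pos = c(100L, 1100L, 2100L), strand = "+"))
  counts <- fixture_counts(c(100L, 1100L, 2100L),
                           meth = c(17L, 2L, 1L), total = c(20L, 20L, 5L))
  dis <- data.frame(region_id = c("rPos", "rArt", "rNoCov"),
                    wgbs_beta = c(0.2, 0.2, 0.2),
                    array_beta = c(0.9, 0.9, 0.9), stringsAsFactors = FALSE)
  out <- classify_disagreements(dis, counts, man, regions, tau = 0.2)
  # array 0.9 vs own-CpG 0.85 vs region 0.2: faithful probe, bad position
  expect_equal(out$type[1], "PROBE_POSITIONING")
  # array 0.9 vs own-CpG 0.1: the readout itself disagrees
  expect_equal(out$type[2], "TECHNICAL_ARTIFACT")
  # under 10x coverage at the probe CpG: unclassified
  expect_true(is.na(out$type[3]))
})
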