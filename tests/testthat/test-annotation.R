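# Derived annotation tracks, probe context assignment, coverage strata.

simple_bundle <- function(genes = NULL, islands = NULL, len = 30000L) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), region_id = character(0))
  build_annotation(
    genes = genes %||% data.frame(chrom = character(0), start = integer(0),
                                  end = integer(0), strand = character(0),
                                  tss = integer(0)),
    islands = islands %||% empty[, 1:3],
    dhs_proximal = empty, dhs_distal = empty, enhancers = empty,
    chrom_lengths = c(chr1 = len))
}

test_that("derived tracks match their definitions", {
  b <- simple_bundle(genes = data.frame(chrom = "chr1", start = 10000L,
                                        end = 15000L, strand = "+",
                                        tss = 10000L))
  expect_equal(b$promoters, data.frame(chrom = "chr1", start = 8000L, end = 12000L))
  # gene body: transcript +/- 2 kb minus the promoter
  expect_equal(b$gene_bodies, data.frame(chrom = "chr1", start = 12000L, end = 17000L))
  # intergenic is the complement; the three contexts partition the genome
  widths <- function(df) sum(df$end - df$start)
  expect_equal(widths(b$promoters) + widths(b$gene_bodies) + widths(b$intergenic),
               30000)
  b2 <- simple_bundle(islands = data.frame(chrom = "chr1", start = 5000L, end = 5500L))
  expect_equal(b2$shores,
               data.frame(chrom = "chr1", start = c(3000L, 5500L),
                          end = c(5000L, 7500L)))
  # empty gene set: everything is intergenic
  expect_equal(simple_bundle()$intergenic,
               data.frame(chrom = "chr1", start = 0L, end = 30000L))
  # out-of-bounds regions are clipped with a warning
  warns <- capture_warnings(
    b3 <- simple_bundle(genes = data.frame(chrom = "chr1", start = 500L,
                                           end = 29900L, strand = "+",
                                           tss = 500L)))
  expect_true(any(grepl("clipped", warns)))
  expect_equal(b3$promoters$start, 0L)
})

test_that("probe context assignment uses the documented precedence", {
  genes <- data.frame(chrom = "chr1", start = 10000L, end = 15000L,
                      strand = "+", tss = 10000L)
  b <- simple_bundle(genes = genes,
                     islands = data.frame(chrom = "chr1", start = 10050L,
                                          end = 10300L))
  man <- make_manifest(data.frame(
    probe_id = c("cg1", "cg2", "cg3", "cg4"), infinium_type = "II",
    chrom = "chr1", strand = "+",
    # promoter+island; promoter+shore; body; intergenic open sea (>2 kb
    # from the island flanks)
    target_pos = c(10100L, 11000L, 13000L, 25000L)))
  cats <- assign_probe_categories(man, b)
  expect_equal(cats$gene_context, c("promoter", "promoter", "gene_body", "intergenic"))
  expect_equal(cats$cpg_context, c("island", "shore", "open_sea", "open_sea"))
  # unknown chromosome: unassigned with a warning
  man2 <- make_manifest(data.frame(probe_id = "cg9", infinium_type = "II",
                                   chrom = "chrZ", target_pos = 100L,
                                   strand = "+"))
  expect_warning(cats2 <- assign_probe_categories(man2, b), "absent")
  expect_true(is.na(cats2$gene_context))
})

test_that("stratified coverage equals the brute-force oracle", {
  regions <- data.frame(chrom = "chr1", start = c(0L, 100L, 300L),
                        end = c(50L, 200L, 400L),
                        region_id = c("r1", "r2", "r3"))
  pos <- data.frame(chrom = "chr1", pos = c(10L, 20L, 150L, 500L))
  cov <- coverage_stratified(regions, pos, "fix")
  expect_equal(c(cov$n_ge1, cov$n_ge2, cov$n_ge3), c(2L, 1L, 0L))
  expect_equal(unname(unlist(
    coverage_stratified(regions, pos[0, ])[, c("n_ge1", "n_ge2", "n_ge3")])),
    c(0L, 0L, 0L))
  # random fixtures against an R loop oracle
  set.seed(8)
  for (rep in 1:5) {
    r <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                    start = sample.int(5000L, 30))
    r$end <- r$start + sample.int(300L, 30)
    p <- data.frame(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                    pos = sample.int(5300L, 200, replace = TRUE))
    got <- coverage_stratified(r, p)
    oracle <- r_coverage_oracle(r, p)
    expect_equal(got$n_ge1, sum(oracle >= 1))
    expect_equal(got$n_ge2, sum(oracle >= 2))
    expect_equal(got$n_ge3, sum(oracle >= 3))
    expect_true(got$n_ge3 <= got$n_ge2 && got$n_ge2 <= got$n_ge1 &&
                  got$n_ge1 <= got$n_regions)
  }
})

test_that("specific/common DHS split follows the median rule", {
  m <- matrix(TRUE, 4, 5, dimnames = list(paste0("r", 1:4), NULL))
  s <- split_specific_common(m)
  expect_length(s$specific, 0L)       # all at the median: all common
  expect_setequal(s$common, paste0("r", 1:4))

  occ <- c(1L, 1L, 5L, 5L)
  m2 <- matrix(FALSE, 4, 5, dimnames = list(paste0("r", 1:4), NULL))
  for (i in 1:4) m2[i, seq_len(occ[i])] <- TRUE
  s2 <- split_specific_common(m2)
  expect_equal(s2$median, 3)
  expect_setequal(s2$specific, c("r1", "r2"))
  expect_setequal(s2$common, c("r3", "r4"))
  expect_error(split_specific_common(m2[0, ]), class = "epicqc_integrity_error")
})

test_that("gene context is total and category counts add up", {
  w <- world1()
  ann <- w$annotation
  b <- build_annotation(ann$genes, w$genome$islands, ann$dhs_proximal,
                        ann$dhs_distal, ann$enhancers, w$genome$chrom_lengths,
                        ann$presence_distal, ann$presence_proximal)
  cats <- assign_probe_categories(w$manifest, b)
  n_cg <- sum(w$manifest$probes$probe_class == "cg")
  expect_equal(nrow(cats), n_cg)
  expect_false(anyNA(cats$gene_context))
  expect_equal(sum(table(cats$gene_context)), n_cg)
  expect_equal(sum(table(cats$cpg_context)), n_cg)
  # per-cell-type coverage is a fraction
  cc <- coverage_by_cell_type(ann$dhs_distal, ann$presence_distal,
                              data.frame(chrom = w$genome$cpg$chrom,
                                         pos = w$genome$cpg$pos))
  expect_true(all(cc >= 0 & cc <= 1, na.rm = TRUE))
})
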