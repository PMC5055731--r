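# Synthetic assay readouts: two-group array intensities with planted
# differential methylation, negative-control probes, WGBS count tables, and
# a minimal VCF of planted variants with known probe-overlap categories.

logit2 <- function(b, cap = 0.01) {
  b <- pmin(pmax(b, cap), 1 - cap)
  log2(b / (1 - b))
}
ilogit2 <- function(m) 2^m / (1 + 2^m)

#' Simulate two-group array intensities with known truth
#'
#' Signal model per probe and sample: the group-level true beta is jittered
#' on the M-value scale by N(0, `sigma_m`) biological replicate noise, a
#' total signal T ~ round(logNormal(log 8000, 0.25)) is split binomially
#' into methylated/unmethylated counts at the sample beta, and both
#' channels receive additive Gamma(4, scale 50) optical background.
#' Negative controls are drawn from the background distribution only, so
#' `E[M/(M+U+100)]` tracks the true beta and detection p-values separate
#' signal from background.
#'
#' @param config a [sim_config()].
#' @param manifest an `epicqc_manifest`.
#' @param truth optional output of [simulate_methylation_truth()]; when
#'   given, probe baselines are the truth at the probe's target CpG.
#' @param true_beta optional probes x 2 matrix overriding the group-level
#'   true betas entirely (rownames = probe ids).
#' @return `sim_intensities` list: `M`, `U` (probe x sample matrices),
#'   `controls_M`, `controls_U`, `samples` (sample_id, group), `true_beta`,
#'   `true_dmp_ids`, `delta_beta_true`.
#' @export
simulate_intensities <- function(config, manifest, truth = NULL,
                                 true_beta = NULL) {
  set_stream(config$seed, "intensities")
  probes <- manifest$probes
  n <- nrow(probes)
  if (is.null(true_beta)) {
    base <- runif(n, 0.70, 0.95)  # fallback: open-sea-like
    if (!is.null(truth)) {
      i <- match(paste(probes$chrom, probes$target_pos),
                 paste(truth$cpg$chrom, truth$cpg$pos))
      base[!is.na(i)] <- truth$cpg$base_m[i[!is.na(i)]]
    }
    g2 <- base
    is_cg <- probes$probe_class == "cg"
    n_dmp <- round(config$prop_dmp * sum(is_cg))
    dmp_idx <- which(is_cg)[sample.int(sum(is_cg), n_dmp)]
    for (j in dmp_idx) {
      d <- config$delta_beta_true * sample(c(-1, 1), 1)
      if (g2[j] + d > 0.99 || g2[j] + d < 0.01) d <- -d
      g2[j] <- g2[j] + d
    }
    true_beta <- cbind(group1 = base, group2 = g2)
    rownames(true_beta) <- probes$probe_id
    true_dmp_ids <- probes$probe_id[dmp_idx]
  } else {
    stopifnot(nrow(true_beta) == n, ncol(true_beta) == 2L)
    if (is.null(rownames(true_beta))) rownames(true_beta) <- probes$probe_id
    true_dmp_ids <- probes$probe_id[abs(true_beta[, 2] - true_beta[, 1]) > 0]
  }
  nsg <- config$n_samples_per_group
  samples <- data.frame(
    sample_id = c(paste0("g1_s", seq_len(nsg)), paste0("g2_s", seq_len(nsg))),
    group = rep(c("group1", "group2"), each = nsg),
    stringsAsFactors = FALSE)
  ns <- nrow(samples)
  M <- U <- matrix(0, n, ns, dimnames = list(probes$probe_id, samples$sample_id))
  for (s in seq_len(ns)) {
    b_true <- true_beta[, if (samples$group[s] == "group1") 1L else 2L]
    m_samp <- logit2(b_true) + rnorm(n, 0, config$sigma_m)
    b_samp <- ilogit2(m_samp)
    total <- as.integer(round(rlnorm(n, log(8000), 0.25)))
    msig <- rbinom(n, total, b_samp)
    M[, s] <- msig + round(rgamma(n, 4, scale = 50))
    U[, s] <- (total - msig) + round(rgamma(n, 4, scale = 50))
  }
  nc <- config$n_negative_controls
  ctrl <- function() {
    matrix(round(rgamma(nc * ns, 4, scale = 50)), nc, ns,
           dimnames = list(sprintf("neg%04d", seq_len(nc)), samples$sample_id))
  }
  structure(list(M = M, U = U, controls_M = ctrl(), controls_U = ctrl(),
                 samples = samples, true_beta = true_beta,
                 true_dmp_ids = true_dmp_ids,
                 delta_beta_true = config$delta_beta_true),
            class = "sim_intensities")
}

#' Write/read intensity matrices as long CSVs
#'
#' Format: `probe_id, sample, M_signal, U_signal` (negative controls use
#' `control_id` in place of `probe_id`).
#'
#' @param x a `sim_intensities`.
#' @param intensities_path,controls_path output CSV paths.
#' @return the paths, invisibly.
#' @export
write_intensities_csv <- function(x, intensities_path, controls_path) {
  long <- function(M, U, id_col) {
    df <- expand.grid(id = rownames(M), sample = colnames(M),
                      stringsAsFactors = FALSE)
    df$M_signal <- as.vector(M)
    df$U_signal <- as.vector(U)
    names(df)[1] <- id_col
    df
  }
  utils::write.csv(long(x$M, x$U, "probe_id"), intensities_path, row.names = FALSE)
  utils::write.csv(long(x$controls_M, x$controls_U, "control_id"),
                   controls_path, row.names = FALSE)
  invisible(c(intensities_path, controls_path))
}

#' @rdname write_intensities_csv
#' @param intensities_path,controls_path CSV paths written by
#'   [write_intensities_csv()].
#' @return for `read_intensities_csv`: list with `M`, `U`, `controls_M`,
#'   `controls_U` matrices.
#' @export
read_intensities_csv <- function(intensities_path, controls_path) {
  wide <- function(path, id_col) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    ids <- unique(df[[id_col]])
    samples <- unique(df$sample)
    shape <- function(col) {
      m <- matrix(NA_real_, length(ids), length(samples),
                  dimnames = list(ids, samples))
      m[cbind(match(df[[id_col]], ids), match(df$sample, samples))] <- df[[col]]
      m
    }
    list(M = shape("M_signal"), U = shape("U_signal"))
  }
  a <- wide(intensities_path, "probe_id")
  b <- wide(controls_path, "control_id")
  list(M = a$M, U = a$U, controls_M = b$M, controls_U = b$U)
}

#' Simulate a WGBS per-CpG count table
#'
#' Coverage is Poisson(`wgbs_mean_coverage`); methylated counts are
#' Binomial(coverage, true methylation).
#'
#' @param genome a `sim_genome`.
#' @param config a [sim_config()].
#' @param true_m per-CpG true methylation (defaults to the island/open-sea
#'   baseline of [simulate_methylation_truth()] when `truth` is given, else
#'   a flat 0.8); recycled/matched to `genome$cpg` rows.
#' @param label substream label, so multiple samples (e.g. per cell type)
#'   draw independent counts.
#' @return data.frame (bedGraph-like): `chrom`, `start`, `end`,
#'   `methylated_count`, `total_count`.
#' @export
simulate_wgbs_counts <- function(genome, config, true_m = NULL, label = "wgbs") {
  set_stream(config$seed, label)
  cpg <- genome$cpg
  n <- nrow(cpg)
  if (is.null(true_m)) true_m <- rep(0.8, n)
  if (length(true_m) == 1L) true_m <- rep(true_m, n)
  stopifnot(length(true_m) == n)
  cov <- rpois(n, config$wgbs_mean_coverage)
  meth <- rbinom(n, cov, true_m)
  data.frame(chrom = cpg$chrom, start = cpg$pos, end = cpg$pos + 2L,
             methylated_count = meth, total_count = cov,
             stringsAsFactors = FALSE)
}

#' Simulate genetic variants with known probe-overlap categories
#'
#' Plants SNPs/INDELs at target CpG, single-base-extension (Type I only)
#' and probe-body positions of isolated probes (footprints not overlapping
#' any other probe), at minor allele frequencies above the 0.05 filter;
#' additionally plants below-threshold overlaps (ground truth: filtered)
#' and background variants away from all probes, a fraction of them
#' multi-allelic to exercise MAF folding.
#'
#' @param genome a `sim_genome`.
#' @param manifest an `epicqc_manifest`.
#' @param config a [sim_config()].
#' @param path optional path; when given, the VCF is written there.
#' @return list: `vcf_lines` (character), `variants` (emitted records with
#'   their folded MAF), `ground_truth` (data.frame `probe_id`, `category`,
#'   `chrom`, `pos`, `maf`, `retained`).
#' @export
simulate_variants <- function(genome, manifest, config, path = NULL) {
  set_stream(config$seed, "variants")
  probes <- manifest$probes[manifest$probes$probe_class == "cg", ]
  # isolated probes: footprint (plus SBE base) not overlapping any other
  span <- data.frame(chrom = probes$chrom,
                     start = pmin(probes$fp_start, probes$sbe_pos),
                     end = pmax(probes$fp_end, probes$sbe_pos + 1L))
  gr <- ivs_to_gr(span)
  iso <- GenomicRanges::countOverlaps(gr, gr) == 1L
  iso_probes <- probes[iso, ]

  n_planted <- min(nrow(iso_probes), max(6L, config$n_variants %/% 4L))
  sel <- iso_probes[sample.int(nrow(iso_probes), n_planted), ]
  t1 <- which(sel$infinium_type == "I")
  cat_pool <- rep("PROBE_BODY", n_planted)
  cat_pool[seq_len(min(3L, n_planted))] <- "TARGET_CPG"
  if (length(t1)) {
    free <- setdiff(t1, which(cat_pool == "TARGET_CPG"))
    cat_pool[head(free, 2L)] <- "SBE"
  }

  recs <- list()
  truth <- NULL
  add_rec <- function(chrom, pos, ref, alts, afs) {
    recs[[length(recs) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, ref = ref,
      alt = paste(alts, collapse = ","), af = paste(afs, collapse = ","),
      stringsAsFactors = FALSE)
  }
  genome_base <- function(chrom, pos, len = 1L) {
    substr(genome$seq[[chrom]], pos + 1L, pos + len)
  }
  alt_base <- function(ref) sample(setdiff(c("A", "C", "G", "T"), ref), 1L)

  low_maf_every <- 4L   # every 4th planted overlap is below the MAF filter
  for (i in seq_len(n_planted)) {
    p <- sel[i, ]
    category <- cat_pool[i]
    pos <- switch(category,
                  TARGET_CPG = p$target_pos + sample(0:1, 1L),
                  SBE = p$sbe_pos,
                  PROBE_BODY = {
                    cand <- setdiff(seq(p$body_start, p$body_end - 1L),
                                    c(p$target_pos, p$target_pos + 1L, p$sbe_pos))
                    cand[sample.int(length(cand), 1L)]
                  })
    maf <- if (i %% low_maf_every == 0L) runif(1, 0.005, 0.045) else runif(1, 0.06, 0.5)
    af <- if (runif(1) < 0.5) maf else 1 - maf
    ref <- genome_base(p$chrom, pos)
    add_rec(p$chrom, pos, ref, alt_base(ref), signif(af, 4))
    truth <- rbind(truth, data.frame(
      probe_id = p$probe_id, category = category, chrom = p$chrom, pos = pos,
      maf = maf, retained = maf > 0.05, stringsAsFactors = FALSE))
  }

  # background variants clear of all probe spans
  n_bg <- max(0L, config$n_variants - n_planted)
  occupied <- ivs_to_gr(data.frame(chrom = span$chrom, start = span$start - 5L,
                                   end = span$end + 5L))
  placed <- 0L
  guard <- 0L
  while (placed < n_bg && guard < n_bg * 50L) {
    guard <- guard + 1L
    chrom <- sample(names(genome$seq), 1L)
    pos <- sample.int(genome$chrom_lengths[[chrom]] - 10L, 1L) - 1L
    hit <- GenomicRanges::countOverlaps(
      points_to_gr(chrom, pos), occupied) > 0L
    if (hit) next
    ref <- genome_base(chrom, pos)
    if (ref == "N") next
    maf <- runif(1, config$maf_distribution[1], config$maf_distribution[2])
    if (runif(1) < 0.10) {          # multi-allelic
      a1 <- alt_base(ref)
      a2 <- sample(setdiff(c("A", "C", "G", "T"), c(ref, a1)), 1L)
      af1 <- maf
      af2 <- runif(1, 0, min(0.3, 1 - af1 - 0.01))
      add_rec(chrom, pos, ref, c(a1, a2), signif(c(af1, af2), 4))
    } else if (runif(1) < 0.20) {   # deletion-style INDEL
      len <- sample(2:3, 1L)
      ref_s <- genome_base(chrom, pos, len)
      add_rec(chrom, pos, ref_s, substr(ref_s, 1, 1),
              signif(if (runif(1) < 0.5) maf else 1 - maf, 4))
    } else {
      add_rec(chrom, pos, ref, alt_base(ref),
              signif(if (runif(1) < 0.5) maf else 1 - maf, 4))
    }
    placed <- placed + 1L
  }

  variants <- do.call(rbind, recs)
  variants <- variants[order(variants$chrom, variants$pos), ]
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele Frequency">',
    paste0("##contig=<ID=", names(genome$seq), ",length=",
           genome$chrom_lengths, ">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\tAF=%s",
                  variants$chrom, variants$pos + 1L,
                  sprintf("var%04d", seq_len(nrow(variants))),
                  variants$ref, variants$alt, variants$af)
  vcf_lines <- c(header, body)
  if (!is.null(path)) writeLines(vcf_lines, path)
  list(vcf_lines = vcf_lines, variants = variants, ground_truth = truth)
}

#' Simulate the full synthetic evaluation world
#'
#' Runs every generator in order (genome, annotation, methylation truth,
#' manifest, intensities, WGBS for the first two cell types, variants) and
#' optionally writes all artifacts to `outdir` in their standard formats.
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory.
#' @return list with all generated objects and ground truths.
#' @export
simulate_world <- function(config, outdir = NULL) {
  genome <- simulate_genome(config)
  annotation <- simulate_annotation(genome, config)
  truth <- simulate_methylation_truth(genome, annotation, config)
  man <- simulate_manifest(genome, config)
  intens <- simulate_intensities(config, man$manifest, truth = truth)
  wgbs <- lapply(seq_len(min(2L, config$n_cell_types)), function(ct) {
    simulate_wgbs_counts(genome, config, true_m = truth$cell_m[, ct],
                         label = paste0("wgbs_cell", ct))
  })
  names(wgbs) <- annotation$cell_types[seq_along(wgbs)]
  vars <- simulate_variants(genome, man$manifest, config)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outdir, f)
    write_genome_fasta(genome, p("genome.fa"))
    write_cpg_bed(genome, p("cpg.bed"))
    write_bed(genome$islands, p("islands.bed"))
    write_bed(annotation$dhs_proximal, p("dhs_proximal.bed"), extra = "region_id")
    write_bed(annotation$dhs_distal, p("dhs_distal.bed"), extra = "region_id")
    write_bed(annotation$enhancers, p("enhancers.bed"), extra = "region_id")
    utils::write.table(annotation$genes, p("transcripts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_manifest(man$manifest, p("manifest.csv"))
    write_intensities_csv(intens, p("intensities.csv"), p("negative_controls.csv"))
    for (ct in names(wgbs)) {
      write_cpg_counts(wgbs[[ct]], p(paste0("wgbs_", ct, ".tsv")))
    }
    writeLines(vars$vcf_lines, p("variants.vcf"))
  }
  list(config = config, genome = genome, annotation = annotation,
       truth = truth, manifest = man$manifest,
       ground_truth = c(man$ground_truth,
                        list(variant_overlaps = vars$ground_truth,
                             true_dmp_ids = intens$true_dmp_ids)),
       intensities = intens, wgbs = wgbs, variants = vars)
}
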