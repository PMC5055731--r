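#' Simulation configuration for the synthetic evaluation world
#'
#' Bundles every tunable of the synthetic-data generators. Defaults describe
#' a desk-scale world whose rates mirror the real-data setting: CpG islands
#' at roughly one CpG per 12 bp versus a ~1% background density, three
#' samples per group (the matched fibroblast design), WGBS at 20x mean
#' coverage, and cross-hybridising duplications at 47/50 identity -- the
#' homology level at which array probes are considered cross-reactive.
#'
#' @param seed master seed; every generator derives its own substream from
#'   it, so outputs are byte-identical for a fixed seed.
#' @param genome_length_bp total genome length, split evenly over
#'   `n_chromosomes` (minimum 10,000).
#' @param n_chromosomes number of chromosomes.
#' @param n_islands number of CpG islands (>= 200 bp, spaced >= 4 kb).
#' @param island_cpg_rate expected CpG starts per bp inside islands.
#' @param background_cpg_rate expected CpG starts per bp elsewhere.
#' @param n_duplicated_segments planted cross-hybridisation sources.
#' @param duplication_identity fraction of the 50-base footprint that the
#'   planted copy preserves; `duplication_identity * 50` must be an integer.
#' @param n_probes_type1,n_probes_type2 CpG probe counts by Infinium type.
#' @param n_variants number of genetic variants emitted to the VCF.
#' @param maf_distribution length-2 numeric, (low, high) bounds for minor
#'   allele frequencies of planted variants.
#' @param n_samples_per_group array samples per group in the two-group
#'   intensity simulation.
#' @param delta_beta_true effect size (on the beta scale) added to group 2
#'   at planted differentially methylated probes.
#' @param prop_dmp fraction of CpG probes planted as true DMPs.
#' @param wgbs_mean_coverage Poisson mean of per-CpG WGBS coverage.
#' @param n_negative_controls number of negative-control probes.
#' @param sigma_m between-replicate biological noise on the M-value scale.
#' @param n_cell_types number of cell types in the DHS presence matrix.
#' @param n_dhs_distal,n_dhs_proximal,n_enhancers,n_genes annotation track
#'   sizes.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length_bp = 100000L,
                       n_chromosomes = 2L,
                       n_islands = 8L,
                       island_cpg_rate = 0.08,
                       background_cpg_rate = 0.01,
                       n_duplicated_segments = 4L,
                       duplication_identity = 47 / 50,
                       n_probes_type1 = 60L,
                       n_probes_type2 = 140L,
                       n_variants = 120L,
                       maf_distribution = c(0.01, 0.5),
                       n_samples_per_group = 3L,
                       delta_beta_true = 0.3,
                       prop_dmp = 0.05,
                       wgbs_mean_coverage = 20L,
                       n_negative_controls = 200L,
                       sigma_m = 0.15,
                       n_cell_types = 6L,
                       n_dhs_distal = 30L,
                       n_dhs_proximal = 10L,
                       n_enhancers = 10L,
                       n_genes = 10L) {
  cfg <- list(seed = as.integer(seed),
              genome_length_bp = as.integer(genome_length_bp),
              n_chromosomes = as.integer(n_chromosomes),
              n_islands = as.integer(n_islands),
              island_cpg_rate = island_cpg_rate,
              background_cpg_rate = background_cpg_rate,
              n_duplicated_segments = as.integer(n_duplicated_segments),
              duplication_identity = duplication_identity,
              n_probes_type1 = as.integer(n_probes_type1),
              n_probes_type2 = as.integer(n_probes_type2),
              n_variants = as.integer(n_variants),
              maf_distribution = maf_distribution,
              n_samples_per_group = as.integer(n_samples_per_group),
              delta_beta_true = delta_beta_true,
              prop_dmp = prop_dmp,
              wgbs_mean_coverage = as.integer(wgbs_mean_coverage),
              n_negative_controls = as.integer(n_negative_controls),
              sigma_m = sigma_m,
              n_cell_types = as.integer(n_cell_types),
              n_dhs_distal = as.integer(n_dhs_distal),
              n_dhs_proximal = as.integer(n_dhs_proximal),
              n_enhancers = as.integer(n_enhancers),
              n_genes = as.integer(n_genes))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$genome_length_bp < 10000L) {
    stop_config("genome_length_bp must be >= 10,000")
  }
  rates <- c(island = cfg$island_cpg_rate, background = cfg$background_cpg_rate)
  if (any(rates < 0 | rates > 1)) stop_config("CpG rates must lie in [0, 1]")
  if (cfg$island_cpg_rate >= 0.5 || cfg$background_cpg_rate >= 0.5) {
    stop_config("CpG rates must be < 0.5 (CpGs occupy two bases)")
  }
  if (cfg$duplication_identity < 0 || cfg$duplication_identity > 1) {
    stop_config("duplication_identity must lie in [0, 1]")
  }
  m <- cfg$duplication_identity * 50
  if (abs(m - round(m)) > 1e-9) {
    stop_config("duplication_identity * 50 must be an integer, got ", m)
  }
  if (length(cfg$maf_distribution) != 2L ||
      any(cfg$maf_distribution < 0) || any(cfg$maf_distribution > 0.5) ||
      cfg$maf_distribution[1] > cfg$maf_distribution[2]) {
    stop_config("maf_distribution must be (low, high) bounds within [0, 0.5]")
  }
  if (cfg$n_samples_per_group < 2L) {
    stop_config("n_samples_per_group must be >= 2 (residual df needed)")
  }
  if (any(cfg$delta_beta_true < -1 | cfg$delta_beta_true > 1)) {
    stop_config("delta_beta_true must lie in [-1, 1]")
  }
  if (cfg$prop_dmp < 0 || cfg$prop_dmp > 1) stop_config("prop_dmp must lie in [0, 1]")
  if (cfg$wgbs_mean_coverage < 1L) stop_config("wgbs_mean_coverage must be >= 1")
  if (cfg$sigma_m < 0) stop_config("sigma_m must be >= 0")
  # island layout feasibility: each island needs >= 200 bp plus 4 kb spacing,
  # and each chromosome reserves a duplication landing zone.
  per_chrom <- cfg$genome_length_bp %/% cfg$n_chromosomes
  islands_per_chrom <- ceiling(cfg$n_islands / cfg$n_chromosomes)
  need <- islands_per_chrom * (600 + 4000) + 4000
  if (per_chrom < need) {
    stop_config("island/duplication layout infeasible: chromosomes of ",
                per_chrom, " bp cannot hold ", islands_per_chrom,
                " islands with 4 kb spacing")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$genome_length_bp, "bp over",
      x$n_chromosomes, "chromosome(s) |", x$n_islands, "islands |",
      x$n_probes_type1 + x$n_probes_type2, "CpG probes |",
      x$n_duplicated_segments, "planted duplications\n")
  invisible(x)
}
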