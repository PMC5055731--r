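# Shared fixtures and independent oracles. Worlds are cached per session so
# several test files can reuse the same seeded simulation.

.fixture_env <- new.env(parent = emptyenv())

world1 <- function() {
  if (is.null(.fixture_env$world1)) {
    .fixture_env$world1 <- simulate_world(sim_config(seed = 1))
  }
  .fixture_env$world1
}

# tiny config for scan-heavy tests
tiny_config <- function(seed, n_duplicated_segments = 2L,
                        duplication_identity = 47 / 50) {
  sim_config(seed = seed, genome_length_bp = 12000L, n_chromosomes = 1L,
             n_islands = 1L, n_duplicated_segments = n_duplicated_segments,
             duplication_identity = duplication_identity,
             n_probes_type1 = 5L, n_probes_type2 = 10L, n_variants = 20L,
             n_dhs_distal = 4L, n_dhs_proximal = 2L, n_enhancers = 2L,
             n_genes = 2L)
}

# independent R-level match counter (base matching rules re-derived, not the
# C++ path): query over A/C/G/T/R/Y vs genome window over A/C/G/T/N
r_match_count <- function(query, window) {
  q <- strsplit(query, "")[[1]]
  w <- strsplit(window, "")[[1]]
  ok <- q == w
  ok <- ok | (q == "R" & w %in% c("A", "G"))
  ok <- ok | (q == "Y" & w %in% c("C", "T"))
  ok[w == "N"] <- FALSE
  sum(ok)
}

# all-window R oracle: every (start, count) with count >= min_count
r_scan_oracle <- function(query, genome_seq, min_count) {
  L <- nchar(genome_seq)
  w <- nchar(query)
  if (L < w) return(data.frame(start = integer(0), count = integer(0)))
  starts <- 0:(L - w)
  counts <- vapply(starts, function(s) {
    r_match_count(query, substr(genome_seq, s + 1, s + w))
  }, numeric(1))
  keep <- counts >= min_count
  data.frame(start = starts[keep], count = as.integer(counts[keep]))
}

# per-region brute-force point-overlap counting oracle
r_coverage_oracle <- function(regions, positions) {
  vapply(seq_len(nrow(regions)), function(i) {
    sum(positions$chrom == regions$chrom[i] &
          positions$pos >= regions$start[i] &
          positions$pos < regions$end[i])
  }, numeric(1))
}

# manifest built from a hand-written probe table (sequences are
# placeholders; geometry-only tests)
make_manifest <- function(df) {
  tmp <- tempfile(fileext = ".csv")
  if (is.null(df$sequence_u)) df$sequence_u <- strrep("A", 50)
  if (is.null(df$sequence_m)) {
    df$sequence_m <- ifelse(df$infinium_type == "I", strrep("A", 50), "")
  }
  out <- data.frame(probe_id = df$probe_id, infinium_type = df$infinium_type,
                    chrom = df$chrom, mapinfo = df$target_pos + 1L,
                    strand = df$strand, sequence_u = df$sequence_u,
                    sequence_m = df$sequence_m)
  utils::write.csv(out, tmp, row.names = FALSE, quote = FALSE)
  read_manifest(tmp, "fixture")
}

# beta_matrix wrapper around a plain beta matrix (no detection p-values)
make_beta_matrix <- function(beta, groups = NULL) {
  samples <- if (!is.null(groups)) {
    data.frame(sample_id = colnames(beta), group = groups,
               stringsAsFactors = FALSE)
  }
  structure(list(beta = beta, detection_p = NULL, M = NULL, U = NULL,
                 samples = samples), class = "beta_matrix")
}

# region_methylation row builder for fixtures
make_region_meth <- function(region_id, mean_beta, platform = "WGBS",
                             informative = TRUE) {
  out <- data.frame(region_id = region_id, platform = platform,
                    mean_beta = mean_beta, n_cpgs_in_region = 3L,
                    n_used = 3L, total_coverage = 100,
                    status = ifelse(mean_beta <= 0.3, "low",
                                    ifelse(mean_beta > 0.6, "high", "mid")),
                    informative = informative, stringsAsFactors = FALSE)
  class(out) <- c("region_methylation", "data.frame")
  out
}
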