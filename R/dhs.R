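# Region-level methylation at distal regulatory elements, WGBS vs array.
#
# WGBS region methylation is the pooled ratio: sum of methylated readouts
# over sum of total readouts across all CpGs in the region (equivalently
# the coverage-weighted mean of per-CpG ratios). Array region methylation
# is the unweighted mean beta of detection-passing probes in the region.
# Region status: low (beta <= 0.3), mid, high (beta > 0.6).

#' Write / read per-CpG WGBS count tables
#'
#' bedGraph-like TSV with header: `chrom`, `start`, `end`,
#' `methylated_count`, `total_count` (0-based half-open CpG intervals).
#'
#' @param counts data.frame as produced by [simulate_wgbs_counts()].
#' @param path TSV path.
#' @return the path / the counts data.frame.
#' @export
write_cpg_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cpg_counts
#' @export
read_cpg_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "methylated_count", "total_count")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_format("count table missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(df$methylated_count > df$total_count) || any(df$methylated_count < 0)) {
    stop_format("methylated_count must lie in [0, total_count]")
  }
  df
}

meth_status <- function(beta) {
  ifelse(is.na(beta), NA_character_,
         ifelse(beta <= 0.3, "low", ifelse(beta > 0.6, "high", "mid")))
}

#' Select regions with enough genomic CpGs
#'
#' @param regions catalog data.frame (`chrom`, `start`, `end`,
#'   `region_id`).
#' @param cpg_positions data.frame (`chrom`, `pos`).
#' @param min_cpgs minimum CpG count (default 3).
#' @return the eligible subset of `regions` with an `n_cpgs` column.
#' @export
select_regions <- function(regions, cpg_positions, min_cpgs = 3L) {
  counts <- count_points_in_ivs(regions, cpg_positions$chrom, cpg_positions$pos)
  out <- regions[counts >= min_cpgs, , drop = FALSE]
  out$n_cpgs <- counts[counts >= min_cpgs]
  rownames(out) <- NULL
  out
}

#' Region methylation from WGBS counts
#'
#' Pooled ratio per region: `sum(methylated) / sum(total)` over the CpGs
#' inside the region. A region is informative when its pooled observation
#' count reaches `min_region_cov` (default 50; set
#' `coverage_rule = "mean_per_cpg"` for the mean-coverage-per-CpG
#' interpretation instead).
#'
#' @param counts per-CpG count table (see [read_cpg_counts()]).
#' @param regions region catalog with `region_id`.
#' @param min_region_cov coverage threshold (default 50).
#' @param coverage_rule `"pooled"` (default) or `"mean_per_cpg"`.
#' @return data.frame of class `region_methylation`: `region_id`,
#'   `platform` ("WGBS"), `mean_beta`, `n_cpgs_in_region`, `n_used`,
#'   `total_coverage`, `status`, `informative`.
#' @export
region_methylation_wgbs <- function(counts, regions, min_region_cov = 50L,
                                    coverage_rule = c("pooled", "mean_per_cpg")) {
  coverage_rule <- match.arg(coverage_rule)
  gr_r <- ivs_to_gr(regions)
  gr_c <- points_to_gr(counts$chrom, counts$start)
  ov <- GenomicRanges::findOverlaps(gr_r, gr_c)
  ri <- S4Vectors::queryHits(ov)
  ci <- S4Vectors::subjectHits(ov)
  n <- nrow(regions)
  meth <- total <- n_cpg <- n_used <- rep(0, n)
  if (length(ov)) {
    meth <- as.numeric(tapply(counts$methylated_count[ci], factor(ri, levels = seq_len(n)), sum, default = 0))
    total <- as.numeric(tapply(counts$total_count[ci], factor(ri, levels = seq_len(n)), sum, default = 0))
    n_cpg <- as.integer(tapply(ci, factor(ri, levels = seq_len(n)), length, default = 0L))
    n_used <- as.integer(tapply(counts$total_count[ci] > 0, factor(ri, levels = seq_len(n)), sum, default = 0L))
  }
  mean_beta <- ifelse(total > 0, meth / total, NA_real_)
  informative <- if (coverage_rule == "pooled") {
    total >= min_region_cov
  } else {
    n_cpg > 0 & (total / pmax(n_cpg, 1)) >= min_region_cov
  }
  out <- data.frame(region_id = regions$region_id, platform = "WGBS",
                    mean_beta = mean_beta, n_cpgs_in_region = n_cpg,
                    n_used = n_used, total_coverage = total,
                    status = meth_status(mean_beta),
                    informative = informative & !is.na(mean_beta),
                    stringsAsFactors = FALSE)
  class(out) <- c("region_methylation", "data.frame")
  out
}

#' Region methylation from array beta-values
#'
#' Unweighted mean of the betas of detection-passing probes whose assayed
#' CpG lies in the region; informative when at least one probe passes.
#'
#' @param beta_matrix a `beta_matrix`.
#' @param manifest an `epicqc_manifest`.
#' @param regions region catalog with `region_id`.
#' @param sample sample id (column of the beta matrix).
#' @param detection_threshold probe filter, detection p < this (default
#'   0.01); ignored when detection p-values are unavailable.
#' @return data.frame of class `region_methylation` (platform "array").
#' @export
region_methylation_array <- function(beta_matrix, manifest, regions, sample,
                                     detection_threshold = 0.01) {
  probes <- manifest$probes[manifest$probes$probe_class == "cg", ]
  beta <- beta_matrix$beta[probes$probe_id, sample]
  pass <- !is.na(beta)
  if (!is.null(beta_matrix$detection_p)) {
    pass <- pass & beta_matrix$detection_p[probes$probe_id, sample] < detection_threshold
  }
  gr_r <- ivs_to_gr(regions)
  gr_p <- points_to_gr(probes$chrom, probes$target_pos)
  ov <- GenomicRanges::findOverlaps(gr_r, gr_p)
  ri <- S4Vectors::queryHits(ov)
  pi <- S4Vectors::subjectHits(ov)
  n <- nrow(regions)
  f <- factor(ri[pass[pi]], levels = seq_len(n))
  mean_beta <- as.numeric(tapply(beta[pi[pass[pi]]], f, mean, default = NA_real_))
  n_used <- as.integer(table(f))
  n_probes <- as.integer(table(factor(ri, levels = seq_len(n))))
  out <- data.frame(region_id = regions$region_id, platform = "array",
                    mean_beta = mean_beta, n_cpgs_in_region = n_probes,
                    n_used = n_used, total_coverage = n_used,
                    status = meth_status(mean_beta),
                    informative = n_used >= 1L,
                    stringsAsFactors = FALSE)
  class(out) <- c("region_methylation", "data.frame")
  out
}

#' Association between region methylation and DHS presence
#'
#' 2x2 table over informative regions: lowly methylated (beta <= 0.3)
#' versus not, crossed with DHS present versus absent in the cell type.
#' The log odds ratio is positive when presence goes with low methylation
#' (the expected open-chromatin signal). Wald 95% CI; Haldane 0.5
#' correction on zero cells (flagged).
#'
#' @param region_meth a `region_methylation` data.frame.
#' @param presence named logical vector (region_id -> present) for one
#'   cell type.
#' @return list: `log_or`, `ci_lo`, `ci_hi` (log scale), `table`
#'   (low/notlow x present/absent), `haldane`, `n_regions`.
#' @export
methylation_vs_dhs <- function(region_meth, presence) {
  rm <- region_meth[region_meth$informative, ]
  pres <- presence[rm$region_id]
  if (any(is.na(pres))) stop_integrity("presence missing for some regions")
  low <- rm$mean_beta <= 0.3
  tab <- c(sum(low & pres), sum(!low & pres), sum(low & !pres), sum(!low & !pres))
  or <- odds_ratio(tab[1], tab[2], tab[3], tab[4])
  list(log_or = or$log_or, ci_lo = log(or$ci_lo), ci_hi = log(or$ci_hi),
       table = matrix(tab, 2, 2, byrow = TRUE,
                      dimnames = list(c("present", "absent"), c("low", "not_low"))),
       haldane = or$haldane, n_regions = nrow(rm))
}

#' Cross-platform concordance of region methylation
#'
#' Computed over regions informative on both platforms: Spearman rho of
#' the region means, nested agreement fractions at absolute differences
#' < 0.20 / 0.10 / 0.05 (on the beta scale), and the list of large
#' disagreements (low on one platform, high on the other).
#'
#' @param wgbs_regions,array_regions `region_methylation` data.frames on a
#'   shared catalog.
#' @return list of class `concordance_result`: `n_common_regions`,
#'   `spearman_rho`, `frac_lt_20`, `frac_lt_10`, `frac_lt_05`,
#'   `disagreements` (region_id, wgbs_beta, array_beta).
#' @export
cross_platform_concordance <- function(wgbs_regions, array_regions) {
  i <- match(wgbs_regions$region_id, array_regions$region_id)
  ok <- wgbs_regions$informative & !is.na(i) & array_regions$informative[i]
  w <- wgbs_regions[ok, ]
  a <- array_regions[i[ok], ]
  if (nrow(w) < 3L) {
    stop_integrity("fewer than 3 regions informative on both platforms")
  }
  d <- abs(w$mean_beta - a$mean_beta)
  dis <- (w$mean_beta <= 0.3 & a$mean_beta > 0.6) |
    (w$mean_beta > 0.6 & a$mean_beta <= 0.3)
  structure(list(
    n_common_regions = nrow(w),
    spearman_rho = cor(w$mean_beta, a$mean_beta, method = "spearman"),
    frac_lt_20 = mean(d < 0.20), frac_lt_10 = mean(d < 0.10),
    frac_lt_05 = mean(d < 0.05),
    disagreements = data.frame(region_id = w$region_id[dis],
                               wgbs_beta = w$mean_beta[dis],
                               array_beta = a$mean_beta[dis],
                               stringsAsFactors = FALSE)),
    class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance over %d regions: rho = %.3f; |diff| < 0.20/0.10/0.05: %.0f%%/%.0f%%/%.0f%%; %d large disagreements\n",
              x$n_common_regions, x$spearman_rho, 100 * x$frac_lt_20,
              100 * x$frac_lt_10, 100 * x$frac_lt_05, nrow(x$disagreements)))
  invisible(x)
}

#' Type large platform disagreements
#'
#' For each disagreement region, compares the array region beta with the
#' WGBS beta at the probe's own target CpG (requiring `min_cov`
#' observations there): when the probe agrees with its own CpG
#' (|array - own CpG| < tau) but not with the region mean, the probe is
#' faithfully assaying an unrepresentative CpG (`PROBE_POSITIONING`);
#' when it disagrees with its own CpG too, the readout itself is suspect
#' (`TECHNICAL_ARTIFACT`). Regions without `min_cov` coverage at the
#' probe CpG stay unclassified (`NA`).
#'
#' @param disagreements data.frame from
#'   [cross_platform_concordance()]`$disagreements`.
#' @param counts per-CpG WGBS count table.
#' @param manifest an `epicqc_manifest`.
#' @param regions the region catalog (`region_id`, `chrom`, `start`,
#'   `end`).
#' @param tau agreement threshold on the beta scale (default 0.2).
#' @param min_cov minimum WGBS coverage at the probe CpG (default 10).
#' @return `disagreements` with `own_cpg_beta`, `own_cpg_coverage`,
#'   `type` columns.
#' @export
classify_disagreements <- function(disagreements, counts, manifest, regions,
                                   tau = 0.2, min_cov = 10L) {
  probes <- manifest$probes[manifest$probes$probe_class == "cg", ]
  key <- paste(counts$chrom, counts$start)
  out <- disagreements
  out$own_cpg_beta <- NA_real_
  out$own_cpg_coverage <- 0L
  out$type <- NA_character_
  for (i in seq_len(nrow(out))) {
    r <- regions[regions$region_id == out$region_id[i], ]
    inreg <- probes$chrom == r$chrom & probes$target_pos >= r$start &
      probes$target_pos < r$end
    j <- match(paste(probes$chrom[inreg], probes$target_pos[inreg]), key)
    j <- j[!is.na(j)]
    j <- j[counts$total_count[j] >= min_cov]
    if (!length(j)) next
    own <- mean(counts$methylated_count[j] / counts$total_count[j])
    out$own_cpg_beta[i] <- own
    out$own_cpg_coverage[i] <- sum(counts$total_count[j])
    arr <- out$array_beta[i]
    out$type[i] <- if (abs(arr - own) < tau &&
                       abs(arr - out$wgbs_beta[i]) >= tau) {
      "PROBE_POSITIONING"
    } else {
      "TECHNICAL_ARTIFACT"
    }
  }
  out
}
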