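# Platform-to-platform probe comparison and 2x2 enrichment statistics.

#' Odds ratio with Wald 95% confidence interval from a 2x2 table
#'
#' The table is `(a, b, c, d)` read row-wise:
#' `a` = group1 & property, `b` = group1 & !property,
#' `c` = group2 & property, `d` = group2 & !property.
#' When any cell is zero the Haldane-Anscombe 0.5 correction is added to all
#' four cells so the OR and its interval stay finite (flagged in the result).
#'
#' @param a,b,c,d non-negative cell counts.
#' @param conf_level confidence level (default 0.95).
#' @return list with `or`, `log_or`, `ci_lo`, `ci_hi`, `se_log_or`,
#'   `haldane` (logical).
#' @export
odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop_integrity("negative cell count in 2x2 table")
  haldane <- any(cells == 0)
  if (haldane) cells <- cells + 0.5
  lor <- log(cells[1]) - log(cells[2]) - log(cells[3]) + log(cells[4])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(lor), log_or = lor,
       ci_lo = exp(lor - z * se), ci_hi = exp(lor + z * se),
       se_log_or = se, haldane = haldane)
}

#' Compare two platform manifests
#'
#' Reports the shared/unique probe id sets and, for a binary probe property,
#' the enrichment of that property among probes of `a` that are absent from
#' `b` ("excluded") versus retained, as an odds ratio with Wald 95% CI.
#'
#' @param a,b `epicqc_manifest` objects.
#' @param property named logical vector over probe ids of `a` (or `NULL`);
#'   by default the property is "probe is Infinium Type I".
#' @return list of class `platform_comparison` with `shared_ids`,
#'   `unique_to_a`, `unique_to_b` and `enrichment` (from [odds_ratio()]).
#' @export
compare_platforms <- function(a, b, property = NULL) {
  if (nrow(a$probes) == 0L || nrow(b$probes) == 0L) {
    stop_integrity("cannot compare empty manifests")
  }
  ids_a <- a$probes$probe_id
  ids_b <- b$probes$probe_id
  shared <- intersect(ids_a, ids_b)
  only_a <- setdiff(ids_a, ids_b)
  only_b <- setdiff(ids_b, ids_a)

  if (is.null(property)) {
    property <- setNames(a$probes$infinium_type == "I", ids_a)
  }
  prop <- property[ids_a]
  excluded <- !(ids_a %in% shared)
  enr <- odds_ratio(sum(excluded & prop), sum(excluded & !prop),
                    sum(!excluded & prop), sum(!excluded & !prop))
  structure(list(platform_a = a$platform_name, platform_b = b$platform_name,
                 shared_ids = shared, unique_to_a = only_a,
                 unique_to_b = only_b, enrichment = enr),
            class = "platform_comparison")
}

#' @export
print.platform_comparison <- function(x, ...) {
  n_a <- length(x$shared_ids) + length(x$unique_to_a)
  cat(sprintf("%s vs %s: %d shared (%.1f%% of %s), %d unique to %s, %d unique to %s\n",
              x$platform_a, x$platform_b, length(x$shared_ids),
              100 * length(x$shared_ids) / n_a, x$platform_a,
              length(x$unique_to_a), x$platform_a,
              length(x$unique_to_b), x$platform_b))
  cat(sprintf("  excluded-probe enrichment: OR = %.2f (95%% CI %.2f-%.2f)\n",
              x$enrichment$or, x$enrichment$ci_lo, x$enrichment$ci_hi))
  invisible(x)
}
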