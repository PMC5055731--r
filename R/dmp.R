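# Differential methylation calling.
#
# Per probe, a two-group ordinary-least-squares fit on M-values with
# empirical-Bayes variance moderation: residual variances are shrunk
# towards a pooled prior fitted by method of moments on the log-variance
# scale (a scaled inverse-chi-square prior; equivalently the residual
# variances follow a scaled F distribution marginally). The moderated t
# gains the prior degrees of freedom; with prior df = 0 it reduces to the
# ordinary t, with prior df = Inf to a z-like statistic. A probe is a DMP
# when its moderated p-value and the absolute group beta difference both
# pass their thresholds.

# Newton solve of trigamma(x) = y (y > 0), vectorised.
trigamma_inverse <- function(y) {
  stopifnot(all(y > 0))
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of residual variances
#'
#' Fits a scaled inverse-chi-square prior (df_prior, s2_prior) to the
#' observed residual variances by matching the mean and variance of
#' `log(s2)` (using digamma/trigamma moments of the log-chi-square), then
#' returns the posterior (shrunk) variances
#' `(df_prior * s2_prior + df * s2) / (df_prior + df)`.
#'
#' @param s2 residual variances (one per probe).
#' @param df residual degrees of freedom (scalar).
#' @param df_prior,s2_prior optional fixed prior (skips estimation);
#'   `df_prior = 0` returns the unmoderated variances, `df_prior = Inf`
#'   returns `s2_prior` everywhere.
#' @return list: `s2_post`, `df_prior`, `s2_prior`, `df_total`.
#' @export
moderate_variances <- function(s2, df, df_prior = NULL, s2_prior = NULL) {
  stopifnot(df > 0)
  if (is.null(df_prior)) {
    z <- log(pmax(s2, 1e-300))
    e <- z - digamma(df / 2) + log(df / 2)
    evar <- if (length(e) > 1L) var(e) - trigamma(df / 2) else 0
    if (is.finite(evar) && evar > 0) {
      df_prior <- 2 * trigamma_inverse(evar)
      s2_prior <- exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2))
    } else {
      df_prior <- Inf
      s2_prior <- exp(mean(e))
    }
  } else if (is.null(s2_prior)) {
    s2_prior <- mean(s2)
  }
  s2_post <- if (is.infinite(df_prior)) {
    rep(s2_prior, length(s2))
  } else {
    (df_prior * s2_prior + df * s2) / (df_prior + df)
  }
  list(s2_post = s2_post, df_prior = df_prior, s2_prior = s2_prior,
       df_total = df + df_prior)
}

#' Call differentially methylated probes between two groups
#'
#' Probes must pass the detection filter (p < `detection_threshold`) in
#' every sample; M-values are the logit2-transformed betas (clamped at
#' 0.01/0.99); testing is an unpaired two-group comparison with
#' empirical-Bayes moderated t-statistics. A probe is flagged as a DMP
#' when `p < p_thresh` and `|delta_beta| > db_thresh`.
#'
#' @param beta_matrix a `beta_matrix`.
#' @param groups character/factor of group labels per sample (2 levels);
#'   defaults to `beta_matrix$samples$group`.
#' @param p_thresh p-value threshold (default 0.001).
#' @param db_thresh minimum absolute group beta difference (default 0.1).
#' @param detection_threshold detection-p filter applied in all samples
#'   (default 0.01); `NULL` skips filtering.
#' @param df_prior optional fixed prior df (see [moderate_variances()]).
#' @return data.frame of class `dmp_result`: `probe_id`, `delta_beta`,
#'   `moderated_t`, `p_value`, `is_dmp`; prior fit in attributes
#'   `df_prior`, `s2_prior`, `df_total`.
#' @export
call_dmps <- function(beta_matrix, groups = NULL, p_thresh = 0.001,
                      db_thresh = 0.1, detection_threshold = 0.01,
                      df_prior = NULL) {
  beta <- beta_matrix$beta
  if (is.null(groups)) groups <- beta_matrix$samples$group
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(beta))
  lev <- unique(groups)
  if (length(lev) != 2L) stop_integrity("exactly two groups required")
  n1 <- sum(groups == lev[1])
  n2 <- sum(groups == lev[2])
  if (n1 < 2L || n2 < 2L) {
    stop_integrity("each group needs >= 2 samples (no residual df otherwise)")
  }
  keep <- rep(TRUE, nrow(beta))
  if (!is.null(detection_threshold)) {
    if (is.null(beta_matrix$detection_p)) {
      stop_integrity("detection p-values unavailable; cannot apply detection filter")
    }
    keep <- rowSums(beta_matrix$detection_p < detection_threshold) == ncol(beta)
  }
  b <- beta[keep, , drop = FALSE]
  m <- beta_to_m(b)
  i1 <- groups == lev[1]
  i2 <- groups == lev[2]
  mean1 <- rowMeans(m[, i1, drop = FALSE])
  mean2 <- rowMeans(m[, i2, drop = FALSE])
  rss <- rowSums((m[, i1, drop = FALSE] - mean1)^2) +
    rowSums((m[, i2, drop = FALSE] - mean2)^2)
  df <- n1 + n2 - 2L
  s2 <- rss / df
  mod <- moderate_variances(s2, df, df_prior = df_prior)
  se <- sqrt(mod$s2_post * (1 / n1 + 1 / n2))
  tstat <- (mean2 - mean1) / se
  p <- if (is.infinite(mod$df_total)) {
    2 * stats::pnorm(-abs(tstat))
  } else {
    2 * pt(-abs(tstat), df = mod$df_total)
  }
  delta_beta <- rowMeans(b[, i2, drop = FALSE]) - rowMeans(b[, i1, drop = FALSE])
  out <- data.frame(probe_id = rownames(b) %||% as.character(which(keep)),
                    delta_beta = delta_beta, moderated_t = tstat,
                    p_value = p,
                    is_dmp = p < p_thresh & abs(delta_beta) > db_thresh,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "df_prior") <- mod$df_prior
  attr(out, "s2_prior") <- mod$s2_prior
  attr(out, "df_total") <- mod$df_total
  attr(out, "groups") <- lev
  class(out) <- c("dmp_result", "data.frame")
  out
}

#' Cross-platform agreement of DMP calls
#'
#' Treats platform `a` as the reference call set: of its DMPs, how many are
#' present as probes on platform `b`, how many are confirmed as DMPs on
#' `b` at the primary thresholds, and how many at a relaxed p-value cutoff
#' (the delta-beta criterion is kept). Also reports the Spearman
#' correlation of the estimated delta-betas across the shared DMPs.
#'
#' @param results_a,results_b `dmp_result` objects.
#' @param relaxed_p relaxed p-value cutoff for confirmation on `b`
#'   (default 0.01).
#' @param db_thresh delta-beta threshold used for relaxed confirmation.
#' @return list of class `agreement_summary`.
#' @export
dmp_agreement <- function(results_a, results_b, relaxed_p = 0.01,
                          db_thresh = 0.1) {
  shared <- intersect(results_a$probe_id, results_b$probe_id)
  if (!length(shared)) stop_integrity("disjoint probe universes")
  a_dmps <- results_a$probe_id[results_a$is_dmp]
  b_dmps <- results_b$probe_id[results_b$is_dmp]
  on_b <- intersect(a_dmps, results_b$probe_id)
  ib <- match(on_b, results_b$probe_id)
  confirmed <- on_b[results_b$is_dmp[ib]]
  relaxed <- on_b[results_b$p_value[ib] < relaxed_p &
                    abs(results_b$delta_beta[ib]) > db_thresh]
  rho <- if (length(on_b) >= 3L) {
    cor(results_a$delta_beta[match(on_b, results_a$probe_id)],
        results_b$delta_beta[ib], method = "spearman")
  } else NA_real_
  structure(list(n_dmps_a = length(a_dmps), n_dmps_b = length(b_dmps),
                 n_a_probes_on_b = length(on_b),
                 n_confirmed_at_primary_threshold = length(confirmed),
                 n_confirmed_at_relaxed_threshold = length(relaxed),
                 confirmed_ids = confirmed, relaxed_ids = relaxed,
                 spearman_rho = rho),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("DMPs: a = %d, b = %d; a-DMPs on b = %d; confirmed = %d (relaxed: %d); rho(delta-beta) = %.3f\n",
              x$n_dmps_a, x$n_dmps_b, x$n_a_probes_on_b,
              x$n_confirmed_at_primary_threshold,
              x$n_confirmed_at_relaxed_threshold, x$spearman_rho))
  invisible(x)
}
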