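# Beta-value computation and descriptive statistics.
#
# beta = M / (M + U + 100): the +100 offset regularises low-intensity
# probes and keeps beta strictly below 1 for finite signals. Background is
# removed by subtracting a configurable percentile of the negative-control
# intensities per channel and sample (an approximation of scanner-software
# background normalisation), flooring at zero. The detection p-value of a
# probe is the one-sided empirical rank of its total intensity (M + U)
# within the negative-control total-intensity distribution, floored at
# 1/(n_controls + 1); probes dimmer than every control get p = 1.

#' Compute beta-values and detection p-values from raw intensities
#'
#' @param intensities list with `M` and `U` probe x sample matrices
#'   (matching dimnames), e.g. from [read_intensities_csv()] or a
#'   `sim_intensities` object.
#' @param negative_controls list with `M` and `U` (or `controls_M` /
#'   `controls_U`) control x sample matrices, or `NULL` (no background
#'   step, detection unavailable).
#' @param offset the +100 stabilising offset.
#' @param bg_percentile percentile of control intensities subtracted per
#'   channel (default 0.5, the median).
#' @param samples optional data.frame with `sample_id`, `group`.
#' @return object of class `beta_matrix`: `beta`, `detection_p` (or NULL),
#'   `M`, `U`, `samples`.
#' @export
compute_beta <- function(intensities, negative_controls = NULL, offset = 100,
                         bg_percentile = 0.5, samples = NULL) {
  if (inherits(intensities, "sim_intensities")) {
    if (is.null(negative_controls)) {
      negative_controls <- list(M = intensities$controls_M,
                                U = intensities$controls_U)
    }
    if (is.null(samples)) samples <- intensities$samples
  }
  M <- intensities$M
  U <- intensities$U
  stopifnot(is.matrix(M), is.matrix(U), all(dim(M) == dim(U)))
  if (any(M < 0) || any(U < 0)) stop_format("negative raw intensities")
  ctrl <- NULL
  if (!is.null(negative_controls)) {
    cm <- negative_controls$M %||% negative_controls$controls_M
    cu <- negative_controls$U %||% negative_controls$controls_U
    if (is.null(cm) || nrow(cm) == 0L) {
      negative_controls <- NULL
    } else {
      ctrl <- list(M = cm, U = cu)
    }
  }
  detection_p <- NULL
  Mb <- M
  Ub <- U
  if (!is.null(ctrl)) {
    detection_p <- matrix(NA_real_, nrow(M), ncol(M), dimnames = dimnames(M))
    n_ctrl <- nrow(ctrl$M)
    for (s in seq_len(ncol(M))) {
      Mb[, s] <- pmax(M[, s] - quantile(ctrl$M[, s], bg_percentile), 0)
      Ub[, s] <- pmax(U[, s] - quantile(ctrl$U[, s], bg_percentile), 0)
      ctot <- sort(ctrl$M[, s] + ctrl$U[, s])
      tot <- M[, s] + U[, s]
      n_ge <- n_ctrl - findInterval(tot - 1e-9, ctot)  # controls >= total
      detection_p[, s] <- (1 + n_ge) / (n_ctrl + 1)
    }
  }
  beta <- Mb / (Mb + Ub + offset)
  structure(list(beta = beta, detection_p = detection_p, M = M, U = U,
                 samples = samples), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("beta_matrix:", nrow(x$beta), "probes x", ncol(x$beta), "samples",
      if (is.null(x$detection_p)) "(no detection p-values)" else "", "\n")
  invisible(x)
}

#' Beta to M-value (logit2) transformation
#'
#' `M = log2(beta / (1 - beta))` after clamping beta to `[cap, 1 - cap]`
#' to avoid infinite M-values at the extremes.
#'
#' @param beta numeric vector/matrix in `[0, 1]`.
#' @param cap clamp bound (default 0.01).
#' @return M-values, same shape.
#' @export
beta_to_m <- function(beta, cap = 0.01) {
  b <- pmin(pmax(beta, cap), 1 - cap)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @param m M-values.
#' @return for `m_to_beta`: beta-values.
#' @export
m_to_beta <- function(m) 2^m / (1 + 2^m)

#' Histogram densities of beta-values per sample and probe subset
#'
#' Kernel-free histogram on a fixed beta grid, normalised so that
#' `sum(density) * binwidth = 1`.
#'
#' @param beta_matrix a `beta_matrix` (or plain beta matrix).
#' @param probe_subsets named list of probe-id vectors (default: all
#'   probes as one subset).
#' @param binwidth bin width on the beta scale (default 0.02).
#' @return long data.frame: `subset`, `sample`, `bin_mid`, `density`.
#' @export
distribution_summary <- function(beta_matrix, probe_subsets = NULL,
                                 binwidth = 0.02) {
  beta <- if (inherits(beta_matrix, "beta_matrix")) beta_matrix$beta else beta_matrix
  if (is.null(probe_subsets)) probe_subsets <- list(all = rownames(beta))
  breaks <- seq(0, 1, by = binwidth)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- list()
  for (nm in names(probe_subsets)) {
    ids <- intersect(probe_subsets[[nm]], rownames(beta))
    if (!length(ids)) {
      warning("probe subset '", nm, "' is empty")
      next
    }
    for (s in colnames(beta)) {
      v <- beta[ids, s]
      v <- v[!is.na(v)]
      bin <- pmin(pmax(ceiling(v / binwidth), 1L), length(mids))
      counts <- tabulate(bin, nbins = length(mids))
      out[[length(out) + 1L]] <- data.frame(
        subset = nm, sample = s, bin_mid = mids,
        density = counts / (length(v) * binwidth),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(subset = character(0), sample = character(0),
                      bin_mid = numeric(0), density = numeric(0)))
  }
  do.call(rbind, out)
}

#' Spearman correlation of beta-values between paired samples
#'
#' Shared probes are resolved by rowname; cells failing the detection
#' filter on either side are excluded pairwise; ranks use average-rank tie
#' handling.
#'
#' @param beta_a,beta_b `beta_matrix` objects.
#' @param pairing data.frame with `sample_a`, `sample_b`.
#' @param detection_threshold mask cells with detection p >= this when
#'   detection p-values are available (default 0.01).
#' @return named numeric vector of Spearman rho per pair.
#' @export
platform_correlation <- function(beta_a, beta_b, pairing,
                                 detection_threshold = 0.01) {
  shared <- intersect(rownames(beta_a$beta), rownames(beta_b$beta))
  if (length(shared) < 3L) stop_integrity("fewer than 3 shared probes")
  out <- numeric(nrow(pairing))
  names(out) <- paste(pairing$sample_a, pairing$sample_b, sep = "~")
  for (i in seq_len(nrow(pairing))) {
    va <- beta_a$beta[shared, pairing$sample_a[i]]
    vb <- beta_b$beta[shared, pairing$sample_b[i]]
    keep <- !is.na(va) & !is.na(vb)
    if (!is.null(beta_a$detection_p)) {
      keep <- keep & beta_a$detection_p[shared, pairing$sample_a[i]] < detection_threshold
    }
    if (!is.null(beta_b$detection_p)) {
      keep <- keep & beta_b$detection_p[shared, pairing$sample_b[i]] < detection_threshold
    }
    if (sum(keep) < 3L) {
      stop_integrity("fewer than 3 shared unmasked probes for pair ", names(out)[i])
    }
    out[i] <- cor(va[keep], vb[keep], method = "spearman")
  }
  out
}
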