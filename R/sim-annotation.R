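# Synthetic annotation tracks (gene models, DHS catalogs, enhancers) and the
# per-CpG methylation truth. The emulated biology: CpG islands are lowly
# methylated, open sea highly methylated, and a distal DNase hypersensitive
# site (DHS) is lowly methylated exactly in the cell types where it is
# present (open chromatin), highly methylated elsewhere -- the
# anti-correlation the real data shows.

place_nonoverlapping <- function(starts_pool, width, n, min_gap = 200L) {
  starts_pool <- sort(starts_pool)
  out <- integer(0)
  last_end <- -Inf
  for (s in starts_pool) {
    if (length(out) >= n) break
    if (s >= last_end + min_gap) {
      out <- c(out, s)
      last_end <- s + width
    }
  }
  out
}

#' Simulate annotation tracks over a synthetic genome
#'
#' @param genome a `sim_genome`.
#' @param config the [sim_config()].
#' @return `sim_annotation` list: `genes` (transcripts with TSS and strand),
#'   `islands`, `dhs_proximal`, `dhs_distal`, `enhancers` (all 0-based
#'   half-open data.frames with a `region_id`), `presence_distal` and
#'   `presence_proximal` (region x cell-type logical matrices) and
#'   `cell_types`.
#' @export
simulate_annotation <- function(genome, config) {
  set_stream(config$seed, "annotation")
  chroms <- names(genome$seq)
  lens <- genome$chrom_lengths

  # transcripts: round-robin over chromosomes, kept clear of the landing zone
  n_genes <- config$n_genes
  g_chrom <- chroms[((seq_len(n_genes) - 1L) %% length(chroms)) + 1L]
  genes <- do.call(rbind, lapply(chroms, function(chrom) {
    n <- sum(g_chrom == chrom)
    if (n == 0L) return(NULL)
    hi <- lens[[chrom]] - 8000L
    slot <- (hi - 3000L) %/% n
    st <- 3000L + (seq_len(n) - 1L) * slot +
      as.integer(round(runif(n, 0, max(0, slot - 7000L))))
    wd <- as.integer(round(runif(n, 2000, 5000)))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    data.frame(chrom = chrom, start = st, end = st + wd, strand = strand,
               tss = ifelse(strand == "+", st, st + wd - 1L),
               stringsAsFactors = FALSE)
  }))
  genes$transcript_id <- sprintf("tx%03d", seq_len(nrow(genes)))

  # proximal DHS: windows centred near TSSs
  n_prox <- min(config$n_dhs_proximal, nrow(genes))
  prox_idx <- sample.int(nrow(genes), n_prox)
  wd <- as.integer(round(runif(n_prox, 200, 400)))
  prox <- data.frame(chrom = genes$chrom[prox_idx],
                     start = pmax(0L, genes$tss[prox_idx] - wd %/% 2L),
                     stringsAsFactors = FALSE)
  prox$end <- prox$start + wd
  prox$region_id <- sprintf("dhsP%03d", seq_len(n_prox))

  # distal DHS: anchored on runs of >= 3 background CpGs, far from any TSS
  cpg <- genome$cpg
  in_island <- rep(FALSE, nrow(cpg))
  for (r in seq_len(nrow(genome$islands))) {
    isl <- genome$islands[r, ]
    in_island <- in_island | (cpg$chrom == isl$chrom &
                                cpg$pos >= isl$start & cpg$pos < isl$end)
  }
  distal <- NULL
  per_chrom_n <- table(factor(
    chroms[((seq_len(config$n_dhs_distal) - 1L) %% length(chroms)) + 1L],
    levels = chroms))
  for (chrom in chroms) {
    n_want <- per_chrom_n[[chrom]]
    if (n_want == 0L) next
    pos <- cpg$pos[cpg$chrom == chrom & !in_island]
    tss <- genes$tss[genes$chrom == chrom]
    zone <- genome$dup_zone[genome$dup_zone$chrom == chrom, ]
    # candidate anchors: CpG triples within 400 bp, distal to every TSS
    ok <- logical(0)
    anchors <- integer(0)
    if (length(pos) >= 3L) {
      for (i in seq_len(length(pos) - 2L)) {
        span <- pos[i + 2L] - pos[i]
        if (span > 360L) next
        mid <- pos[i] + span %/% 2L
        if (length(tss) && min(abs(mid - tss)) < 2500L) next
        if (mid >= zone$start - 500L) next
        anchors <- c(anchors, i)
      }
    }
    anchors <- anchors[sample.int(length(anchors))]
    sel <- integer(0)
    last <- -Inf
    for (i in sort(anchors)) {
      if (length(sel) >= n_want) break
      st <- pos[i] - 20L
      if (st < last + 600L) next
      sel <- c(sel, i)
      last <- st
    }
    if (length(sel) < n_want) {
      stop_config("could not place ", n_want, " distal DHS on ", chrom)
    }
    distal <- rbind(distal, data.frame(
      chrom = chrom, start = pos[sel] - 20L, end = pos[sel + 2L] + 22L,
      stringsAsFactors = FALSE))
  }
  distal <- distal[order(distal$chrom, distal$start), ]
  distal$region_id <- sprintf("dhsD%03d", seq_len(nrow(distal)))

  # enhancers: a subset of distal DHS plus independent windows
  n_enh <- config$n_enhancers
  enh_src <- distal[sample.int(nrow(distal), min(n_enh, nrow(distal))), ]
  enh <- data.frame(chrom = enh_src$chrom,
                    start = pmax(0L, enh_src$start - 100L),
                    end = enh_src$end + 100L, stringsAsFactors = FALSE)
  enh$region_id <- sprintf("enh%03d", seq_len(nrow(enh)))

  # per-cell-type presence: region-specific commonness drives occurrence
  presence <- function(regions) {
    common <- stats::rbeta(nrow(regions), 2, 2)
    m <- matrix(runif(nrow(regions) * config$n_cell_types) < common,
                nrow = nrow(regions))
    rownames(m) <- regions$region_id
    colnames(m) <- paste0("cell", seq_len(config$n_cell_types))
    m
  }
  structure(list(genes = genes, islands = genome$islands,
                 dhs_proximal = prox, dhs_distal = distal, enhancers = enh,
                 presence_distal = presence(distal),
                 presence_proximal = presence(prox),
                 cell_types = paste0("cell", seq_len(config$n_cell_types))),
            class = "sim_annotation")
}

#' Simulate the per-CpG methylation truth
#'
#' Baseline: island CpGs lowly methylated (0.02-0.15), open sea highly
#' methylated (0.70-0.95). Per cell type, CpGs inside a distal DHS are set
#' low when the DHS is present in that cell type (open chromatin) and high
#' otherwise.
#'
#' @param genome a `sim_genome`.
#' @param annotation a `sim_annotation`.
#' @param config the [sim_config()].
#' @return list with `cpg` (chrom, pos, `base_m`) and `cell_m` (CpG x
#'   cell-type matrix of true methylation).
#' @export
simulate_methylation_truth <- function(genome, annotation, config) {
  set_stream(config$seed, "truth")
  cpg <- genome$cpg
  in_island <- rep(FALSE, nrow(cpg))
  for (r in seq_len(nrow(genome$islands))) {
    isl <- genome$islands[r, ]
    in_island <- in_island | (cpg$chrom == isl$chrom &
                                cpg$pos >= isl$start & cpg$pos < isl$end)
  }
  base_m <- ifelse(in_island, runif(nrow(cpg), 0.02, 0.15),
                   runif(nrow(cpg), 0.70, 0.95))
  cell_m <- matrix(rep(base_m, config$n_cell_types), ncol = config$n_cell_types)
  colnames(cell_m) <- annotation$cell_types
  dd <- annotation$dhs_distal
  pres <- annotation$presence_distal
  for (r in seq_len(nrow(dd))) {
    idx <- which(cpg$chrom == dd$chrom[r] & cpg$pos >= dd$start[r] &
                   cpg$pos < dd$end[r])
    if (!length(idx)) next
    lo <- runif(1, 0.02, 0.20)
    hi <- runif(1, 0.70, 0.95)
    for (ct in seq_len(ncol(cell_m))) {
      cell_m[idx, ct] <- if (pres[dd$region_id[r], ct]) lo else hi
    }
  }
  list(cpg = data.frame(chrom = cpg$chrom, pos = cpg$pos, base_m = base_m,
                        stringsAsFactors = FALSE),
       cell_m = cell_m)
}
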