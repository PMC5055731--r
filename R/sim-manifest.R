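# Synthetic manifest generator. Probe sequences are read off the in-silico
# converted genomes (see convert.R for the orientation convention), Type I
# probes carry separate unmethylated/methylated allele sequences, Type II a
# single sequence with degenerate R at every CpG read-out. Probes placed on
# the anchor CpG of a planted duplication are the ground-truth
# cross-reactive set.

eligible_strands <- function(pos, chrom_len) {
  plus_ok <- pos >= 1L & (pos + 50L) <= chrom_len
  minus_ok <- (pos - 48L) >= 0L & (pos + 3L) <= chrom_len
  list(plus = plus_ok, minus = minus_ok)
}

#' Simulate an array manifest over a synthetic genome
#'
#' Emits `n_probes_type1` + `n_probes_type2` CpG (cg) probes -- Type I
#' preferentially inside CpG islands, mirroring real designs -- plus a few
#' CNG (ch) and SNP (rs) probes that are carried through I/O but excluded
#' from CpG-specific analyses. One probe is placed on the anchor CpG of each
#' planted duplication (design strand +), forming the ground-truth
#' cross-reactive set.
#'
#' @param genome a `sim_genome`.
#' @param config the [sim_config()] used to build it.
#' @return list with `manifest` (an `epicqc_manifest`) and `ground_truth`
#'   (`planted_crossreactive_probe_ids`, and the duplication anchor map).
#' @export
simulate_manifest <- function(genome, config) {
  set_stream(config$seed, "manifest")
  cpg <- genome$cpg
  # exclude CpGs inside the duplication landing zones (repeat copies)
  in_zone <- rep(FALSE, nrow(cpg))
  for (r in seq_len(nrow(genome$dup_zone))) {
    z <- genome$dup_zone[r, ]
    in_zone <- in_zone | (cpg$chrom == z$chrom & cpg$pos >= z$start & cpg$pos < z$end)
  }
  cpg <- cpg[!in_zone, ]

  in_island <- rep(FALSE, nrow(cpg))
  for (r in seq_len(nrow(genome$islands))) {
    isl <- genome$islands[r, ]
    in_island <- in_island | (cpg$chrom == isl$chrom &
                                cpg$pos >= isl$start & cpg$pos < isl$end)
  }

  dup <- genome$duplications
  n_dup <- nrow(dup)
  dup_type <- if (n_dup) rep(c("I", "II"), length.out = n_dup) else character(0)
  n1_rest <- config$n_probes_type1 - sum(dup_type == "I")
  n2_rest <- config$n_probes_type2 - sum(dup_type == "II")
  if (n1_rest < 0L || n2_rest < 0L) {
    stop_config("probe counts smaller than the planted duplication count")
  }

  is_anchor <- paste(cpg$chrom, cpg$pos) %in%
    (if (n_dup) paste(dup$chrom, dup$anchor_cpg) else character(0))
  pool <- cpg[!is_anchor, ]
  pool_island <- in_island[!is_anchor]
  len <- genome$chrom_lengths[pool$chrom]
  elig <- eligible_strands(pool$pos, len)
  ok <- elig$plus | elig$minus
  pool <- pool[ok, ]
  pool_island <- pool_island[ok]
  elig <- lapply(elig, `[`, ok)

  pick <- function(from_island, n) {
    idx <- which(pool_island == from_island & !pool$used)
    if (length(idx) < n) idx <- c(idx, which(!pool$used & pool_island != from_island))
    if (length(idx) < n) {
      stop_config("not enough CpGs for the requested probe counts (need ", n,
                  ", have ", length(idx), ")")
    }
    sel <- idx[sample.int(length(idx), n)]
    pool$used[sel] <<- TRUE
    sel
  }
  pool$used <- FALSE
  idx1 <- pick(TRUE, n1_rest)    # Type I: island-biased
  idx2 <- pick(FALSE, n2_rest)   # Type II: open-sea biased

  rows <- rbind(
    if (n_dup) data.frame(chrom = dup$chrom, pos = dup$anchor_cpg,
                          type = dup_type, strand = "+", planted = TRUE),
    data.frame(chrom = pool$chrom[idx1], pos = pool$pos[idx1], type = "I",
               strand = NA_character_, planted = FALSE),
    data.frame(chrom = pool$chrom[idx2], pos = pool$pos[idx2], type = "II",
               strand = NA_character_, planted = FALSE)
  )
  # random design strand among the eligible ones
  need <- which(is.na(rows$strand))
  el <- eligible_strands(rows$pos[need], genome$chrom_lengths[rows$chrom[need]])
  draw <- runif(length(need)) < 0.5
  rows$strand[need] <- ifelse(el$plus & el$minus, ifelse(draw, "+", "-"),
                              ifelse(el$plus, "+", "-"))

  rows <- rows[order(rows$chrom, rows$pos), ]
  rows$probe_id <- sprintf("cg%07d", seq_len(nrow(rows)))

  # a few CNG (ch) and SNP (rs) probes, Type II design on the plus strand
  extra <- sim_noncpg_probes(genome, n_ch = 3L, n_rs = 2L)
  probes <- data.frame(
    probe_id = c(rows$probe_id, extra$probe_id),
    infinium_type = c(rows$type, extra$infinium_type),
    chrom = c(rows$chrom, extra$chrom),
    target_pos = c(rows$pos, extra$target_pos),
    strand = c(rows$strand, extra$strand),
    stringsAsFactors = FALSE)
  probes <- cbind(probes, compute_footprint(probes$infinium_type,
                                            probes$target_pos, probes$strand,
                                            genome$chrom_lengths, probes$chrom))
  probes$sequence_u <- NA_character_
  probes$sequence_m <- ""
  for (i in seq_len(nrow(probes))) {
    chromseq <- genome$seq[[probes$chrom[i]]]
    if (probes$infinium_type[i] == "I") {
      probes$sequence_u[i] <- probe_sequence_from_genome(
        chromseq, probes$fp_start[i], probes$fp_end[i], probes$strand[i], "u")
      probes$sequence_m[i] <- probe_sequence_from_genome(
        chromseq, probes$fp_start[i], probes$fp_end[i], probes$strand[i], "m")
    } else {
      probes$sequence_u[i] <- probe_sequence_from_genome(
        chromseq, probes$fp_start[i], probes$fp_end[i], probes$strand[i], "both")
    }
  }
  probes <- probes[, c("probe_id", "infinium_type", "chrom", "target_pos",
                       "strand", "sequence_u", "sequence_m", "fp_start",
                       "fp_end", "sbe_pos", "body_start", "body_end")]
  manifest <- new_manifest(probes, "synthetic")
  planted <- rows$probe_id[rows$planted]
  list(manifest = manifest,
       ground_truth = list(
         planted_crossreactive_probe_ids = planted,
         duplication_map = if (n_dup) cbind(dup, probe_id = planted) else NULL))
}

# non-CpG cytosines (ch) and arbitrary loci (rs) for the minor probe classes
sim_noncpg_probes <- function(genome, n_ch, n_rs) {
  chrom <- names(genome$seq)[1]
  s <- genome$seq[[chrom]]
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  len <- length(ch)
  is_c <- which(ch == "C")
  is_c <- is_c[is_c < len - 60 & is_c > 2]
  nonCpG <- is_c[ch[is_c + 1L] != "G"] - 1L   # 0-based
  # keep out of the duplication landing zone
  z <- genome$dup_zone[genome$dup_zone$chrom == chrom, ]
  nonCpG <- nonCpG[nonCpG < z$start - 60L]
  sel <- nonCpG[sample.int(length(nonCpG), n_ch + n_rs)]
  data.frame(
    probe_id = c(sprintf("ch%07d", seq_len(n_ch)), sprintf("rs%07d", seq_len(n_rs))),
    infinium_type = "II", chrom = chrom, target_pos = sel[seq_len(n_ch + n_rs)],
    strand = "+", stringsAsFactors = FALSE)
}
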