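# Synthetic genome generator. Every CpG in the emitted genome is planted
# deliberately: the raw base draw is scrubbed of accidental CG dinucleotides,
# then CpGs are inserted at sampled positions (dense inside islands, sparse
# outside), so CpG ground truth is exact by construction. Cross-hybridising
# duplications copy a probe-sized window (footprint plus one flanking base on
# each side, so bisulphite conversion context is preserved) into a reserved
# landing zone, with A<->T substitutions providing mismatches that survive
# conversion in all four in-silico genomes and can neither create nor destroy
# a CpG.

# sample CpG start positions in [start, end) with expected rate `rate` per bp
# and a minimum gap of 2 (CpGs occupy two bases)
sample_cpg_positions <- function(start, end, rate) {
  if (rate <= 0 || end - start < 2L) return(integer(0))
  p <- rate / (1 - rate)          # E[2 + geom(p)] = 1/rate
  pos <- integer(0)
  cur <- start + stats::rgeom(1L, p)
  while (cur <= end - 2L) {
    pos <- c(pos, cur)
    cur <- cur + 2L + stats::rgeom(1L, p)
  }
  pos
}

scan_cpg_positions <- function(seqs) {
  out <- lapply(names(seqs), function(chrom) {
    m <- gregexpr("CG", seqs[[chrom]], fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(chrom = chrom, pos = as.integer(m) - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), pos = integer(0))
  }
  out
}

#' Simulate a genome with CpG islands and planted cross-hybridising
#' duplications
#'
#' @param config a [sim_config()].
#' @return object of class `sim_genome`: chromosome sequences, exact CpG
#'   positions, island intervals, planted duplication records and the
#'   reserved duplication landing zones. All coordinates 0-based half-open.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set_stream(config$seed, "genome")
  per_chrom <- config$genome_length_bp %/% config$n_chromosomes
  chroms <- paste0("chr", seq_len(config$n_chromosomes))

  # island layout: round-robin across chromosomes, even slots with jitter
  island_chrom <- chroms[((seq_len(config$n_islands) - 1L) %% config$n_chromosomes) + 1L]
  dup_zone <- data.frame(chrom = chroms,
                         start = per_chrom - 3500L,
                         end = per_chrom - 500L,
                         stringsAsFactors = FALSE)

  islands <- NULL
  seqs <- list()
  cpg_planted <- list()
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    n_isl <- sum(island_chrom == chrom)
    usable_lo <- 2000L
    usable_hi <- per_chrom - 6000L
    isl <- NULL
    if (n_isl > 0L) {
      slot <- (usable_hi - usable_lo) %/% n_isl
      if (slot < 600L || (n_isl > 1L && slot < 4600L)) {
        stop_config("island layout infeasible on ", chrom)
      }
      len <- as.integer(round(runif(n_isl, 250, 600)))
      off <- as.integer(round(runif(n_isl, 0, max(0L, slot - 4600L))))
      st <- usable_lo + (seq_len(n_isl) - 1L) * slot + off
      isl <- data.frame(chrom = chrom, start = st, end = st + len,
                        stringsAsFactors = FALSE)
    }

    # raw bases, then remove accidental CG dinucleotides
    ch <- sample(c("A", "C", "G", "T"), per_chrom, replace = TRUE)
    hit <- which(ch[-per_chrom] == "C" & ch[-1L] == "G")
    if (length(hit)) ch[hit + 1L] <- "A"

    # plant CpGs: island-rate inside islands, background elsewhere
    pos <- integer(0)
    bounds <- c(0L, if (!is.null(isl)) as.vector(t(as.matrix(isl[, c("start", "end")]))), per_chrom)
    for (k in seq_len(length(bounds) - 1L)) {
      lo <- bounds[k]; hi <- bounds[k + 1L]
      inside <- !is.null(isl) && k %% 2L == 0L
      rate <- if (inside) config$island_cpg_rate else config$background_cpg_rate
      pos <- c(pos, sample_cpg_positions(lo, hi, rate))
    }
    ch[pos + 1L] <- "C"
    ch[pos + 2L] <- "G"
    seqs[[chrom]] <- ch
    cpg_planted[[chrom]] <- sort(pos)
    islands <- rbind(islands, isl)
  }

  # planted duplications: copy footprint windows of background CpGs into the
  # landing zone of the same chromosome, at the requested identity
  n_mm <- 50L - as.integer(round(config$duplication_identity * 50))
  dup <- NULL
  if (config$n_duplicated_segments > 0L) {
    dup_chrom <- chroms[((seq_len(config$n_duplicated_segments) - 1L) %% config$n_chromosomes) + 1L]
    for (ci in seq_along(chroms)) {
      chrom <- chroms[ci]
      n_dup <- sum(dup_chrom == chrom)
      if (n_dup == 0L) next
      zone <- dup_zone[dup_zone$chrom == chrom, ]
      if (zone$end - zone$start < n_dup * 70L + 10L) {
        stop_config("duplication landing zone too small on ", chrom)
      }
      ch <- seqs[[chrom]]
      pos <- cpg_planted[[chrom]]
      in_island <- rep(FALSE, length(pos))
      isl <- islands[islands$chrom == chrom, ]
      for (r in seq_len(nrow(isl))) {
        in_island <- in_island | (pos >= isl$start[r] & pos < isl$end[r])
      }
      cand <- pos[!in_island & pos >= 1L & (pos + 51L) < zone$start]
      cand <- cand[sample.int(length(cand))]
      placed <- 0L
      used <- integer(0)
      for (anchor in cand) {
        if (placed >= n_dup) break
        if (length(used) && min(abs(anchor - used)) < 120L) next
        win <- ch[(anchor - 1L + 1L):(anchor + 51L)]     # 52 bases, 1-based idx
        at <- which(win %in% c("A", "T"))
        at <- at[at >= 2L & at <= 51L]                   # interior = footprint
        if (length(at) < n_mm) next
        copy <- win
        if (n_mm > 0L) {
          swap <- at[sample.int(length(at), n_mm)]
          copy[swap] <- chartr("AT", "TA", copy[swap])
        }
        dst <- zone$start + placed * 70L + 5L
        ch[(dst + 1L):(dst + 52L)] <- copy
        ch[dst] <- "T"                                   # junction guards
        ch[dst + 53L] <- "A"
        dup <- rbind(dup, data.frame(
          chrom = chrom, anchor_cpg = anchor,
          src_start = anchor, src_end = anchor + 50L,
          dst_start = dst + 1L, dst_end = dst + 51L,
          n_mismatches = n_mm, stringsAsFactors = FALSE))
        used <- c(used, anchor)
        placed <- placed + 1L
      }
      if (placed < n_dup) {
        stop_config("could not place ", n_dup, " duplications on ", chrom,
                    ": too few eligible background CpGs")
      }
      seqs[[chrom]] <- ch
    }
  }

  seqs <- vapply(seqs, paste, character(1), collapse = "")
  genome <- structure(list(
    seq = seqs,
    chrom_lengths = vapply(seqs, nchar, integer(1)),
    cpg = scan_cpg_positions(seqs),
    islands = islands,
    duplications = dup %||% data.frame(),
    dup_zone = dup_zone,
    config = config
  ), class = "sim_genome")
  genome
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("sim_genome:", length(x$seq), "chromosome(s),", sum(x$chrom_lengths),
      "bp,", nrow(x$cpg), "CpGs,", nrow(x$islands), "islands,",
      nrow(x$duplications), "planted duplications\n")
  invisible(x)
}

#' Write a simulated genome as FASTA
#' @param genome a `sim_genome`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write CpG positions as BED (0-based half-open, width 2)
#' @param genome a `sim_genome`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_cpg_bed <- function(genome, path) {
  df <- data.frame(chrom = genome$cpg$chrom, start = genome$cpg$pos,
                   end = genome$cpg$pos + 2L)
  write_bed(df, path)
}
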