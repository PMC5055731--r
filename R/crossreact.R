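# Cross-reactive probe detection.
#
# The alignment of 50-base probe sequences to the four in-silico bisulphite
# genomes is an exact-k-mer seed + ungapped extension scan (a deterministic
# stand-in for BLAT). With non-overlapping seeds of length k the scan is
# provably complete for hits with at most floor(50/k) - 1 mismatches: the
# default k = 12 gives four seeds, so every hit with >= 47 matching bases is
# found (pigeonhole: three mismatches cannot touch all four seeds). Hits
# below that homology are reported best-effort. A brute-force all-window
# scanner with identical scoring is exposed as the independent oracle.
#
# Scoring: positional base identity; degenerate R in a probe matches A or G
# (the purine read-out of a converted CpG); genome N never matches; gapped
# alignment is out of scope (homology = matched bases of the 50).

#' Scan query sequences against converted genomes
#'
#' Low-level scanner. Each query is compared positionally against every
#' window of every genome variant in both orientations: `"fwd"` (query as
#' stored) and `"rev"` (reverse complement of the query, where R becomes Y,
#' matching C or T).
#'
#' @param sequences named character vector of probe sequences (A/C/G/T/R).
#' @param genomes a `converted_genomes` object from
#'   [build_converted_genomes()].
#' @param min_count report windows with at least this many matching bases
#'   (default 40; completeness only guaranteed down to `51 - floor(50/k)`,
#'   i.e. 47 for the default `k`).
#' @param method `"seeded"` (seed-and-extend, default) or `"brute"`
#'   (all-window oracle).
#' @param k seed length for the seeded method.
#' @return data.frame with `query`, `genome_id`, `chrom`, `start` (0-based),
#'   `orientation`, `match_count`.
#' @export
scan_sequences <- function(sequences, genomes, min_count = 40L,
                           method = c("seeded", "brute"), k = 12L) {
  method <- match.arg(method)
  stopifnot(inherits(genomes, "converted_genomes"))
  if (length(sequences) == 0L) {
    return(data.frame(query = character(0), genome_id = character(0),
                      chrom = character(0), start = integer(0),
                      orientation = character(0), match_count = integer(0)))
  }
  if (any(nchar(sequences) != 50L)) {
    stop_integrity("all probe sequences must be exactly 50 bases")
  }
  qnames <- names(sequences) %||% as.character(seq_along(sequences))
  queries <- list(fwd = unname(sequences), rev = unname(revcomp(sequences)))
  scan_fun <- function(qs, gseq) {
    if (method == "seeded") .cpp_scan_seeded(qs, gseq, as.integer(min_count), as.integer(k))
    else .cpp_scan_brute(qs, gseq, as.integer(min_count))
  }
  out <- list()
  for (gid in names(genomes$genomes)) {
    gset <- genomes$genomes[[gid]]
    for (chrom in names(gset)) {
      for (ori in c("fwd", "rev")) {
        res <- scan_fun(queries[[ori]], gset[[chrom]])
        for (qi in seq_along(res)) {
          st <- res[[qi]]$start
          if (length(st) == 0L) next
          out[[length(out) + 1L]] <- data.frame(
            query = qnames[qi], genome_id = gid, chrom = chrom,
            start = st, orientation = ori,
            match_count = res[[qi]]$count, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(query = character(0), genome_id = character(0),
                      chrom = character(0), start = integer(0),
                      orientation = character(0), match_count = integer(0)))
  }
  do.call(rbind, out)
}

probe_queries <- function(probes) {
  seqs <- probes$sequence_u
  names(seqs) <- paste0(probes$probe_id, "|u")
  m <- probes$infinium_type == "I"
  if (any(m)) {
    sm <- probes$sequence_m[m]
    names(sm) <- paste0(probes$probe_id[m], "|m")
    seqs <- c(seqs, sm)
  }
  seqs
}

annotate_hits <- function(hits, probes) {
  if (nrow(hits) == 0L) {
    hits$probe_id <- character(0)
    hits$allele <- character(0)
    hits$is_target <- logical(0)
    return(hits)
  }
  parts <- strsplit(hits$query, "|", fixed = TRUE)
  hits$probe_id <- vapply(parts, `[`, character(1), 1L)
  hits$allele <- vapply(parts, `[`, character(1), 2L)
  i <- match(hits$probe_id, probes$probe_id)
  design_ori <- ifelse(probes$strand[i] == "+", "fwd", "rev")
  hits$is_target <- hits$orientation == design_ori &
    hits$chrom == probes$chrom[i] &
    hits$start < probes$fp_end[i] & (hits$start + 50L) > probes$fp_start[i]
  hits
}

#' Scan one probe against the converted genomes
#'
#' @param probe a single row of `manifest$probes` (both allele sequences are
#'   scanned for Type I probes).
#' @param genomes a `converted_genomes`.
#' @inheritParams scan_sequences
#' @return data.frame of alignment hits with `probe_id`, `allele`,
#'   `genome_id`, `chrom`, `start`, `orientation`, `match_count`,
#'   `is_target` (hit overlaps the annotated footprint in the design
#'   orientation).
#' @export
scan_probe <- function(probe, genomes, min_count = 40L,
                       method = c("seeded", "brute"), k = 12L) {
  stopifnot(is.data.frame(probe), nrow(probe) == 1L)
  hits <- scan_sequences(probe_queries(probe), genomes, min_count, method, k)
  annotate_hits(hits, probe)
}

#' Scan every probe of a manifest
#'
#' @param manifest an `epicqc_manifest`.
#' @inheritParams scan_probe
#' @param include_noncpg also scan ch/rs probes (default FALSE).
#' @return data.frame as in [scan_probe()].
#' @export
scan_manifest <- function(manifest, genomes, min_count = 40L,
                          method = c("seeded", "brute"), k = 12L,
                          include_noncpg = FALSE) {
  probes <- manifest$probes
  if (!include_noncpg) probes <- probes[probes$probe_class == "cg", ]
  hits <- scan_sequences(probe_queries(probes), genomes, min_count, method, k)
  annotate_hits(hits, probes)
}

#' Call cross-reactive probes
#'
#' A probe is flagged when any of its allele sequences has an off-target hit
#' (a window not overlapping the annotated footprint in the design
#' orientation) with at least `threshold` matching bases. `tie` marks
#' probes whose best off-target homology is attained in more than one
#' in-silico genome.
#'
#' @param manifest an `epicqc_manifest`.
#' @param genomes a `converted_genomes`.
#' @param threshold minimum matched bases of 50 (default 47).
#' @inheritParams scan_manifest
#' @return data.frame sorted by `probe_id`: one row per scanned probe with
#'   `flagged`, `n_offtarget_hits`, best off-target locus
#'   (`best_genome_id`, `best_chrom`, `best_start`, `best_match_count`) and
#'   `tie`.
#' @export
call_crossreactive <- function(manifest, genomes, threshold = 47L,
                               method = c("seeded", "brute"), k = 12L,
                               include_noncpg = FALSE) {
  probes <- manifest$probes
  if (!include_noncpg) probes <- probes[probes$probe_class == "cg", ]
  out <- data.frame(probe_id = sort(probes$probe_id),
                    flagged = FALSE, n_offtarget_hits = 0L,
                    best_genome_id = NA_character_,
                    best_chrom = NA_character_, best_start = NA_integer_,
                    best_match_count = NA_integer_, tie = FALSE,
                    stringsAsFactors = FALSE)
  if (threshold > 50L) return(out)
  hits <- scan_manifest(manifest, genomes, min_count = threshold,
                        method = method, k = k,
                        include_noncpg = include_noncpg)
  off <- hits[!hits$is_target & hits$match_count >= threshold, , drop = FALSE]
  if (nrow(off)) {
    # a window may be hit by both allele sequences or both orientations;
    # count distinct off-target loci per probe
    key <- paste(off$probe_id, off$genome_id, off$chrom, off$start, off$orientation)
    off <- off[!duplicated(key), , drop = FALSE]
    sp <- split(off, off$probe_id)
    for (pid in names(sp)) {
      h <- sp[[pid]]
      best <- max(h$match_count)
      hb <- h[h$match_count == best, , drop = FALSE]
      hb <- hb[order(hb$genome_id, hb$chrom, hb$start), , drop = FALSE]
      i <- match(pid, out$probe_id)
      out$flagged[i] <- TRUE
      out$n_offtarget_hits[i] <- nrow(h)
      out$best_genome_id[i] <- hb$genome_id[1]
      out$best_chrom[i] <- hb$chrom[1]
      out$best_start[i] <- hb$start[1]
      out$best_match_count[i] <- best
      out$tie[i] <- length(unique(hb$genome_id)) > 1L
    }
  }
  out
}

#' Precision/recall of cross-reactivity calls against a reference list
#'
#' Pairs are matched on `(probe_id, chrom, start)` with a positional
#' tolerance.
#'
#' @param calls data.frame with `probe_id`, `chrom`, `start` (called
#'   off-target loci).
#' @param reference data.frame with the same columns (reference pairs).
#' @param tolerance allowed |start difference| for a match (default 0).
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
validate_against_reference <- function(calls, reference, tolerance = 0L) {
  if (is.null(reference) || nrow(reference) == 0L) {
    stop_integrity("reference list is empty")
  }
  match_one <- function(df, other) {
    vapply(seq_len(nrow(df)), function(i) {
      any(other$probe_id == df$probe_id[i] &
            other$chrom == df$chrom[i] &
            abs(other$start - df$start[i]) <= tolerance)
    }, logical(1))
  }
  ref_hit <- if (nrow(calls)) match_one(reference, calls) else rep(FALSE, nrow(reference))
  call_hit <- if (nrow(calls)) match_one(calls, reference) else logical(0)
  tp <- sum(ref_hit)
  fp <- sum(!call_hit)
  fn <- sum(!ref_hit)
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = tp / (tp + fn))
}
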