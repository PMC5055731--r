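# Genomic/CpG-context annotation and regulatory coverage accounting.
#
# Derived track definitions: promoters are TSS +/- 2 kb; gene bodies are
# transcripts with 2 kb flanks minus promoters; intergenic is the
# complement, so the three gene contexts partition the genome. Island
# shores are the 2 kb island flanks minus any island overlap. A region
# counts as "covered" when at least one probe's assayed CpG position (not
# its footprint) falls inside it.

clip_regions <- function(df, chrom_lengths, what) {
  len <- chrom_lengths[df$chrom]
  bad <- df$start < 0L | df$end > len
  if (any(bad, na.rm = TRUE)) {
    warning(sum(bad, na.rm = TRUE), " ", what,
            " region(s) extended beyond chromosome bounds; clipped")
  }
  df$start <- pmax(df$start, 0L)
  df$end <- pmin(df$end, len)
  df[df$end > df$start, , drop = FALSE]
}

reduce_ivs <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  gr_to_ivs(GenomicRanges::reduce(ivs_to_gr(df)))
}

setdiff_ivs <- function(a, b) {
  if (nrow(a) == 0L) return(a[, c("chrom", "start", "end")])
  if (nrow(b) == 0L) return(reduce_ivs(a))
  gr_to_ivs(GenomicRanges::setdiff(ivs_to_gr(a), ivs_to_gr(b)))
}

complement_ivs <- function(dfs, chrom_lengths) {
  covered <- do.call(rbind, lapply(dfs, function(d) d[, c("chrom", "start", "end")]))
  out <- NULL
  for (chrom in names(chrom_lengths)) {
    len <- chrom_lengths[[chrom]]
    cc <- covered[covered$chrom == chrom, , drop = FALSE]
    if (nrow(cc) == 0L) {
      out <- rbind(out, data.frame(chrom = chrom, start = 0L, end = len))
      next
    }
    cc <- reduce_ivs(cc)
    cc <- cc[order(cc$start), ]
    gaps_start <- c(0L, cc$end)
    gaps_end <- c(cc$start, len)
    keep <- gaps_end > gaps_start
    if (any(keep)) {
      out <- rbind(out, data.frame(chrom = chrom, start = gaps_start[keep],
                                   end = gaps_end[keep]))
    }
  }
  out %||% data.frame(chrom = character(0), start = integer(0), end = integer(0))
}

#' Build the annotation bundle with derived tracks
#'
#' @param genes data.frame of transcripts: `chrom`, `start`, `end`,
#'   `strand`, `tss` (0-based position). Promoters are derived from every
#'   transcript TSS.
#' @param islands CpG island intervals (`chrom`, `start`, `end`).
#' @param dhs_proximal,dhs_distal,enhancers regulatory catalogs with a
#'   `region_id` column.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param presence_distal,presence_proximal optional region x cell-type
#'   logical matrices (rownames = region ids).
#' @param flank promoter/shore/body flank size in bp (default 2000).
#' @return `annotation_bundle` list with the input catalogs plus derived
#'   `promoters`, `gene_bodies`, `intergenic`, `shores` tracks (0-based
#'   half-open, merged).
#' @export
build_annotation <- function(genes, islands, dhs_proximal, dhs_distal,
                             enhancers, chrom_lengths,
                             presence_distal = NULL, presence_proximal = NULL,
                             flank = 2000L) {
  islands <- clip_regions(islands, chrom_lengths, "island")
  promoters <- data.frame(chrom = genes$chrom, start = genes$tss - flank,
                          end = genes$tss + flank)
  promoters <- reduce_ivs(clip_regions(promoters, chrom_lengths, "promoter"))
  bodies_raw <- data.frame(chrom = genes$chrom, start = genes$start - flank,
                           end = genes$end + flank)
  bodies_raw <- reduce_ivs(clip_regions(bodies_raw, chrom_lengths, "gene body"))
  gene_bodies <- setdiff_ivs(bodies_raw, promoters)
  intergenic <- complement_ivs(list(promoters, gene_bodies), chrom_lengths)

  shore_raw <- data.frame(chrom = islands$chrom,
                          start = islands$start - flank,
                          end = islands$end + flank)
  shore_raw <- reduce_ivs(clip_regions(shore_raw, chrom_lengths, "shore"))
  shores <- setdiff_ivs(shore_raw, islands)

  structure(list(genes = genes, islands = islands,
                 promoters = promoters, gene_bodies = gene_bodies,
                 intergenic = intergenic, shores = shores,
                 dhs_proximal = dhs_proximal, dhs_distal = dhs_distal,
                 enhancers = enhancers,
                 presence_distal = presence_distal,
                 presence_proximal = presence_proximal,
                 chrom_lengths = chrom_lengths),
            class = "annotation_bundle")
}

point_in <- function(chrom, pos, df) {
  if (is.null(df) || nrow(df) == 0L) return(rep(FALSE, length(pos)))
  suppressWarnings(
    GenomicRanges::countOverlaps(points_to_gr(chrom, pos), ivs_to_gr(df)) > 0L)
}

#' Assign each probe its genomic, CpG and regulatory context
#'
#' Gene context uses precedence promoter > gene body > intergenic; CpG
#' context uses island > shore > open sea; regulatory memberships (DHS
#' proximal/distal, enhancer) are independent logicals. Contexts are
#' assigned from the probe's assayed CpG position.
#'
#' @param manifest an `epicqc_manifest`.
#' @param bundle an `annotation_bundle`.
#' @param include_noncpg include ch/rs probes (default FALSE).
#' @return data.frame: `probe_id`, `gene_context`, `cpg_context`,
#'   `dhs_proximal`, `dhs_distal`, `enhancer`.
#' @export
assign_probe_categories <- function(manifest, bundle, include_noncpg = FALSE) {
  probes <- manifest$probes
  if (!include_noncpg) probes <- probes[probes$probe_class == "cg", ]
  known <- probes$chrom %in% names(bundle$chrom_lengths)
  if (!all(known)) {
    warning(sum(!known), " probe(s) on chromosomes absent from the bundle; unassigned")
  }
  chrom <- probes$chrom
  pos <- probes$target_pos
  gene_context <- ifelse(point_in(chrom, pos, bundle$promoters), "promoter",
                         ifelse(point_in(chrom, pos, bundle$gene_bodies),
                                "gene_body", "intergenic"))
  cpg_context <- ifelse(point_in(chrom, pos, bundle$islands), "island",
                        ifelse(point_in(chrom, pos, bundle$shores),
                               "shore", "open_sea"))
  gene_context[!known] <- NA_character_
  cpg_context[!known] <- NA_character_
  data.frame(probe_id = probes$probe_id,
             gene_context = gene_context, cpg_context = cpg_context,
             dhs_proximal = point_in(chrom, pos, bundle$dhs_proximal),
             dhs_distal = point_in(chrom, pos, bundle$dhs_distal),
             enhancer = point_in(chrom, pos, bundle$enhancers),
             stringsAsFactors = FALSE)
}

#' Stratified coverage of a region catalog
#'
#' Counts regions with >= 1, >= 2 and >= 3 overlapping positions (probe
#' target CpGs, or genomic CpG loci), by point-in-interval test.
#'
#' @param regions data.frame (`chrom`, `start`, `end`), one catalog.
#' @param positions data.frame (`chrom`, `pos`) of assayed/genomic CpGs.
#' @param catalog optional catalog label.
#' @return one-row data.frame: `catalog`, `n_regions`, `n_ge1`, `n_ge2`,
#'   `n_ge3`.
#' @export
coverage_stratified <- function(regions, positions, catalog = NA_character_) {
  counts <- count_points_in_ivs(regions, positions$chrom, positions$pos)
  data.frame(catalog = catalog, n_regions = nrow(regions),
             n_ge1 = sum(counts >= 1L), n_ge2 = sum(counts >= 2L),
             n_ge3 = sum(counts >= 3L), stringsAsFactors = FALSE)
}

#' Split a DHS catalog into cell-type-specific and common regions
#'
#' Occurrence of a region is its row sum over the presence matrix; the
#' catalog is split at the median occurrence. Regions at exactly the
#' median go to the common set (documented tie rule).
#'
#' @param presence region x cell-type logical matrix (rownames = ids).
#' @return list: `specific`, `common` (region ids), `occurrence`, `median`.
#' @export
split_specific_common <- function(presence) {
  if (is.null(presence) || nrow(presence) == 0L) {
    stop_integrity("presence matrix is empty")
  }
  occ <- rowSums(presence)
  med <- median(occ)
  list(specific = rownames(presence)[occ < med],
       common = rownames(presence)[occ >= med],
       occurrence = occ, median = med)
}

#' Per-cell-type coverage of present regions
#'
#' For each cell type: among the regions present in that cell type, the
#' fraction covered by at least one position.
#'
#' @param regions catalog data.frame with `region_id`.
#' @param presence region x cell-type logical matrix.
#' @param positions data.frame (`chrom`, `pos`).
#' @return named numeric vector of fractions per cell type.
#' @export
coverage_by_cell_type <- function(regions, presence, positions) {
  counts <- count_points_in_ivs(regions, positions$chrom, positions$pos)
  names(counts) <- regions$region_id
  vapply(colnames(presence), function(ct) {
    ids <- rownames(presence)[presence[, ct]]
    if (!length(ids)) return(NA_real_)
    mean(counts[ids] >= 1L)
  }, numeric(1))
}
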