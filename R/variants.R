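# Variant-in-probe classification. Variants overlapping a probe are binned
# into three disjoint categories with fixed precedence:
#   TARGET_CPG > SBE > PROBE_BODY
# TARGET_CPG spans both bases of the assayed CpG dinucleotide (either allele
# disrupts the readout); SBE is the single-base-extension locus of Type I
# probes (for Type II the extension locus is the target C itself, which the
# target zone already covers); PROBE_BODY is the remaining 48 bp (Type I) or
# 49 bp (Type II) of the footprint. INDELs are classified by any
# overlapping base; a variant spanning several zones lands in the
# highest-precedence one.

#' Read variants from a VCF with an MAF filter
#'
#' Records are parsed with `VariantAnnotation`; the minor allele frequency
#' of a record is folded over its alternate alleles as
#' `max_alt(min(AF, 1 - AF))`, and only records with MAF strictly above
#' `maf_threshold` are retained. When the AF INFO field is absent, AC/AN
#' are used; records with neither raise a format error naming the record.
#'
#' @param vcf_path path to a VCF (4.x) file.
#' @param maf_threshold retain records with folded MAF > this (default 0.05).
#' @return data.frame: `chrom`, `pos` (0-based), `ref`, `alt`
#'   (comma-separated), `variant_class` (`SNP`/`INDEL`), `maf`.
#' @export
read_variants <- function(vcf_path, maf_threshold = 0.05) {
  vcf <- VariantAnnotation::readVcf(vcf_path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  alt_chr <- lapply(seq_along(alt_list), function(i) as.character(alt_list[[i]]))
  info <- VariantAnnotation::info(vcf)

  afs <- NULL
  if ("AF" %in% names(info)) {
    afs <- lapply(seq_along(alt_chr), function(i) as.numeric(info$AF[[i]]))
  } else if (all(c("AC", "AN") %in% names(info))) {
    afs <- lapply(seq_along(alt_chr), function(i) {
      as.numeric(info$AC[[i]]) / as.numeric(info$AN[i])
    })
  }
  if (is.null(afs)) {
    stop_format("VCF has neither AF nor AC/AN INFO fields")
  }
  bad <- which(vapply(afs, function(a) length(a) == 0L || anyNA(a), logical(1)))
  if (length(bad)) {
    stop_format("missing allele frequency for record ",
                rownames(vcf)[bad[1]], " (", bad[1], ")")
  }
  maf <- vapply(afs, function(a) max(pmin(a, 1 - a)), numeric(1))
  is_snp <- nchar(ref) == 1L &
    vapply(alt_chr, function(a) all(nchar(a) == 1L), logical(1))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr) - 1L,
    ref = ref,
    alt = vapply(alt_chr, paste, character(1), collapse = ","),
    variant_class = ifelse(is_snp, "SNP", "INDEL"),
    maf = maf, stringsAsFactors = FALSE)
  out <- out[out$maf > maf_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify variants overlapping probe footprints
#'
#' Every (probe, variant) pair whose intervals intersect is emitted exactly
#' once with the highest-precedence category it touches. The variant span
#' is `[pos, pos + nchar(ref))`; probe zones are on the plus strand (VCF
#' coordinates are plus-strand by definition).
#'
#' @param manifest an `epicqc_manifest`.
#' @param variants data.frame from [read_variants()].
#' @param include_noncpg also classify against ch/rs probes (default FALSE).
#' @return data.frame sorted by probe then position: `probe_id`,
#'   `category`, `chrom`, `pos`, `ref`, `alt`, `maf`, `variant_class`,
#'   `offset_from_3prime` (unsigned distance from the extension locus).
#' @export
classify_overlaps <- function(manifest, variants, include_noncpg = FALSE) {
  probes <- manifest$probes
  if (!include_noncpg) probes <- probes[probes$probe_class == "cg", ]
  empty <- data.frame(probe_id = character(0), category = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      maf = numeric(0), variant_class = character(0),
                      offset_from_3prime = integer(0))
  if (nrow(probes) == 0L || is.null(variants) || nrow(variants) == 0L) {
    return(empty)
  }
  vspan <- data.frame(chrom = variants$chrom, start = variants$pos,
                      end = variants$pos + nchar(variants$ref))
  # overall probe span = footprint plus (Type I) the SBE base
  pspan <- data.frame(chrom = probes$chrom,
                      start = pmin(probes$fp_start, probes$sbe_pos),
                      end = pmax(probes$fp_end, probes$sbe_pos + 1L))
  ov <- GenomicRanges::findOverlaps(ivs_to_gr(pspan), ivs_to_gr(vspan))
  if (length(ov) == 0L) return(empty)
  pi <- S4Vectors::queryHits(ov)
  vi <- S4Vectors::subjectHits(ov)

  isect <- function(zs, ze) vspan$start[vi] < ze[pi] & vspan$end[vi] > zs[pi]
  hit_target <- isect(probes$target_pos, probes$target_pos + 2L)
  hit_sbe <- isect(probes$sbe_pos, probes$sbe_pos + 1L)
  hit_body <- isect(probes$body_start, probes$body_end)
  category <- ifelse(hit_target, "TARGET_CPG",
                     ifelse(hit_sbe, "SBE",
                            ifelse(hit_body, "PROBE_BODY", NA_character_)))
  keep <- !is.na(category)
  out <- data.frame(
    probe_id = probes$probe_id[pi][keep],
    category = category[keep],
    chrom = variants$chrom[vi][keep],
    pos = variants$pos[vi][keep],
    ref = variants$ref[vi][keep],
    alt = variants$alt[vi][keep],
    maf = variants$maf[vi][keep],
    variant_class = variants$variant_class[vi][keep],
    offset_from_3prime = abs(variants$pos[vi][keep] - probes$sbe_pos[pi][keep]),
    stringsAsFactors = FALSE)
  out <- out[order(out$probe_id, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-category probe counts
#'
#' A probe is counted once per category in which it has at least one
#' qualifying variant (set semantics, matching how annotated probe lists
#' are published).
#'
#' @param overlaps data.frame from [classify_overlaps()].
#' @return named integer vector over `TARGET_CPG`, `SBE`, `PROBE_BODY`.
#' @export
summarize_overlaps <- function(overlaps) {
  cats <- c("TARGET_CPG", "SBE", "PROBE_BODY")
  out <- setNames(integer(3), cats)
  if (!is.null(overlaps) && nrow(overlaps)) {
    for (cat in cats) {
      out[cat] <- length(unique(overlaps$probe_id[overlaps$category == cat]))
    }
  }
  out
}
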