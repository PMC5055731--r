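# Probe data model and manifest I/O.
#
# A probe interrogates the CpG whose C sits at `target_pos` (0-based, plus
# strand). Its 50-base genomic footprint, single-base-extension (SBE) locus
# and probe body depend on the Infinium chemistry and the design strand:
#
#   Type I  : the probe 3' terminus lies on the target C; the labelled ddNTP
#             is incorporated one base upstream of the CpG (on the
#             hybridised strand), so the SBE base sits just outside the
#             footprint. Body = footprint minus the target CpG = 48 bp.
#   Type II : the target C itself is the extension locus (sbe_pos ==
#             target_pos on the plus strand); body = footprint minus the
#             SBE base = 49 bp.
#
# Minus-strand designs are the mirror image of the plus-strand layout.

#' Compute probe footprint, SBE position and body interval
#'
#' Vectorised over probes. All coordinates 0-based half-open on the plus
#' strand.
#'
#' @param infinium_type character, `"I"` or `"II"`.
#' @param target_pos integer, 0-based position of the CpG C (plus strand).
#' @param strand `"+"` or `"-"` (design strand).
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   supplied together with `chrom`, footprints beyond the chromosome bounds
#'   raise a coordinate error.
#' @param chrom optional chromosome names (needed for the bounds check).
#' @return data.frame with `fp_start`, `fp_end`, `sbe_pos`, `body_start`,
#'   `body_end`.
#' @export
compute_footprint <- function(infinium_type, target_pos, strand,
                              chrom_lengths = NULL, chrom = NULL) {
  n <- length(target_pos)
  stopifnot(length(infinium_type) == n, length(strand) == n)
  if (!all(infinium_type %in% c("I", "II"))) {
    stop_format("infinium_type must be 'I' or 'II'")
  }
  if (!all(strand %in% c("+", "-"))) stop_format("strand must be '+' or '-'")
  plus <- strand == "+"
  t1 <- infinium_type == "I"
  p <- as.integer(target_pos)

  fp_start <- ifelse(plus, p, p - 48L)
  fp_end <- fp_start + 50L
  sbe_pos <- ifelse(t1, ifelse(plus, p - 1L, p + 2L),  # Type I: upstream of CpG
                    ifelse(plus, p, p + 1L))           # Type II: the C itself
  body_start <- ifelse(t1, ifelse(plus, p + 2L, fp_start),
                       ifelse(plus, p + 1L, fp_start))
  body_end <- ifelse(t1, ifelse(plus, fp_end, p),
                     ifelse(plus, fp_end, p + 1L))

  if (!is.null(chrom_lengths) && !is.null(chrom)) {
    len <- chrom_lengths[chrom]
    lo <- pmin(fp_start, sbe_pos)
    hi <- pmax(fp_end, sbe_pos + 1L)
    bad <- which(is.na(len) | lo < 0L | hi > len)
    if (length(bad)) {
      stop_format("probe footprint exceeds chromosome bounds for ",
                  length(bad), " probe(s), first at index ", bad[1])
    }
  }
  data.frame(fp_start = as.integer(fp_start), fp_end = as.integer(fp_end),
             sbe_pos = as.integer(sbe_pos),
             body_start = as.integer(body_start),
             body_end = as.integer(body_end))
}

probe_class_from_id <- function(probe_id) {
  cls <- substr(probe_id, 1, 2)
  ifelse(cls %in% c("cg", "ch", "rs"), cls, NA_character_)
}

new_manifest <- function(probes, platform_name) {
  if (anyDuplicated(probes$probe_id)) {
    stop_integrity("duplicate probe_id in manifest: ",
                   probes$probe_id[duplicated(probes$probe_id)][1])
  }
  probes$probe_class <- probe_class_from_id(probes$probe_id)
  counts <- table(factor(probes$probe_class, levels = c("cg", "ch", "rs")),
                  factor(probes$infinium_type, levels = c("I", "II")))
  structure(list(platform_name = platform_name,
                 probes = probes,
                 counts = counts),
            class = "epicqc_manifest")
}

#' @export
print.epicqc_manifest <- function(x, ...) {
  cat("Manifest", x$platform_name, "-", nrow(x$probes), "probes\n")
  cls <- rowSums(x$counts)
  cat(sprintf("  CpG (cg): %d | CNG (ch): %d | SNP (rs): %d\n",
              cls["cg"], cls["ch"], cls["rs"]))
  cat(sprintf("  Infinium I: %d | Infinium II: %d\n",
              sum(x$counts[, "I"]), sum(x$counts[, "II"])))
  invisible(x)
}

MANIFEST_COLUMNS <- c("probe_id", "infinium_type", "chrom", "mapinfo",
                      "strand", "sequence_u", "sequence_m")

#' Read a manifest CSV
#'
#' Expected columns: `probe_id`, `infinium_type` (I/II), `chrom`, `mapinfo`
#' (1-based position of the target C), `strand` (+/-), `sequence_u`,
#' `sequence_m` (empty for Type II). Malformed rows are rejected with their
#' row numbers; positions are converted to the package-internal 0-based
#' convention and probe footprints are derived.
#'
#' @param path CSV path.
#' @param platform_name label stored on the result.
#' @return an `epicqc_manifest`.
#' @export
read_manifest <- function(path, platform_name = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing)) {
    stop_format("manifest is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$mapinfo <- suppressWarnings(as.integer(df$mapinfo))
  df$sequence_m[is.na(df$sequence_m)] <- ""

  bad_row <- function(cond, what) {
    rows <- which(cond)
    if (length(rows)) {
      stop_format("manifest row(s) ", paste(head(rows, 5), collapse = ", "),
                  ": ", what)
    }
  }
  bad_row(!df$infinium_type %in% c("I", "II"), "infinium_type must be I or II")
  bad_row(is.na(df$mapinfo) | df$mapinfo < 1L, "mapinfo must be a 1-based integer position")
  bad_row(!df$strand %in% c("+", "-"), "strand must be + or -")
  bad_row(nchar(df$sequence_u) != 50L, "sequence_u must be exactly 50 bases")
  bad_row(df$infinium_type == "I" & nchar(df$sequence_m) != 50L,
          "Type I probes need a 50-base sequence_m")
  bad_row(df$infinium_type == "II" & nchar(df$sequence_m) > 0L,
          "Type II probes must not carry sequence_m")
  bad_row(grepl("[^ACGTR]", df$sequence_u), "sequence_u has characters outside A/C/G/T/R")
  bad_row(df$infinium_type == "I" &
            (grepl("R", df$sequence_u, fixed = TRUE) |
               grepl("R", df$sequence_m, fixed = TRUE)),
          "Type I sequences must not contain degenerate R bases")
  if (anyDuplicated(df$probe_id)) {
    stop_integrity("duplicate probe_id: ", df$probe_id[duplicated(df$probe_id)][1])
  }

  probes <- data.frame(probe_id = df$probe_id,
                       infinium_type = df$infinium_type,
                       chrom = df$chrom,
                       target_pos = df$mapinfo - 1L,
                       strand = df$strand,
                       sequence_u = df$sequence_u,
                       sequence_m = df$sequence_m,
                       stringsAsFactors = FALSE)
  probes <- cbind(probes, compute_footprint(probes$infinium_type,
                                            probes$target_pos, probes$strand))
  new_manifest(probes, platform_name)
}

#' Write a manifest to CSV
#' @param manifest an `epicqc_manifest`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  df <- manifest$probes
  out <- data.frame(probe_id = df$probe_id,
                    infinium_type = df$infinium_type,
                    chrom = df$chrom,
                    mapinfo = df$target_pos + 1L,
                    strand = df$strand,
                    sequence_u = df$sequence_u,
                    sequence_m = df$sequence_m)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export probe footprints as a BED data.frame
#' @param manifest an `epicqc_manifest`.
#' @return data.frame with chrom, start, end, probe_id (0-based half-open).
#' @export
manifest_footprints_bed <- function(manifest) {
  df <- manifest$probes
  data.frame(chrom = df$chrom, start = df$fp_start, end = df$fp_end,
             name = df$probe_id, stringsAsFactors = FALSE)
}
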