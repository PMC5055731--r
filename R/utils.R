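# Internal helpers shared across modules. All genomic intervals inside the
# package are 0-based half-open [start, end); conversion to 1-based closed
# happens only at I/O boundaries (manifest MAPINFO, VCF POS, GRanges).

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("epicqc_config_error", "epicqc_error", "error")))
}
stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("epicqc_format_error", "epicqc_error", "error")))
}
stop_integrity <- function(...) {
  stop(errorCondition(paste0(...), class = c("epicqc_integrity_error", "epicqc_error", "error")))
}

#' Reverse complement of IUPAC-lite sequences
#'
#' Complements A/C/G/T and the two degenerate codes used by probe sequences
#' (R = purine, Y = pyrimidine); N maps to N.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYN", "TGCAYRN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Stable substream seed derived from a master seed and a generator label, so
# that adding a generator never perturbs the draws of another. Plain 31-hash
# of the label folded with the seed; kept below 2^31 - 1 (doubles are exact
# far beyond the intermediate magnitudes involved).
substream_seed <- function(seed, label) {
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% 2147480009
  as.integer((h + (seed %% 2147480009) * 97) %% 2147483647L)
}

set_stream <- function(seed, label) {
  set.seed(substream_seed(seed, label))
}

# data.frame(chrom, start, end) [0-based half-open] <-> GRanges
ivs_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

points_to_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = pos + 1L, width = 1L))
}

gr_to_ivs <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# Overlap count of point positions per interval row of `df`.
count_points_in_ivs <- function(df, chrom, pos) {
  if (nrow(df) == 0L) return(integer(0))
  if (length(pos) == 0L) return(integer(nrow(df)))
  # differing seqlevel sets between query and subject are expected here
  suppressWarnings(
    GenomicRanges::countOverlaps(ivs_to_gr(df), points_to_gr(chrom, pos)))
}

# Write a minimal BED (0-based half-open) file.
write_bed <- function(df, path, extra = NULL) {
  out <- df[, c("chrom", "start", "end")]
  if (!is.null(extra)) out <- cbind(out, df[, extra, drop = FALSE])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_bed <- function(path, extra = character(0)) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (length(extra)) names(df)[3 + seq_along(extra)] <- extra
  df
}
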