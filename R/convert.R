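# In-silico bisulphite genome construction.
#
# Bisulphite treatment converts unmethylated cytosines to uracil (read as T),
# while methylated cytosines -- in practice those in CpG context -- are
# protected. Aligning probe sequences therefore requires four genome
# variants: the converted plus and minus strands, each under the two extreme
# methylation assumptions (fully unmethylated vs all CpGs methylated). The
# minus-strand variants are stored in plus coordinates, where full C->T
# conversion of the reverse complement is equivalent to G->A conversion of
# the forward sequence (with the G of each CpG retained when methylated).

GENOME_IDS <- c("plus_unmethylated", "plus_cpg_methylated",
                "minus_unmethylated", "minus_cpg_methylated")

#' Convert a single sequence under one bisulphite model
#'
#' @param seq character scalar over A/C/G/T/N.
#' @param genome_id one of `"plus_unmethylated"`, `"plus_cpg_methylated"`,
#'   `"minus_unmethylated"`, `"minus_cpg_methylated"`.
#' @return converted sequence, same length, plus-strand coordinates.
#' @export
convert_sequence <- function(seq, genome_id) {
  genome_id <- match.arg(genome_id, GENOME_IDS)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop_format("non-ACGTN character(s) in sequence: ", paste(bad, collapse = ", "))
  }
  n <- length(ch)
  if (n == 0L) return(seq)
  if (startsWith(genome_id, "plus")) {
    idx <- which(ch == "C")
    if (genome_id == "plus_cpg_methylated" && length(idx)) {
      # retain C of CpG (C followed by G)
      nxt <- c(ch[-1L], "N")
      idx <- idx[nxt[idx] != "G"]
    }
    ch[idx] <- "T"
  } else {
    idx <- which(ch == "G")
    if (genome_id == "minus_cpg_methylated" && length(idx)) {
      # retain G of CpG (G preceded by C)
      prev <- c("N", ch[-n])
      idx <- idx[prev[idx] != "C"]
    }
    ch[idx] <- "A"
  }
  paste(ch, collapse = "")
}

#' Build the four in-silico bisulphite-converted genomes
#'
#' @param genome named character vector of chromosome sequences, a
#'   `sim_genome` object, or a path to a FASTA file.
#' @return object of class `converted_genomes`: a list with one named
#'   character vector of chromosome sequences per genome variant.
#' @export
build_converted_genomes <- function(genome) {
  seqs <- as_genome_seqs(genome)
  out <- lapply(GENOME_IDS, function(gid) {
    vapply(seqs, convert_sequence, character(1), genome_id = gid)
  })
  names(out) <- GENOME_IDS
  structure(list(genomes = out,
                 chrom_lengths = vapply(seqs, nchar, integer(1))),
            class = "converted_genomes")
}

# Accept a sim_genome, a named character vector, or a FASTA path.
as_genome_seqs <- function(genome) {
  if (inherits(genome, "sim_genome")) return(genome$seq)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    return(setNames(as.character(ss), names(ss)))
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  stop_format("genome must be a sim_genome, named character vector or FASTA path")
}

#' @export
print.converted_genomes <- function(x, ...) {
  cat("converted_genomes:", length(x$chrom_lengths), "chromosome(s),",
      sum(x$chrom_lengths), "bp;", length(x$genomes), "variants\n")
  invisible(x)
}

# Probe sequence synthesis -------------------------------------------------
#
# Stored probe sequences are 50 bases over {A,C,G,T,R}. The orientation
# convention is chosen so that a probe finds its design footprint by direct
# positional comparison ("fwd") against the minus genomes when
# design_strand == "+", and by reverse-complement comparison ("rev") against
# the plus genomes when design_strand == "-". Degenerate R marks the
# purine read-out of a non-assayed CpG (A when converted/unmethylated, G
# when protected/methylated); Type I probes carry no R because each allele
# sequence assumes one methylation state throughout.
#
# allele: "u" (unmethylated bead), "m" (methylated bead), or "both" (Type II
# single degenerate sequence).
probe_sequence_from_genome <- function(chromseq, fp_start, fp_end, strand, allele) {
  ch <- strsplit(substr(chromseq, fp_start + 1L, fp_end), "", fixed = TRUE)[[1]]
  n <- length(ch)
  L <- nchar(chromseq)
  before <- if (fp_start > 0L) substr(chromseq, fp_start, fp_start) else "N"
  after <- if (fp_end < L) substr(chromseq, fp_end + 1L, fp_end + 1L) else "N"
  if (strand == "+") {
    # minus-genome representation: G -> A, CpG G -> A/G/R
    is_g <- ch == "G"
    prev <- c(before, ch[-n])
    is_cpg_g <- is_g & prev == "C"
    out <- ch
    out[is_g & !is_cpg_g] <- "A"
    out[is_cpg_g] <- switch(allele, u = "A", m = "G", both = "R")
    paste(out, collapse = "")
  } else {
    # reverse complement of the CT-converted plus window
    is_c <- ch == "C"
    nxt <- c(ch[-1L], after)
    is_cpg_c <- is_c & nxt == "G"
    template <- ch
    template[is_c & !is_cpg_c] <- "T"
    template[is_cpg_c] <- switch(allele, u = "T", m = "C", both = "R")
    # complement (R stays R: degenerate read-out in probe space), then reverse
    comp <- chartr("ACGT", "TGCA", paste(template, collapse = ""))
    vapply(list(rev(strsplit(comp, "", fixed = TRUE)[[1]])),
           paste, character(1), collapse = "")
  }
}
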