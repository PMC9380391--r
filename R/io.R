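## Readers/writers for the plain-text formats shared by all modules, plus the
## coordinate and seeding conventions. Internal coordinates are always 0-based
## half-open; BED/BEDPE on disk use the same convention, VCF POS is 1-based.

#' Read a FASTA file into an uppercase DNAStringSet
#'
#' Sequence names are truncated at the first whitespace; soft-masked
#' (lowercase) bases are normalized to uppercase.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet]; empty set for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) return(Biostrings::DNAStringSet())
  gen <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  names(gen) <- sub("\\s.*$", "", names(gen))
  if (anyDuplicated(names(gen)))
    stop("duplicate sequence ids in ", path)
  Biostrings::DNAStringSet(toupper(gen))
}

#' Write a DNAStringSet to FASTA
#' @param genome Named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

## ---- genomic intervals -----------------------------------------------------

#' Validate 0-based half-open intervals against chromosome lengths
#'
#' @param chrom,start,end Parallel vectors describing intervals.
#' @param chrom_lengths Named vector of chromosome lengths (optional).
#' @return Invisibly TRUE; stops with an informative error otherwise.
#' @keywords internal
validate_intervals <- function(chrom, start, end, chrom_lengths = NULL) {
  if (any(start < 0) || any(end < start))
    stop("invalid interval: need 0 <= start < end")
  if (!is.null(chrom_lengths)) {
    bad <- !(chrom %in% names(chrom_lengths))
    if (any(bad)) stop("unknown chromosome: ", chrom[which(bad)[1]])
    over <- end > chrom_lengths[chrom]
    if (any(over))
      stop("interval beyond chromosome length on ", chrom[which(over)[1]])
  }
  invisible(TRUE)
}

#' Read/write BED (0-based half-open)
#'
#' @param path File path.
#' @return `read_bed`: data.frame with chrom, start, end (+ name if present).
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df
}

#' @rdname read_bed
#' @param bed data.frame with chrom, start, end columns.
#' @param chrom_lengths Optional named lengths for validation.
#' @export
write_bed <- function(bed, path, chrom_lengths = NULL) {
  if (nrow(bed)) validate_intervals(bed$chrom, bed$start, bed$end, chrom_lengths)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write BEDPE interval-pair files
#'
#' BEDPE pairs two genomic intervals per line (six mandatory columns, 0-based
#' half-open), used here for breakpoint regions and homologous-region pairs.
#' Extra columns beyond the first six are preserved on read and written back.
#'
#' @param path File path.
#' @return `read_bedpe`: data.frame with chrom1, start1, end1, chrom2, start2,
#'   end2 and any extra columns.
#' @export
read_bedpe <- function(path) {
  empty <- data.frame(chrom1 = character(), start1 = integer(), end1 = integer(),
                      chrom2 = character(), start2 = integer(), end2 = integer())
  if (file.size(path) == 0) return(empty)
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("BEDPE needs >= 6 columns: ", path)
  names(df)[1:6] <- names(empty)
  if (ncol(df) >= 7) names(df)[7] <- "name"
  if (ncol(df) >= 8) names(df)[8] <- "score"
  df
}

#' @rdname read_bedpe
#' @param pairs data.frame with the six BEDPE columns (extras allowed).
#' @param chrom_lengths Optional named chromosome lengths for validation.
#' @export
write_bedpe <- function(pairs, path, chrom_lengths = NULL) {
  if (nrow(pairs)) {
    validate_intervals(pairs$chrom1, pairs$start1, pairs$end1, chrom_lengths)
    validate_intervals(pairs$chrom2, pairs$start2, pairs$end2, chrom_lengths)
  }
  write.table(pairs, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- seeding ---------------------------------------------------------------

#' Derive a reproducible per-module substream seed from a global seed
#'
#' One global integer seed deterministically yields independent seeds for each
#' stochastic stage, so that whole-pipeline runs are reproducible while stages
#' remain individually re-runnable.
#'
#' @param seed Global integer seed.
#' @param stream Stage label (character) or integer offset.
#' @return An integer seed < 2^31.
#' @export
derive_seed <- function(seed, stream) {
  off <- if (is.character(stream)) {
    sum(as.integer(charToRaw(stream)) * seq_along(charToRaw(stream)))
  } else as.integer(stream)
  as.integer((as.double(seed) * 48271 + off * 8191) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
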