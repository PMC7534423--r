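#' Read sequences from FASTA or FASTQ
#'
#' Reads a (possibly gzip-compressed) FASTA or FASTQ file into a named
#' [Biostrings::DNAStringSet]. Sequences are uppercased; FASTQ qualities are
#' parsed for validation but not carried further, as all downstream
#' algorithms operate on the base calls alone (reads are assumed
#' quality-filtered upstream).
#'
#' @param path Path to the sequence file.
#' @param format One of `"auto"` (default; decided from the first non-empty
#'   character: `>` for FASTA, `@` for FASTQ), `"fasta"`, `"fastq"`.
#' @return A `DNAStringSet` with unique, non-empty names, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "ACGT"), fa)
#' readSequences(fa)
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("input file not found: ", path)
  if (format == "auto")
    format <- sniffFormat(path)
  seqs <- if (format == "fastq") {
    validateFastq(path)
    Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    Biostrings::readDNAStringSet(path, format = "fasta")
  }
  # FASTA headers keep only the first word as the record id
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyNA(nm) || any(!nzchar(nm)))
    stop("parse error in ", path, ": record with empty id")
  dup <- nm[duplicated(nm)]
  if (length(dup))
    stop("duplicate sequence id in ", path, ": ", dup[1L])
  if (any(Biostrings::width(seqs) == 0L))
    stop("parse error in ", path, ": zero-length sequence '",
      nm[Biostrings::width(seqs) == 0L][1L], "'")
  chars <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad))
    stop("sequence '", nm[bad][1L], "' contains characters outside {A,C,G,T,N}")
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- nm
  out
}

# structural check of 4-line FASTQ records (the parser itself tolerates a
# quality line of the wrong length, so lengths are compared here)
validateFastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  ln <- 0L
  repeat {
    rec <- readLines(con, n = 4L)
    if (!length(rec)) break
    if (length(rec) < 4L)
      stop("parse error in ", path, " at line ", ln + length(rec),
        ": truncated FASTQ record")
    if (!startsWith(rec[1L], "@"))
      stop("parse error in ", path, " at line ", ln + 1L,
        ": expected '@' header")
    if (!startsWith(rec[3L], "+"))
      stop("parse error in ", path, " at line ", ln + 3L,
        ": expected '+' separator")
    if (nchar(rec[4L]) != nchar(rec[2L]))
      stop("parse error in ", path, " at line ", ln + 4L,
        ": quality length ", nchar(rec[4L]),
        " does not match sequence length ", nchar(rec[2L]))
    ln <- ln + 4L
  }
  invisible(TRUE)
}

sniffFormat <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("parse error in ", path, " at line 1: empty file")
    if (nzchar(trimws(ln))) break
  }
  ch <- substr(trimws(ln), 1L, 1L)
  switch(ch, ">" = "fasta", "@" = "fastq",
    stop("parse error in ", path, " at line 1: not FASTA or FASTQ"))
}

#' Write sequences as FASTA
#'
#' @param seqs A named `DNAStringSet` (or object coercible to one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSequences <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write genomic intervals as BED6
#'
#' Writes a `GRanges` as 6-column BED (0-based half-open, tab-separated),
#' sorted by (seqname, start). The `name` metadata column (or a supplied
#' default) fills column 4 and `score` fills column 5.
#'
#' @param gr A [GenomicRanges::GRanges]; `name` and `score` metadata columns
#'   are used if present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  stopifnot(is(gr, "GRanges"))
  if (length(gr)) {
    if (is.null(gr$name)) gr$name <- paste0("interval_", seq_along(gr))
    if (is.null(gr$score)) gr$score <- 0L
    gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
      GenomicRanges::start(gr))]
    rtracklayer::export(gr, path, format = "BED")
  } else {
    file.create(path)
  }
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Thin character-level wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character(1) over {A,C,G,T,N}.
#' @return character(1).
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
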