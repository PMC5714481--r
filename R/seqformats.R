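#' @importFrom Biostrings DNAStringSet PhredQuality QualityScaledDNAStringSet
#'   readDNAStringSet width quality reverseComplement
#' @importFrom IRanges CharacterList NumericList
NULL

## Connection helper: transparent gzip on read and on write (by .gz suffix).
.openRead <- function(path) gzfile(path, open = "rt")
.openWrite <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, open = "wt") else file(path, open = "wt")
}

.decodeQuality <- function(qualStrings) {
  lapply(qualStrings, function(q) as.integer(charToRaw(q)) - 33L)
}

## Heuristic guard against Phred+64 input: legitimate Phred+33 data has some
## scores below 31 or a maximum at or below 60; an entire file of scores in
## [31, 93] with a maximum above 60 decodes to sensible values only as
## Phred+64.
.checkPhred33 <- function(qualInts) {
  if (!length(qualInts)) return(invisible(TRUE))
  lo <- min(vapply(qualInts, function(v) if (length(v)) min(v) else 93L, 0L))
  hi <- max(vapply(qualInts, function(v) if (length(v)) max(v) else 0L, 0L))
  if (hi > 93L || lo < 0L)
    stop("quality characters outside the printable Phred+33 range")
  if (lo >= 31L && hi > 60L)
    stop("quality scores look Phred+64 encoded; only Phred+33 is supported")
  invisible(TRUE)
}

#' Read a FASTQ file of sequencing reads
#'
#' Parses 4-line-per-record FASTQ with Phred+33 qualities into a
#' \link[Biostrings]{QualityScaledDNAStringSet}.  Gzip-compressed input is
#' read transparently.  Malformed records (missing \code{@}/\code{+} marker
#' lines, or a quality line whose length differs from the sequence line) are
#' reported with the index of the offending record.
#'
#' @param file path to a FASTQ or FASTQ.gz file.
#' @return a \code{QualityScaledDNAStringSet}; read ids are the names.
#' @seealso [readFastaReads()], [collapseReads()]
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' readFastqReads(fq)
#' @export
readFastqReads <- function(file) {
  con <- .openRead(file)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (!length(lines))
    return(QualityScaledDNAStringSet(DNAStringSet(), PhredQuality(character())))
  if (length(lines) %% 4L != 0L)
    stop("FASTQ record ", length(lines) %/% 4L + 1L,
         ": truncated (line count not a multiple of 4)")
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  quals <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("FASTQ record ", bad[1L], ": header does not start with '@'")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("FASTQ record ", bad[1L], ": separator line does not start with '+'")
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("FASTQ record ", bad[1L],
         ": quality length differs from sequence length")
  qi <- .decodeQuality(quals)
  .checkPhred33(qi)
  ids <- sub("^@", "", hdr)
  ids <- sub("\\s.*$", "", ids)
  out <- QualityScaledDNAStringSet(DNAStringSet(toupper(seqs)),
                                   PhredQuality(quals))
  names(out) <- ids
  out
}

#' Read a FASTA file of sequences
#'
#' Wraps \link[Biostrings]{readDNAStringSet}; multi-line sequences are
#' supported and gzip input is transparent.  Sequence data appearing before
#' the first header is an error; a header with no sequence yields a
#' zero-width entry with a warning.
#'
#' @param file path to a FASTA or FASTA.gz file.
#' @return a \code{DNAStringSet} named by the first whitespace-delimited
#'   token of each header.
#' @export
readFastaReads <- function(file) {
  con <- .openRead(file)
  first <- readLines(con, n = 50L, warn = FALSE)
  close(con)
  first <- first[nzchar(trimws(first))]
  if (length(first) && !startsWith(first[1L], ">"))
    stop("FASTA parse error: sequence data before the first '>' header")
  x <- readDNAStringSet(file, format = "fasta")
  names(x) <- sub("\\s.*$", "", names(x))
  if (any(width(x) == 0L))
    warning("FASTA records with empty sequences: ",
            paste(names(x)[width(x) == 0L], collapse = ", "))
  x
}

#' Read a reference gene set
#'
#' Reference genes are plain FASTA; ids may embed coordinates (for example
#' \code{"b0001|190_255"}) and pass through verbatim.  Gene length is the
#' sequence length.
#'
#' @param file path to the reference FASTA.
#' @return a named \code{DNAStringSet} of genes.
#' @export
readGenes <- function(file) {
  g <- readFastaReads(file)
  if (!length(g)) stop("reference gene set is empty")
  if (anyDuplicated(names(g))) stop("duplicated gene ids in reference")
  g
}

#' Format and parse SeqID_CopyNumber identifiers
#'
#' A collapsed record's on-disk identifier is its sequence id with the copy
#' number appended after an underscore.  Parsing splits on the \emph{last}
#' underscore, so ids containing underscores round-trip losslessly as long as
#' they do not themselves end in \code{"_<integer>"}.
#'
#' @param seqId character vector of sequence ids.
#' @param copyNumber integer vector of multiplicities.
#' @param header character vector of formatted identifiers.
#' @return \code{formatPlusId}: character vector of identifiers.
#'   \code{parsePlusId}: a data.frame with columns \code{seqId} and
#'   \code{copyNumber}.
#' @examples
#' parsePlusId("UniqueSeqX_1606515")
#' parsePlusId("a_b_3")  # id "a_b", 3 copies
#' @export
formatPlusId <- function(seqId, copyNumber) {
  stopifnot(all(copyNumber >= 1))
  paste0(seqId, "_", format(copyNumber, scientific = FALSE, trim = TRUE))
}

#' @rdname formatPlusId
#' @export
parsePlusId <- function(header) {
  ok <- grepl("^.+_[0-9]+$", header)
  if (!all(ok))
    stop("not in SeqID_CopyNumber form (no trailing \"_<integer>\"): ",
         paste(utils::head(header[!ok], 3L), collapse = ", "))
  seqId <- sub("_[0-9]+$", "", header)
  copy <- as.integer(sub("^.*_([0-9]+)$", "\\1", header))
  if (any(is.na(copy) | copy < 1L))
    stop("copy number must be a positive integer")
  data.frame(seqId = seqId, copyNumber = copy, stringsAsFactors = FALSE)
}

## Canonical record order for collapsed output: descending copy number,
## ties broken by lexicographic base order, so identical input multisets
## always produce byte-identical files.
.plusOrder <- function(copyNumber, bases) {
  order(-copyNumber, bases, method = "radix")
}

.encodeMeanQuality <- function(means) {
  ## round half up, clamp to printable Phred+33
  v <- pmin(pmax(floor(means + 0.5), 0), 93)
  rawToChar(as.raw(as.integer(v) + 33L))
}

.renderPlus <- function(x, withQuality) {
  ord <- .plusOrder(x@copyNumber, as.character(x@sequences))
  ids <- formatPlusId(x@seqId[ord], x@copyNumber[ord])
  seqs <- as.character(x@sequences)[ord]
  if (withQuality) {
    if (!length(x@meanQuality))
      stop("FASTQ+ output requested but records carry no mean qualities")
    qual <- vapply(x@meanQuality[ord], .encodeMeanQuality, character(1))
    as.vector(rbind(paste0("@", ids), seqs, "+", qual))
  } else {
    as.vector(rbind(paste0(">", ids), seqs))
  }
}

#' Write a collapsed read set as FASTA+ or FASTQ+
#'
#' FASTA+ records are \code{">SeqID_Count"} followed by the sequence; FASTQ+
#' additionally stores the per-site mean quality, rounded half-up to the
#' nearest integer and encoded as Phred+33.  Records are emitted in
#' descending copy number, ties broken by lexicographic order of the bases,
#' so output is deterministic for a given input multiset.
#'
#' @param x a [UniqueReadSet-class].
#' @param file output path; a \code{.gz} suffix triggers gzip compression.
#' @param format \code{"fasta+"} (default) or \code{"fastq+"}.
#' @return the file path, invisibly.
#' @seealso [collapseReads()], [readPlus()]
#' @export
writePlus <- function(x, file, format = c("fasta+", "fastq+")) {
  format <- match.arg(format)
  stopifnot(is(x, "UniqueReadSet"))
  lines <- .renderPlus(x, withQuality = format == "fastq+")
  con <- .openWrite(file)
  on.exit(close(con))
  writeLines(lines, con)
  invisible(file)
}

#' Read a FASTA+/FASTQ+ file
#'
#' The dialect is detected from the first record marker (\code{>} vs
#' \code{@}).  FASTQ+ quality lines are decoded to numeric Phred means (the
#' on-disk values are the rounded means, so a write/read cycle preserves
#' qualities to the nearest integer).
#'
#' @param file path to a \code{.fasP}/\code{.fqP} style file (optionally
#'   gzipped).
#' @return a [UniqueReadSet-class].
#' @export
readPlus <- function(file) {
  con <- .openRead(file)
  first <- readLines(con, n = 1L, warn = FALSE)
  close(con)
  if (!length(first)) {
    return(methods::new("UniqueReadSet", seqId = character(),
                        copyNumber = integer(), sequences = DNAStringSet(),
                        meanQuality = list()))
  }
  if (startsWith(first, "@")) {
    reads <- readFastqReads(file)
    p <- parsePlusId(names(reads))
    methods::new("UniqueReadSet",
                 seqId = p$seqId, copyNumber = p$copyNumber,
                 sequences = DNAStringSet(reads),
                 meanQuality = lapply(.decodeQuality(as.character(quality(reads))),
                                      as.numeric))
  } else {
    reads <- readFastaReads(file)
    p <- parsePlusId(names(reads))
    methods::new("UniqueReadSet",
                 seqId = p$seqId, copyNumber = p$copyNumber,
                 sequences = unname(reads), meanQuality = list())
  }
}

#' Expand a collapsed read set back to individual reads
#'
#' The inverse transform for interoperability with tools that expect one
#' entry per read: each record is replicated \code{copyNumber} times under
#' ids \code{seqId/1 ... seqId/k}.  The multiset of sequences is reproduced
#' exactly; the original read ids and the individual per-read quality vectors
#' are not recoverable (only their per-site mean was stored).
#'
#' @param x a [UniqueReadSet-class].
#' @return a \code{QualityScaledDNAStringSet} when mean qualities are
#'   present (each copy carries the rounded mean quality), otherwise a
#'   \code{DNAStringSet}.
#' @export
expandPlus <- function(x) {
  stopifnot(is(x, "UniqueReadSet"))
  idx <- rep(seq_along(x@seqId), x@copyNumber)
  reps <- sequence(x@copyNumber)
  ids <- paste0(x@seqId[idx], "/", reps)
  seqs <- x@sequences[idx]
  names(seqs) <- ids
  if (length(x@meanQuality)) {
    qual <- vapply(x@meanQuality, .encodeMeanQuality, character(1))[idx]
    out <- QualityScaledDNAStringSet(seqs, PhredQuality(qual))
    names(out) <- ids
    out
  } else {
    seqs
  }
}
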