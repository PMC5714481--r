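#' Element-wise mean of Phred quality vectors
#'
#' The quality vector of a collapsed record is the per-site arithmetic mean
#' of the quality vectors of all its copies: for two copies, site i gets
#' (Q1i + Q2i) / 2, and in general the flat mean over all copies.  Means are
#' kept unrounded; rounding happens only at FASTQ+ encoding time.
#'
#' @param vectors a list of numeric/integer Phred vectors of equal length.
#' @return a numeric vector of per-site means.
#' @examples
#' averageQuality(list(c(30, 40), c(40, 40)))  # 35 40
#' @export
averageQuality <- function(vectors) {
  if (!is.list(vectors) || length(vectors) == 0L)
    stop("need at least one quality vector")
  len <- unique(lengths(vectors))
  if (length(len) != 1L)
    stop("quality vectors differ in length; cannot average")
  if (len == 0L) return(numeric())
  colMeans(do.call(rbind, lapply(vectors, as.numeric)))
}

#' Pairwise Pearson correlation of quality vectors
#'
#' Quality vectors of reads sharing one sequence are typically strongly
#' positively correlated, which motivates storing only their mean.  Entries
#' involving a zero-variance vector are undefined and reported as \code{NA}.
#'
#' @param vectors a list of two or more equal-length numeric vectors.
#' @return a symmetric correlation matrix with unit diagonal.
#' @export
qualityCorrelation <- function(vectors) {
  if (!is.list(vectors) || length(vectors) < 2L)
    stop("need at least two quality vectors")
  if (length(unique(lengths(vectors))) != 1L)
    stop("quality vectors differ in length")
  m <- do.call(cbind, lapply(vectors, as.numeric))
  colnames(m) <- names(vectors) %||% paste0("Q", seq_len(ncol(m)))
  r <- suppressWarnings(stats::cor(m))
  diag(r) <- 1
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Plain-text byte sizes used for the size-reduction statistic (one byte per
## character plus one newline per line).
.textBytes <- function(lines) sum(nchar(lines, type = "bytes")) + length(lines)

.renderReadsBytes <- function(seqs, ids, qualStrings = NULL) {
  if (is.null(qualStrings)) {
    .textBytes(as.vector(rbind(paste0(">", ids), seqs)))
  } else {
    .textBytes(as.vector(rbind(paste0("@", ids), seqs, "+", qualStrings)))
  }
}

#' Collapse reads into a unique-read set with copy numbers
#'
#' Groups reads by exact sequence identity (case-folded; \code{N} kept
#' verbatim; reads of different length are always distinct) and stores each
#' distinct sequence once with its multiplicity.  When qualities are present
#' the per-site mean over all copies is retained.  The collapse is lossless
#' for the sequence multiset; original read ids and individual quality
#' vectors are deliberately dropped.
#'
#' Sequence ids are assigned as \code{"S<rank>"} in the canonical output
#' order (descending copy number, ties by base order), so the same input
#' multiset always collapses to the same records.
#'
#' @param reads a \code{QualityScaledDNAStringSet} (qualities averaged), a
#'   \code{DNAStringSet}, or a character vector of sequences.
#' @param qualities optional list of per-read Phred vectors used when
#'   \code{reads} carries none; must cover every read or be absent (a
#'   mixture cannot be averaged).
#' @param idPrefix prefix for the assigned sequence ids.
#' @return a list with elements \code{unique} (a [UniqueReadSet-class]) and
#'   \code{summary} (a [DedupSummary-class]).
#' @seealso [writePlus()], [expandPlus()]
#' @examples
#' r <- Biostrings::DNAStringSet(c("ACGT", "ACGT", "ACGA"))
#' collapseReads(r)$summary
#' @export
collapseReads <- function(reads, qualities = NULL, idPrefix = "S") {
  if (is(reads, "QualityScaledDNAStringSet")) {
    if (!is.null(qualities))
      stop("reads already carry qualities; do not supply 'qualities'")
    qualities <- .decodeQuality(as.character(quality(reads)))
    seqs <- toupper(as.character(reads))
  } else if (is(reads, "DNAStringSet")) {
    seqs <- toupper(as.character(reads))
  } else {
    seqs <- toupper(as.character(reads))
  }
  n <- length(seqs)
  if (!is.null(qualities)) {
    if (length(qualities) != n || any(vapply(qualities, is.null, TRUE)))
      stop("qualities present for some reads but not all; cannot average")
    if (any(lengths(qualities) != nchar(seqs)))
      stop("quality vector length differs from read length")
  }
  origIds <- names(seqs) %||% paste0("r", seq_len(n))
  grp <- factor(seqs)
  counts <- tabulate(grp, nbins = nlevels(grp))
  uniqSeq <- levels(grp)
  mq <- list()
  if (!is.null(qualities) && n > 0L) {
    byGroup <- split(seq_len(n), grp)
    mq <- lapply(byGroup, function(ii) averageQuality(qualities[ii]))
  }
  ord <- .plusOrder(counts, uniqSeq)
  counts <- counts[ord]
  uniqSeq <- uniqSeq[ord]
  if (length(mq)) mq <- unname(mq[ord])
  ids <- if (length(counts)) paste0(idPrefix, seq_along(counts)) else character()
  ur <- methods::new("UniqueReadSet",
                     seqId = ids, copyNumber = as.integer(counts),
                     sequences = DNAStringSet(uniqSeq), meanQuality = mq)
  withQ <- length(mq) > 0L
  origBytes <- if (n == 0L) 0L else .renderReadsBytes(
    seqs, origIds,
    if (withQ) vapply(qualities, function(v)
      rawToChar(as.raw(as.integer(v) + 33L)), character(1)) else NULL)
  collBytes <- if (n == 0L) 0L else .textBytes(.renderPlus(ur, withQ))
  summary <- methods::new("DedupSummary",
                          nReads = as.integer(n),
                          nUnique = length(counts),
                          maxCopy = if (length(counts)) max(as.integer(counts)) else 0L,
                          sizeRatio = if (n == 0L) NA_real_ else collBytes / origBytes)
  stopifnot(sum(counts) == n)  # conservation, by construction
  list(unique = ur, summary = summary)
}
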