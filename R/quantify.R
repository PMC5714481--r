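#' Reads per kilobase of gene
#'
#' @param count allocated read count (may be fractional).
#' @param lengthNt gene length in nucleotides; must be positive.
#' @return \code{1000 * count / lengthNt}, vectorized.
#' @examples
#' countPerKb(76, 66)      # 1151.515
#' countPerKb(2963, 2463)  # 1203.004
#' @export
countPerKb <- function(count, lengthNt) {
  if (any(lengthNt <= 0)) stop("gene length must be positive")
  1000 * count / lengthNt
}

#' Reads per kilobase per million mapped reads
#'
#' The library-size-standardized expression index: matched reads per
#' kilobase of transcript per million mapped reads, i.e.
#' \code{count * 1e9 / (lengthNt * totalMapped)}.
#'
#' @param count allocated read count.
#' @param lengthNt gene length in nucleotides.
#' @param totalMapped total mapped reads in the run; must be positive.
#' @return the FPKM value, vectorized.
#' @export
fpkm <- function(count, lengthNt, totalMapped) {
  if (any(lengthNt <= 0)) stop("gene length must be positive")
  if (any(totalMapped <= 0)) stop("totalMapped must be positive")
  count * 1e9 / (lengthNt * totalMapped)
}

#' Per-gene expression table
#'
#' One row per reference gene (zero-count genes included), sorted by gene
#' id, with the allocated count, count per kilobase, and FPKM.  The FPKM
#' denominator defaults to the total allocated (mapped) count of the run;
#' unmapped reads are excluded from it.
#'
#' @param counts an [AllocationResult-class] or a named numeric of allocated
#'   counts.
#' @param geneLengths named numeric of gene lengths in nt, or a named
#'   \code{DNAStringSet}; must cover every allocated gene.
#' @param totalMapped optional override of the per-million denominator.
#' @return a data.frame with columns \code{geneId}, \code{length},
#'   \code{count}, \code{countPerKb}, \code{fpkm}.
#' @seealso [writeExpressionTable()]
#' @export
expressionTable <- function(counts, geneLengths, totalMapped = NULL) {
  if (is(counts, "AllocationResult")) counts <- allocatedCounts(counts)
  if (is(geneLengths, "DNAStringSet"))
    geneLengths <- stats::setNames(as.numeric(width(geneLengths)),
                                   names(geneLengths))
  stopifnot(is.numeric(counts), is.numeric(geneLengths),
            !is.null(names(geneLengths)))
  missing <- setdiff(names(counts), names(geneLengths))
  if (length(missing))
    stop("allocated gene(s) missing from the reference: ",
         paste(missing, collapse = ", "))
  genes <- sort(names(geneLengths))
  full <- stats::setNames(numeric(length(genes)), genes)
  full[names(counts)] <- counts
  if (is.null(totalMapped)) totalMapped <- sum(full)
  cpk <- countPerKb(full, geneLengths[genes])
  fp <- if (totalMapped > 0) cpk * 1e6 / totalMapped else cpk * 0
  data.frame(geneId = genes, length = as.numeric(geneLengths[genes]),
             count = as.numeric(full), countPerKb = as.numeric(cpk),
             fpkm = as.numeric(fp), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write an expression table as TSV
#'
#' Columns are \code{Gene ID}, \code{SeqLen}, \code{Count}, \code{Count/Kb},
#' \code{FPKM}; counts print with 5 decimals (allocation yields fractional
#' counts), per-kilobase columns with 3.
#'
#' @param tab a data.frame from [expressionTable()].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeExpressionTable <- function(tab, file) {
  lines <- c("Gene ID\tSeqLen\tCount\tCount/Kb\tFPKM",
             sprintf("%s\t%d\t%.5f\t%.3f\t%.3f",
                     tab$geneId, as.integer(tab$length), tab$count,
                     tab$countPerKb, tab$fpkm))
  con <- .openWrite(file)
  on.exit(close(con))
  writeLines(lines, con)
  invisible(file)
}
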