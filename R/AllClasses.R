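#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Collapsed unique-read set
#'
#' A deduplicated read set in which each distinct sequence appears once,
#' annotated with its multiplicity (copy number) in the original file and,
#' when the input carried base qualities, the per-site arithmetic mean of the
#' Phred scores over all copies.  This is the in-memory form of a FASTA+ /
#' FASTQ+ file: on disk each record's identifier is
#' \code{<seqId>_<copyNumber>}.
#'
#' @slot seqId character vector of sequence identifiers (without the copy
#'   suffix).
#' @slot copyNumber integer vector of multiplicities, all >= 1.
#' @slot sequences a \link[Biostrings]{DNAStringSet} of the distinct
#'   sequences.
#' @slot meanQuality a list of numeric vectors (one per sequence, same length
#'   as the sequence) holding unrounded mean Phred scores, or an empty list
#'   when the source reads had no qualities.
#'
#' @seealso [collapseReads()], [writePlus()], [readPlus()], [expandPlus()]
#' @export
setClass("UniqueReadSet",
  representation(
    seqId = "character",
    copyNumber = "integer",
    sequences = "DNAStringSet",
    meanQuality = "list"
  )
)

setValidity("UniqueReadSet", function(object) {
  n <- length(object@sequences)
  msg <- character()
  if (length(object@seqId) != n)
    msg <- c(msg, "seqId length differs from number of sequences")
  if (length(object@copyNumber) != n)
    msg <- c(msg, "copyNumber length differs from number of sequences")
  if (n > 0 && any(object@copyNumber < 1L))
    msg <- c(msg, "all copy numbers must be >= 1")
  if (anyDuplicated(object@seqId))
    msg <- c(msg, "seqId values must be unique")
  mq <- object@meanQuality
  if (length(mq) != 0L) {
    if (length(mq) != n) {
      msg <- c(msg, "meanQuality must be empty or one vector per sequence")
    } else {
      w <- Biostrings::width(object@sequences)
      if (!all(lengths(mq) == w))
        msg <- c(msg, "each meanQuality vector must match its sequence length")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Deduplication summary statistics
#'
#' @slot nReads integer, number of input reads.
#' @slot nUnique integer, number of distinct sequences.
#' @slot maxCopy integer, largest copy number.
#' @slot sizeRatio numeric, plain-text bytes of the collapsed file divided by
#'   plain-text bytes of the original file (smaller is better; high-quality
#'   libraries with heavy duplication approach a few percent).
#'
#' @export
setClass("DedupSummary",
  representation(
    nReads = "integer",
    nUnique = "integer",
    maxCopy = "integer",
    sizeRatio = "numeric"
  )
)

setValidity("DedupSummary", function(object) {
  msg <- character()
  if (object@nUnique > object@nReads)
    msg <- c(msg, "nUnique cannot exceed nReads")
  if (object@maxCopy > object@nReads)
    msg <- c(msg, "maxCopy cannot exceed nReads")
  if (length(msg)) msg else TRUE
})

#' Per-read best-hit table
#'
#' For every unique read, the set of genes achieving the top alignment score.
#' A read with one best hit is a unique match; a read whose best hits tie
#' across two or more genes is a shared read; a read with an empty hit set is
#' unmapped.  Copy numbers weight every downstream count.
#'
#' @slot hits a \link[S4Vectors]{DataFrame} with columns \code{readId}
#'   (character), \code{copyNumber} (integer), \code{genes}
#'   (CharacterList of tied-best gene ids), \code{scores} (NumericList,
#'   per-gene score parallel to \code{genes}), \code{evalues} (NumericList,
#'   per-gene e-values, \code{NA} when the score source has none).
#'
#' @seealso [matchReads()], [loadTabularHits()], [allocateAll()]
#' @export
setClass("MatchTable", representation(hits = "DataFrame"))

setValidity("MatchTable", function(object) {
  need <- c("readId", "copyNumber", "genes", "scores", "evalues")
  miss <- setdiff(need, colnames(object@hits))
  if (length(miss))
    return(paste("hits is missing columns:", paste(miss, collapse = ", ")))
  h <- object@hits
  if (nrow(h) && any(lengths(h$scores) != lengths(h$genes)))
    return("scores must be parallel to genes")
  TRUE
})

#' Allocation parameters
#'
#' @slot pseudocount nonnegative numeric added per gene to the numerator of
#'   the proportion estimator (and member-count times it to the denominator).
#'   The default 0 uses plain ratios with an explicit equal split when all
#'   unique counts are zero; 0.01 selects the pseudocounted estimator.
#' @slot lengthNormalize one of \code{"auto"}, \code{"always"},
#'   \code{"never"}: whether unique counts are standardized to matches per
#'   kilobase before proportions are formed.  \code{"auto"} normalizes
#'   two-member families only (larger families are assumed to have roughly
#'   equal lengths).
#' @slot scheme one of \code{"unique"}, \code{"bitscore"}, \code{"evalue"}:
#'   unique-count proportional allocation (the default), or per-read
#'   weighting by bit score or e-value.
#' @slot evalueFloor positive numeric; e-values reported as 0 are clamped to
#'   this floor before weighting.
#'
#' @seealso [allocationParams()]
#' @export
setClass("AllocationParams",
  representation(
    pseudocount = "numeric",
    lengthNormalize = "character",
    scheme = "character",
    evalueFloor = "numeric"
  )
)

setValidity("AllocationParams", function(object) {
  msg <- character()
  if (object@pseudocount < 0) msg <- c(msg, "pseudocount must be >= 0")
  if (!object@lengthNormalize %in% c("auto", "always", "never"))
    msg <- c(msg, "lengthNormalize must be auto, always or never")
  if (!object@scheme %in% c("unique", "bitscore", "evalue"))
    msg <- c(msg, "scheme must be unique, bitscore or evalue")
  if (object@evalueFloor <= 0) msg <- c(msg, "evalueFloor must be > 0")
  if (length(msg)) msg else TRUE
})

#' Result of shared-read allocation
#'
#' Final per-gene allocated counts together with the per-shared-set
#' proportion vectors and the accumulated counts after each stage of the
#' progressive algorithm.
#'
#' @slot counts named numeric, final allocated count per gene (fractional in
#'   general).
#' @slot unmapped numeric, total copies of reads with an empty best-hit set.
#' @slot families named integer, gene -> family (connected component) id.
#' @slot proportions list of named numeric vectors, one per shared set,
#'   keyed by the sorted gene ids joined with \code{"+"}; each sums to 1.
#' @slot stages list of named numeric vectors: the accumulated
#'   unique-equivalent counts after processing all shared sets of each size
#'   (names \code{"size2"}, \code{"size3"}, ...).
#'
#' @seealso [progressiveAllocate()], [allocateAll()]
#' @export
setClass("AllocationResult",
  representation(
    counts = "numeric",
    unmapped = "numeric",
    families = "integer",
    proportions = "list",
    stages = "list"
  )
)

setValidity("AllocationResult", function(object) {
  msg <- character()
  if (length(object@counts) && is.null(names(object@counts)))
    msg <- c(msg, "counts must be named by gene")
  if (length(object@counts) && any(object@counts < -1e-9))
    msg <- c(msg, "allocated counts must be nonnegative")
  for (p in object@proportions) {
    if (abs(sum(p) - 1) > 1e-9) {
      msg <- c(msg, "each proportion vector must sum to 1")
      break
    }
  }
  if (length(msg)) msg else TRUE
})
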