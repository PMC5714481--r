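#' @include AllClasses.R
NULL

#' Accessors for paraquant classes
#'
#' Small accessor generics: slot access from user code is discouraged.
#'
#' @param x an object of the documented class.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))
#' @rdname accessors
#' @export
setGeneric("copyNumber", function(x) standardGeneric("copyNumber"))
#' @rdname accessors
#' @export
setGeneric("meanQuality", function(x) standardGeneric("meanQuality"))
#' @rdname accessors
#' @export
setGeneric("readSequences", function(x) standardGeneric("readSequences"))
#' @rdname accessors
#' @export
setGeneric("nReads", function(x) standardGeneric("nReads"))
#' @rdname accessors
#' @export
setGeneric("nUnique", function(x) standardGeneric("nUnique"))
#' @rdname accessors
#' @export
setGeneric("maxCopy", function(x) standardGeneric("maxCopy"))
#' @rdname accessors
#' @export
setGeneric("sizeRatio", function(x) standardGeneric("sizeRatio"))
#' @rdname accessors
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))
#' @rdname accessors
#' @export
setGeneric("allocatedCounts", function(x) standardGeneric("allocatedCounts"))
#' @rdname accessors
#' @export
setGeneric("unmappedCount", function(x) standardGeneric("unmappedCount"))
#' @rdname accessors
#' @export
setGeneric("geneFamilies", function(x) standardGeneric("geneFamilies"))
#' @rdname accessors
#' @export
setGeneric("sharedProportions", function(x) standardGeneric("sharedProportions"))
#' @rdname accessors
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))

#' @rdname accessors
#' @export
setMethod("seqId", "UniqueReadSet", function(x) x@seqId)
#' @rdname accessors
#' @export
setMethod("copyNumber", "UniqueReadSet", function(x) x@copyNumber)
#' @rdname accessors
#' @export
setMethod("meanQuality", "UniqueReadSet", function(x)
  if (length(x@meanQuality)) x@meanQuality else NULL)
#' @rdname accessors
#' @export
setMethod("readSequences", "UniqueReadSet", function(x) {
  s <- x@sequences
  names(s) <- x@seqId
  s
})
#' @rdname accessors
#' @export
setMethod("length", "UniqueReadSet", function(x) length(x@sequences))

#' @rdname accessors
#' @export
setMethod("nReads", "DedupSummary", function(x) x@nReads)
#' @rdname accessors
#' @export
setMethod("nUnique", "DedupSummary", function(x) x@nUnique)
#' @rdname accessors
#' @export
setMethod("maxCopy", "DedupSummary", function(x) x@maxCopy)
#' @rdname accessors
#' @export
setMethod("sizeRatio", "DedupSummary", function(x) x@sizeRatio)

#' @rdname accessors
#' @export
setMethod("hits", "MatchTable", function(x) x@hits)
#' @rdname accessors
#' @export
setMethod("length", "MatchTable", function(x) nrow(x@hits))

#' @rdname accessors
#' @export
setMethod("allocatedCounts", "AllocationResult", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("unmappedCount", "AllocationResult", function(x) x@unmapped)
#' @rdname accessors
#' @export
setMethod("geneFamilies", "AllocationResult", function(x) x@families)
#' @rdname accessors
#' @export
setMethod("sharedProportions", "AllocationResult", function(x) x@proportions)
#' @rdname accessors
#' @export
setMethod("stageCounts", "AllocationResult", function(x) x@stages)

setMethod("show", "UniqueReadSet", function(object) {
  cat("UniqueReadSet with", length(object), "unique sequences,",
      sum(object@copyNumber), "reads",
      if (length(object@meanQuality)) "(with mean qualities)\n" else "\n")
  if (length(object)) {
    k <- seq_len(min(3L, length(object)))
    for (i in k)
      cat(sprintf("  %s_%d  %s%s\n", object@seqId[i], object@copyNumber[i],
                  substr(as.character(object@sequences[[i]]), 1, 40),
                  if (Biostrings::width(object@sequences)[i] > 40) "..." else ""))
    if (length(object) > 3L) cat("  ...\n")
  }
})

setMethod("show", "DedupSummary", function(object) {
  cat(sprintf(
    "DedupSummary: %d reads -> %d unique (max copy %d), size ratio %.4f\n",
    object@nReads, object@nUnique, object@maxCopy, object@sizeRatio))
})

setMethod("show", "MatchTable", function(object) {
  nb <- lengths(object@hits$genes)
  cat(sprintf(
    "MatchTable: %d unique reads (%d unique-match, %d shared, %d unmapped)\n",
    nrow(object@hits), sum(nb == 1L), sum(nb > 1L), sum(nb == 0L)))
})

setMethod("show", "AllocationParams", function(object) {
  cat(sprintf(
    "AllocationParams: scheme=%s, pseudocount=%g, lengthNormalize=%s\n",
    object@scheme, object@pseudocount, object@lengthNormalize))
})

setMethod("show", "AllocationResult", function(object) {
  cat(sprintf(
    "AllocationResult: %d genes in %d families, %.5f reads allocated, %g unmapped\n",
    length(object@counts),
    if (length(object@families)) max(object@families) else 0L,
    sum(object@counts), object@unmapped))
})
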