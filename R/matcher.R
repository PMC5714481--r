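#' Build an exact k-mer index over a reference gene set
#'
#' Indexes every k-mer of every gene on both strands (the reverse complement
#' is indexed so that reads from either strand seed).  Genes shorter than k
#' are excluded from the index with a warning but retained in the gene set
#' for reporting.
#'
#' @param genes a named \code{DNAStringSet} of reference genes.
#' @param k k-mer size, between 8 and 32; default 15.
#' @return an opaque index object for [matchRead()] / [matchReads()].
#' @export
buildKmerIndex <- function(genes, k = 15L) {
  k <- as.integer(k)
  if (length(genes) == 0L) stop("empty gene list")
  if (is.null(names(genes)) || anyDuplicated(names(genes)))
    stop("genes must have unique names")
  if (k < 8L || k > 32L) stop("k must be in [8, 32]")
  fwd <- toupper(as.character(genes))
  rev <- as.character(reverseComplement(DNAStringSet(fwd)))
  short <- which(nchar(fwd) < k)
  if (length(short))
    warning("genes shorter than k excluded from index: ",
            paste(names(genes)[short], collapse = ", "))
  tab <- new.env(parent = emptyenv(), hash = TRUE)
  addKmers <- function(s, gi, strandCode) {
    L <- nchar(s)
    if (L < k) return(invisible())
    starts <- seq_len(L - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    for (j in seq_along(kmers)) {
      km <- kmers[j]
      tab[[km]] <- c(tab[[km]], gi, starts[j], strandCode)
    }
    invisible()
  }
  for (gi in seq_along(fwd)) {
    if (gi %in% short) next
    addKmers(fwd[gi], gi, 1L)   # + strand
    addKmers(rev[gi], gi, 2L)   # - strand (coordinates in the rc sequence)
  }
  structure(list(k = k, geneIds = names(genes),
                 fwd = lapply(fwd, charToRaw),
                 rev = lapply(rev, charToRaw),
                 lengths = nchar(fwd), table = tab),
            class = "kmerIndex")
}

## Count matching bases between a read and one gene at a fixed ungapped
## offset (0-based gene position of read base 1).  Returns score and the
## number of read bases that fall inside the gene.
.scoreAt <- function(readRaw, geneRaw, offset) {
  L <- length(readRaw)
  Lg <- length(geneRaw)
  gs <- max(1L, offset + 1L)
  ge <- min(Lg, offset + L)
  if (ge < gs) return(c(score = 0L, span = 0L))
  rs <- gs - offset
  re <- ge - offset
  c(score = sum(readRaw[rs:re] == geneRaw[gs:ge]), span = ge - gs + 1L)
}

#' Match one read against the index
#'
#' Seeds with every k-mer of the read, then extends each seed without gaps in
#' both directions, scoring one point per matching base.  A hit is kept when
#' at least \code{minInGene} of the read's bases fall inside the gene, so
#' reads overhanging a gene end still count to that gene.  Multiple seed hits
#' within one gene collapse to the single best ungapped placement per gene
#' and strand choice.
#'
#' @param readSeq a single sequence (character or \code{DNAString}).
#' @param index a k-mer index from [buildKmerIndex()].
#' @param minInGene minimum aligned bases inside the gene; default 25.
#' @return a data.frame with columns \code{gene}, \code{score},
#'   \code{strand}, \code{span} (one row per gene hit; zero rows when
#'   unmapped).
#' @export
matchRead <- function(readSeq, index, minInGene = 25L) {
  stopifnot(inherits(index, "kmerIndex"))
  s <- toupper(as.character(readSeq))
  k <- index$k
  L <- nchar(s)
  empty <- data.frame(gene = character(), score = integer(),
                      strand = character(), span = integer(),
                      stringsAsFactors = FALSE)
  if (L < k) return(empty)
  readRaw <- charToRaw(s)
  starts <- seq_len(L - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  ## candidate placements: key = gene, strand, offset
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  best <- list()
  for (j in seq_along(kmers)) {
    ent <- index$table[[kmers[j]]]
    if (is.null(ent)) next
    nhit <- length(ent) %/% 3L
    for (h in seq_len(nhit)) {
      gi <- ent[3L * h - 2L]
      gpos <- ent[3L * h - 1L]
      strandCode <- ent[3L * h]
      offset <- gpos - starts[j]           # 0-based placement
      key <- paste(gi, strandCode, offset)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      geneRaw <- if (strandCode == 1L) index$fwd[[gi]] else index$rev[[gi]]
      sc <- .scoreAt(readRaw, geneRaw, offset)
      if (sc[["span"]] < minInGene) next
      gk <- as.character(gi)
      prev <- best[[gk]]
      if (is.null(prev) || sc[["score"]] > prev$score) {
        best[[gk]] <- list(score = sc[["score"]], span = sc[["span"]],
                           strand = if (strandCode == 1L) "+" else "-")
      }
    }
  }
  if (!length(best)) return(empty)
  gi <- as.integer(names(best))
  data.frame(gene = index$geneIds[gi],
             score = vapply(best, function(b) as.integer(b$score), 0L),
             strand = vapply(best, function(b) b$strand, ""),
             span = vapply(best, function(b) as.integer(b$span), 0L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Keep the tied-best hits
#'
#' Reduces a hit list to the subset achieving the maximal score.  A single
#' survivor is a unique match; two or more are a shared read.  When e-values
#' accompany the scores, a tie additionally requires exact e-value equality.
#'
#' @param hitsDf a data.frame of hits with a \code{score} column and
#'   optionally an \code{evalue} column.
#' @return the best-hit subset (possibly zero rows).
#' @export
classifyHits <- function(hitsDf) {
  if (!nrow(hitsDf)) return(hitsDf)
  top <- hitsDf[hitsDf$score == max(hitsDf$score), , drop = FALSE]
  if (!is.null(top$evalue) && nrow(top) > 1L) {
    top <- top[top$evalue == min(top$evalue), , drop = FALSE]
  }
  top
}

#' Match a collapsed read set against a reference
#'
#' Runs [matchRead()] + [classifyHits()] over every unique read, producing a
#' [MatchTable-class] in which each distinct sequence is matched once no
#' matter how many copies it has — the computational payoff of the collapsed
#' representation.
#'
#' @param x a [UniqueReadSet-class] (or \code{DNAStringSet}, treated as
#'   copy-1 reads).
#' @param index a k-mer index from [buildKmerIndex()].
#' @param minInGene minimum aligned bases inside a gene.
#' @return a [MatchTable-class].
#' @export
matchReads <- function(x, index, minInGene = 25L) {
  if (is(x, "UniqueReadSet")) {
    seqs <- as.character(x@sequences)
    ids <- x@seqId
    copies <- x@copyNumber
  } else {
    seqs <- as.character(x)
    ids <- names(seqs) %||% paste0("S", seq_along(seqs))
    copies <- rep(1L, length(seqs))
  }
  genes <- vector("list", length(seqs))
  scores <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    h <- classifyHits(matchRead(seqs[i], index, minInGene))
    genes[[i]] <- h$gene
    scores[[i]] <- as.numeric(h$score)
  }
  hits <- S4Vectors::DataFrame(
    readId = ids,
    copyNumber = as.integer(copies),
    genes = IRanges::CharacterList(genes),
    scores = IRanges::NumericList(scores),
    evalues = IRanges::NumericList(lapply(lengths(genes), function(m)
      rep(NA_real_, m))))
  methods::new("MatchTable", hits = hits)
}

#' Import BLAST-style tabular hits
#'
#' Reads a 12-column tabular alignment file (query id, subject id, percent
#' identity, alignment length, mismatches, gap opens, qstart, qend, sstart,
#' send, e-value, bit score — the BLAST \code{outfmt 6} layout) and reduces
#' it to per-query best-hit sets: maximal bit score, with ties requiring
#' equal bit score \emph{and} equal e-value.  Multiple rows for one
#' query/subject pair collapse to the best row.  Copy numbers are parsed
#' from query ids in SeqID_CopyNumber form; queries without a parseable
#' suffix count as one copy, with a warning.
#'
#' @param file path to the tab-separated hit file.
#' @return a [MatchTable-class].
#' @export
loadTabularHits <- function(file) {
  con <- .openRead(file)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no alignment rows in ", file)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 12L)
  if (length(bad))
    stop("malformed alignment row at line ", bad[1L],
         ": expected 12 tab-separated columns")
  qid <- vapply(parts, `[[`, "", 1L)
  sid <- vapply(parts, `[[`, "", 2L)
  ev <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 11L)))
  bs <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 12L)))
  bad <- which(is.na(ev) | is.na(bs))
  if (length(bad))
    stop("malformed alignment row at line ", bad[1L],
         ": non-numeric e-value or bit score")
  qLevels <- unique(qid)
  copies <- vapply(qLevels, function(q) {
    p <- tryCatch(parsePlusId(q), error = function(e) NULL)
    if (is.null(p)) {
      warning("query id '", q, "' has no copy suffix; assuming 1 copy")
      1L
    } else p$copyNumber
  }, 0L)
  rowsByQ <- split(seq_along(qid), factor(qid, levels = qLevels))
  genes <- scores <- evs <- vector("list", length(qLevels))
  for (i in seq_along(qLevels)) {
    ii <- rowsByQ[[i]]
    ## best row per subject first, then the tied-best subject set
    d <- data.frame(gene = sid[ii], score = bs[ii], evalue = ev[ii],
                    stringsAsFactors = FALSE)
    d <- d[order(-d$score, d$evalue), , drop = FALSE]
    d <- d[!duplicated(d$gene), , drop = FALSE]
    top <- classifyHits(d)
    genes[[i]] <- top$gene
    scores[[i]] <- top$score
    evs[[i]] <- top$evalue
  }
  hits <- S4Vectors::DataFrame(
    readId = qLevels,
    copyNumber = as.integer(copies),
    genes = IRanges::CharacterList(genes),
    scores = IRanges::NumericList(scores),
    evalues = IRanges::NumericList(evs))
  methods::new("MatchTable", hits = hits)
}

#' Write a match table as TSV for inspection
#'
#' @param x a [MatchTable-class].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeMatchTable <- function(x, file) {
  h <- hits(x)
  lines <- c("readId\tcopyNumber\tgenes\tscores",
             vapply(seq_len(nrow(h)), function(i) {
               paste(h$readId[i], h$copyNumber[i],
                     paste(h$genes[[i]], collapse = ","),
                     paste(h$scores[[i]], collapse = ","), sep = "\t")
             }, ""))
  con <- .openWrite(file)
  on.exit(close(con))
  writeLines(lines, con)
  invisible(file)
}
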