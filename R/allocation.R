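#' Construct allocation parameters
#'
#' @param pseudocount per-gene pseudocount added to the numerator of the
#'   proportion estimator (the denominator gets the member count times it).
#'   Default 0: plain ratios with an explicit equal split when every unique
#'   count in the set is zero.  Set 0.01 for the pseudocounted two-member
#'   estimator.
#' @param lengthNormalize \code{"auto"} (default; standardize unique counts
#'   to matches per kilobase for two-member families only), \code{"always"},
#'   or \code{"never"}.
#' @param scheme \code{"unique"} (unique-count proportional, the default),
#'   \code{"bitscore"} or \code{"evalue"} (per-read weighting by alignment
#'   significance).
#' @param evalueFloor clamp for e-values reported as zero.
#' @return an [AllocationParams-class] object.
#' @export
allocationParams <- function(pseudocount = 0, lengthNormalize = "auto",
                             scheme = "unique", evalueFloor = 1e-180) {
  methods::new("AllocationParams", pseudocount = pseudocount,
               lengthNormalize = lengthNormalize, scheme = scheme,
               evalueFloor = evalueFloor)
}

## Proportion vector over a gene subset from accumulated unique-equivalent
## counts.  With pseudocount 0 and an all-zero subset (e.g. perfectly
## identical paralogs) the read is split equally.
.proportionVec <- function(acc, pseudocount = 0) {
  m <- length(acc)
  tot <- sum(acc)
  if (pseudocount == 0 && tot == 0) return(rep(1 / m, m))
  (pseudocount + acc) / (m * pseudocount + tot)
}

#' Two-member shared-read proportion
#'
#' The share of a read matching two paralogs equally well that is credited
#' to gene 1: \code{P1 = (eps + nu1) / (2 eps + nu1 + nu2)}, where nu are
#' the unique-match counts (optionally standardized to matches per kilobase
#' when gene lengths are supplied) and eps is the pseudocount.  With eps = 0
#' and no unique evidence at all the read is split equally.
#'
#' @param nu1,nu2 nonnegative unique-match counts for the two genes.
#' @param pseudocount per-gene pseudocount (default 0).
#' @param lengths optional numeric of length 2: gene lengths in nt; when
#'   given, each count is replaced by 1000 * nu / L before forming the
#'   ratio, correcting for the longer gene's head start in unique matches.
#' @return the proportion for gene 1, in [0, 1].
#' @examples
#' proportionTwo(291, 86)        # 0.7719...
#' proportionTwo(0, 0)           # 0.5, identical-paralog equal split
#' @export
proportionTwo <- function(nu1, nu2, pseudocount = 0, lengths = NULL) {
  if (nu1 < 0 || nu2 < 0) stop("unique counts must be nonnegative")
  nu <- c(nu1, nu2)
  if (!is.null(lengths)) {
    stopifnot(length(lengths) == 2L, all(lengths > 0))
    nu <- 1000 * nu / lengths
  }
  .proportionVec(nu, pseudocount)[1L]
}

#' Progressive allocation of shared reads within a gene family
#'
#' Allocates reads shared by several paralogs without building a phylogeny:
#' shared-read sets are processed in increasing order of set size (all
#' pairwise-shared sets first, then triple-shared, and so on up to the
#' family-wide set).  Each set's reads are divided among its member genes in
#' proportion to the genes' accumulated unique-equivalent counts at the
#' start of that stage, and the allocations are added to the accumulations
#' before the next stage.  All sets of one size see the same stage-entry
#' state, so the result does not depend on the order of equal-size sets.
#'
#' With only a pairwise set this reduces exactly to the two-member
#' proportional estimator.
#'
#' @param uniqueCounts named nonnegative numeric: unique-match count per
#'   family member (copy numbers already applied).
#' @param sharedSets a list of shared-read sets, each a
#'   \code{list(genes = <character of >= 2 member ids>, count = <reads>)}.
#' @param params an [AllocationParams-class]; governs pseudocount and length
#'   normalization.
#' @param geneLengths optional named numeric of gene lengths (nt), required
#'   when length normalization applies.
#' @return an [AllocationResult-class]: final counts, per-set proportion
#'   vectors (keyed by sorted member ids joined with \code{"+"}), and the
#'   accumulated counts after each stage.
#' @examples
#' ## three paralogs: 20 reads shared by B and C, 23 shared by all three
#' res <- progressiveAllocate(
#'   c(A = 7, B = 6, C = 12),
#'   list(list(genes = c("B", "C"), count = 20),
#'        list(genes = c("A", "B", "C"), count = 23)))
#' allocatedCounts(res)  # A 10.57778, B 19.14074, C 38.28148
#' @export
progressiveAllocate <- function(uniqueCounts, sharedSets = list(),
                                params = allocationParams(),
                                geneLengths = NULL) {
  stopifnot(is.numeric(uniqueCounts), !is.null(names(uniqueCounts)))
  if (any(uniqueCounts < 0)) stop("unique counts must be nonnegative")
  genes <- names(uniqueCounts)
  for (s in sharedSets) {
    if (length(s$genes) < 2L)
      stop("shared sets must contain at least two genes")
    if (!all(s$genes %in% genes))
      stop("shared set names unknown gene(s): ",
           paste(setdiff(s$genes, genes), collapse = ", "))
    if (anyDuplicated(s$genes)) stop("duplicated gene in a shared set")
    if (s$count < 0) stop("shared counts must be nonnegative")
  }
  normalize <- switch(params@lengthNormalize,
                      always = TRUE,
                      never = FALSE,
                      auto = length(genes) == 2L)
  if (normalize && is.null(geneLengths))
    stop("length normalization requested but geneLengths is missing")
  acc <- uniqueCounts
  props <- list()
  stages <- list()
  sizes <- vapply(sharedSets, function(s) length(s$genes), 0L)
  for (sz in sort(unique(sizes))) {
    atEntry <- acc                      # all same-size sets see this state
    delta <- stats::setNames(numeric(length(genes)), genes)
    for (s in sharedSets[sizes == sz]) {
      members <- s$genes
      base <- atEntry[members]
      if (normalize) base <- 1000 * base / geneLengths[members]
      p <- .proportionVec(base, params@pseudocount)
      names(p) <- members
      props[[paste(sort(members), collapse = "+")]] <- p[sort(members)]
      delta[members] <- delta[members] + s$count * p
    }
    acc <- acc + delta
    stages[[paste0("size", sz)]] <- acc
  }
  methods::new("AllocationResult",
               counts = acc, unmapped = 0,
               families = stats::setNames(rep(1L, length(genes)), genes),
               proportions = props, stages = stages)
}

#' Bit-score-weighted share of a multi-mapping read
#'
#' Divides one read among its hit genes in proportion to the alignment bit
#' scores: \code{P_i = BitScore_i / sum(BitScore)}.  Because bit scores of
#' near-tied hits are similar, this scheme tends toward equal allocation.
#'
#' @param bitscores positive numeric vector, one per candidate gene.
#' @return a proportion vector summing to 1.
#' @export
allocateBitscore <- function(bitscores) {
  if (any(bitscores <= 0)) stop("bit scores must be positive")
  bitscores / sum(bitscores)
}

#' E-value-weighted share of a multi-mapping read
#'
#' Weights hits by \code{min(E) / E_i}, normalized to sum to 1.  This favors
#' the best-matching gene much more strongly than bit-score weighting,
#' because e-values spread over orders of magnitude where bit scores differ
#' only slightly.  E-values reported as 0 are clamped to \code{floor}.
#'
#' @param evalues nonnegative numeric vector of e-values.
#' @param floor clamp applied to zeros (default 1e-180).
#' @return a proportion vector summing to 1.
#' @export
allocateEvalue <- function(evalues, floor = 1e-180) {
  if (any(evalues < 0)) stop("e-values must be nonnegative")
  e <- pmax(evalues, floor)
  w <- min(e) / e
  w / sum(w)
}

## Connected components of the co-best-hit graph: genes joined whenever a
## shared read's best-hit set contains both.
.geneFamilies <- function(allGenes, sharedGeneSets) {
  edges <- do.call(rbind, lapply(sharedGeneSets, function(g) {
    if (length(g) < 2L) return(NULL)
    cbind(g[-length(g)], g[-1L])        # a path suffices for connectivity
  }))
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(allGenes)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  stats::setNames(as.integer(comp), allGenes)
}

#' Allocate a whole match table over the reference
#'
#' Drives the allocation over every gene family at once: genes are
#' partitioned into families as connected components of the co-best-hit
#' graph, unique matches seed each family's unique-count state (weighted by
#' read copy numbers), shared reads are grouped by their exact best-hit gene
#' set, and each family is resolved by [progressiveAllocate()].  Under the
#' \code{"bitscore"} / \code{"evalue"} schemes each shared read is instead
#' divided by its own per-gene scores.  Reads with an empty best-hit set are
#' tallied as unmapped.
#'
#' Total reads are conserved exactly: allocated counts plus unmapped equal
#' the total copy number entering the table.
#'
#' @param matchTable a [MatchTable-class].
#' @param geneLengths named numeric of reference gene lengths (nt), or a
#'   named \code{DNAStringSet} of genes; may be omitted, in which case the
#'   gene universe is taken from the hits and length normalization is
#'   unavailable.
#' @param params an [AllocationParams-class].
#' @return an [AllocationResult-class] over all reference genes.
#' @export
allocateAll <- function(matchTable, geneLengths = NULL,
                        params = allocationParams()) {
  h <- hits(matchTable)
  if (is(geneLengths, "DNAStringSet"))
    geneLengths <- stats::setNames(as.numeric(width(geneLengths)),
                                   names(geneLengths))
  nb <- lengths(h$genes)
  hitGenes <- unique(unlist(h$genes, use.names = FALSE))
  if (is.null(geneLengths)) {
    allGenes <- sort(hitGenes)
    if (params@lengthNormalize == "always")
      stop("length normalization requires geneLengths")
    if (params@lengthNormalize == "auto") params@lengthNormalize <- "never"
  } else {
    allGenes <- sort(names(geneLengths))
    missing <- setdiff(hitGenes, allGenes)
    if (length(missing))
      stop("hit gene(s) absent from the reference: ",
           paste(missing, collapse = ", "))
  }
  unmapped <- sum(h$copyNumber[nb == 0L])
  counts <- stats::setNames(numeric(length(allGenes)), allGenes)
  uIdx <- which(nb == 1L)
  if (length(uIdx)) {
    ug <- unlist(h$genes[uIdx], use.names = FALSE)
    add <- tapply(as.numeric(h$copyNumber[uIdx]), ug, sum)
    counts[names(add)] <- counts[names(add)] + add
  }
  sIdx <- which(nb >= 2L)
  sharedGeneSets <- lapply(sIdx, function(i) sort(h$genes[[i]]))
  fam <- .geneFamilies(allGenes, sharedGeneSets)
  props <- list()
  stages <- list()
  if (params@scheme == "unique") {
    setKey <- vapply(sharedGeneSets, paste, "", collapse = "+")
    famOfSet <- vapply(sharedGeneSets, function(g) fam[[g[1L]]], 0L)
    for (f in unique(fam[unique(unlist(sharedGeneSets, use.names = FALSE))])) {
      members <- names(fam)[fam == f]
      here <- which(famOfSet == f)
      sharedCounts <- tapply(as.numeric(h$copyNumber[sIdx[here]]),
                             setKey[here], sum)
      sets <- lapply(names(sharedCounts), function(key)
        list(genes = strsplit(key, "+", fixed = TRUE)[[1L]],
             count = as.numeric(sharedCounts[[key]])))
      res <- progressiveAllocate(counts[members], sets, params,
                                 geneLengths = geneLengths)
      counts[members] <- allocatedCounts(res)
      props <- c(props, sharedProportions(res))
      stages[[paste0("family", f)]] <- stageCounts(res)
    }
  } else {
    for (i in sIdx) {
      g <- h$genes[[i]]
      p <- if (params@scheme == "bitscore") {
        allocateBitscore(h$scores[[i]])
      } else {
        ev <- h$evalues[[i]]
        if (all(is.na(ev)))
          stop("e-value scheme requires e-values in the match table")
        allocateEvalue(ev, params@evalueFloor)
      }
      names(p) <- g
      props[[h$readId[i]]] <- p
      counts[g] <- counts[g] + as.numeric(h$copyNumber[i]) * p
    }
  }
  total <- sum(as.numeric(h$copyNumber))
  if (abs(sum(counts) + unmapped - total) > 1e-9 * max(1, total))
    stop("internal error: read conservation violated in allocation")
  methods::new("AllocationResult", counts = counts,
               unmapped = as.numeric(unmapped), families = fam,
               proportions = props, stages = stages)
}

#' Write a per-family allocation report as TSV
#'
#' @param x an [AllocationResult-class].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeAllocationReport <- function(x, file) {
  fam <- geneFamilies(x)
  counts <- allocatedCounts(x)
  genes <- names(counts)
  lines <- c("family\tgene\tcount",
             vapply(order(fam[genes], genes), function(i) {
               sprintf("%d\t%s\t%.5f", fam[[genes[i]]], genes[i],
                       counts[[genes[i]]])
             }, ""))
  con <- .openWrite(file)
  on.exit(close(con))
  writeLines(lines, con)
  invisible(file)
}
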