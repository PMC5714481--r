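## Synthetic paralog families and read sets with ground truth.  These
## emulate the data regimes the tool is built for: identical or diverged
## paralogs, heavy PCR-style read duplication, and high- vs low-quality
## base calling.

.BASES <- c("A", "C", "G", "T")

## Substitute each site independently with probability `rate`, drawing the
## replacement uniformly from the three other bases, so the realized
## mismatch fraction against the template is Binomial(L, rate)/L.
.mutate <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(.BASES, b), 1L), "")
  }
  chars
}

#' Simulate a paralogous gene family
#'
#' Draws a random ancestor and derives each member by independent per-site
#' substitution at the given divergence rate.  In segmented mode the family
#' has exactly three members with an idealized three-segment structure: the
#' middle third is identical across all members, the first third is shared
#' (identically) by members B and C but diverged in A, and the final third
#' is independently diverged in every member — the canonical situation in
#' which reads are shared by two genes, by all three, or are unique.
#'
#' @param nMembers number of family members (3 in segmented mode).
#' @param length ancestor length in nt.
#' @param divergence per-site substitution probability between the ancestor
#'   and each member, in [0, 1); 0 yields identical paralogs.
#' @param seed optional RNG seed for reproducibility.
#' @param segmented logical; use the three-segment structure.
#' @param ids member ids; defaults to \code{LETTERS}.
#' @return a named \code{DNAStringSet} of family members.
#' @export
makeFamily <- function(nMembers, length, divergence, seed = NULL,
                       segmented = FALSE, ids = LETTERS) {
  stopifnot(nMembers >= 1, length >= 3, divergence >= 0, divergence < 1)
  if (!is.null(seed)) set.seed(seed)
  anc <- sample(.BASES, length, replace = TRUE)
  if (segmented) {
    if (nMembers != 3L) stop("segmented mode builds exactly 3 members")
    third <- length %/% 3L
    seg1 <- seq_len(third)
    seg2 <- seq(third + 1L, 2L * third)
    seg3 <- seq(2L * third + 1L, length)
    bcFirst <- .mutate(anc[seg1], divergence)  # shared by B and C only
    members <- list(
      A = c(anc[seg1], anc[seg2], .mutate(anc[seg3], divergence)),
      B = c(bcFirst, anc[seg2], .mutate(anc[seg3], divergence)),
      C = c(bcFirst, anc[seg2], .mutate(anc[seg3], divergence)))
  } else {
    members <- lapply(seq_len(nMembers), function(i) .mutate(anc, divergence))
    names(members) <- ids[seq_len(nMembers)]
  }
  DNAStringSet(vapply(members, paste, "", collapse = ""))
}

.rzipf <- function(n, skew, mMax = 1000L) {
  if (skew <= 0) return(rep(1L, n))
  m <- seq_len(mMax)
  sample(m, n, replace = TRUE, prob = m^(-skew))
}

.makeQuality <- function(readLength, regime) {
  if (regime == "high") {
    q <- round(stats::rnorm(readLength, mean = 40, sd = 1.2))
  } else {
    ## mean decays along the read, as in degraded later sequencing cycles
    decay <- seq(38, 20, length.out = readLength)
    q <- round(decay + stats::rnorm(readLength, sd = 4))
  }
  pmin(pmax(q, 2L), 41L)
}

#' Simulate sequencing reads from a gene set, with ground truth
#'
#' Per-gene read totals are Poisson at the configured expected abundance;
#' fragment start positions are uniform over the gene.  Each distinct
#' fragment is replicated with a Zipf-distributed multiplicity (PCR-style
#' duplication — the redundancy the collapsed format exploits), and every
#' copy then receives independent per-base substitution errors, so higher
#' error rates fragment the duplicate structure and reduce compressibility.
#' Qualities are drawn near Phred 40 in the \code{"high"} regime and with a
#' decaying mean in the \code{"low"} regime.
#'
#' @param genes named \code{DNAStringSet} of source genes.
#' @param abundance named numeric: expected read count per gene (names must
#'   match \code{genes}); not all zero.
#' @param readLength read length in nt; no longer than the shortest gene.
#' @param errorRate per-base substitution probability in [0, 1).
#' @param qualityRegime \code{"high"} or \code{"low"}.
#' @param dupSkew Zipf exponent for fragment multiplicities; 0 disables
#'   duplication.
#' @param seed optional RNG seed.
#' @return a list: \code{reads} (a \code{QualityScaledDNAStringSet}),
#'   \code{truth} (named numeric, reads emitted per gene), and
#'   \code{origin} (character, source gene of each read in order).
#' @export
simulateReads <- function(genes, abundance, readLength = 50L,
                          errorRate = 0, qualityRegime = c("high", "low"),
                          dupSkew = 0, seed = NULL) {
  qualityRegime <- match.arg(qualityRegime)
  stopifnot(is(genes, "DNAStringSet"), !is.null(names(genes)))
  stopifnot(all(names(abundance) %in% names(genes)))
  if (all(abundance == 0)) stop("all abundances are zero; nothing to simulate")
  if (any(width(genes)[match(names(abundance), names(genes))] < readLength))
    stop("readLength exceeds a gene length")
  if (!is.null(seed)) set.seed(seed)
  seqChars <- lapply(as.character(genes), function(s) strsplit(s, "")[[1L]])
  outSeq <- character(0)
  outGene <- character(0)
  for (g in names(abundance)) {
    nReads <- stats::rpois(1L, abundance[[g]])
    if (nReads == 0L) next
    L <- length(seqChars[[g]])
    emitted <- 0L
    frags <- character(0)
    while (emitted < nReads) {
      start <- sample.int(L - readLength + 1L, 1L)
      mult <- min(.rzipf(1L, dupSkew), nReads - emitted)
      frag <- seqChars[[g]][start:(start + readLength - 1L)]
      copies <- vapply(seq_len(mult), function(i)
        paste(.mutate(frag, errorRate), collapse = ""), "")
      frags <- c(frags, copies)
      emitted <- emitted + mult
    }
    outSeq <- c(outSeq, frags)
    outGene <- c(outGene, rep(g, nReads))
  }
  n <- length(outSeq)
  quals <- vapply(seq_len(n), function(i)
    rawToChar(as.raw(.makeQuality(readLength, qualityRegime) + 33L)), "")
  reads <- QualityScaledDNAStringSet(DNAStringSet(outSeq),
                                     PhredQuality(quals))
  names(reads) <- sprintf("%s.%06d", outGene, seq_len(n))
  truth <- vapply(split(rep(1L, n), outGene), sum, 0L)
  stopifnot(sum(truth) == n)  # conservation of the truth table
  list(reads = reads,
       truth = truth[order(names(truth))],
       origin = outGene)
}

#' Write simulated fixtures to disk
#'
#' Emits the reads as FASTQ, the genes as FASTA, and the per-gene truth
#' counts as a two-column TSV.
#'
#' @param sim output of [simulateReads()].
#' @param genes the gene set the reads were simulated from.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSimFixtures <- function(sim, genes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reads <- sim$reads
  fq <- file.path(dir, "reads.fastq")
  lines <- as.vector(rbind(paste0("@", names(reads)),
                           as.character(reads), "+",
                           as.character(quality(reads))))
  writeLines(lines, fq)
  Biostrings::writeXStringSet(genes, file.path(dir, "genes.fasta"))
  writeLines(c("gene\tcount",
               sprintf("%s\t%d", names(sim$truth), sim$truth)),
             file.path(dir, "truth.tsv"))
  invisible(dir)
}
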