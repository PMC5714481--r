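---
title: "Collapsed read storage and paralog-aware read allocation: methods"
author: "paraquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collapsed read storage and paralog-aware read allocation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paraquant)
```

## The two problems this package addresses

Bulk and single-cell RNA-seq files contain enormous numbers of exactly
identical reads: the most abundant transcript fragments are sequenced
hundreds of thousands of times, and every standard pipeline stores and
aligns each copy separately.  paraquant collapses a read file so that each
distinct sequence is stored once under a `SeqID_CopyNumber` identifier
(FASTA+; FASTQ+ additionally keeps a quality line).  The collapse is
lossless for the sequence multiset: expanding a collapsed file reproduces
exactly the original sequences with their multiplicities.  The original
read ids and the individual (pre-averaging) quality vectors are the two
deliberately discarded fields.

The second problem is quantification in the presence of paralogous genes.
A read drawn from a conserved segment matches two or more family members
with identical alignment score and e-value, and the common options —
discarding such reads, or splitting them equally — are both biased.
paraquant allocates each shared read across the tied genes in proportion
to the *unique-match* evidence for those genes.

## Quality handling in FASTQ+

Quality vectors of identical-sequence reads are strongly positively
correlated, and a Phred score is itself a statistical estimate, so the
collapsed record keeps the per-site arithmetic mean over all copies: for a
sequence of length $L$ seen $n$ times, site $i$ stores
$\bar Q_i = \frac1n \sum_k Q_{ki}$.  Means are held unrounded in memory;
at FASTQ+ encoding time they are rounded half-up to the nearest integer
and written as Phred+33 characters (the format does not accommodate
fractional scores; round-half-up is an encoding choice, stated here
because the on-disk value is what a write/read cycle preserves).  Only
Phred+33 input is accepted; a file whose scores are all in the range that
only makes sense under Phred+64 (minimum decoded score $\ge 31$ with a
maximum above 60) is rejected rather than silently mis-decoded.

Output order is canonical — descending copy number, ties broken by
lexicographic base order, ids assigned as `S<rank>` — so the same input
multiset always produces a byte-identical file.

## The allocation model

For a two-member family, let $N_{U.1}$ and $N_{U.2}$ be the reads matching
gene 1 (resp. 2) strictly better than the other gene.  A read tying both
genes is credited to gene 1 with proportion

$$P_1 = \frac{\varepsilon + N_{U.1}}{2\varepsilon + N_{U.1} + N_{U.2}},$$

with pseudocount $\varepsilon$.  The package default is $\varepsilon = 0$
together with an explicit equal-split rule when $N_{U.1} = N_{U.2} = 0$
(perfectly identical paralogs): the plain ratio is what the worked
three-gene arithmetic below uses, and the pseudocounted variant
($\varepsilon = 0.01$) is available through
`allocationParams(pseudocount = 0.01)` for users who prefer a smoothed
estimator.  When the two genes differ in length, unique counts can be
standardized to matches per kilobase, $SN_{U.i} = 1000\,N_{U.i}/L_i$,
before the ratio is formed; the default (`lengthNormalize = "auto"`)
applies this to two-member families only and assumes larger families have
roughly equal member lengths, both behaviors being overridable.

For families of $F > 2$ genes, naively extending the formula over all $F$
members fails: if B and C are identical but diverged from A, then
$N_{U.B} = N_{U.C} = 0$ and all of B's and C's shared reads would flow to
A.  The progressive algorithm avoids this without building a phylogeny:

1. group shared reads by their exact tied-gene set;
2. process sets in increasing size (all pairwise sets, then triples, ...);
3. allocate each set's reads over its members in proportion to the
   members' *accumulated* counts at the entry of that stage;
4. add the allocations to the accumulations before the next stage.

With unique counts A = 7, B = 6, C = 12, a pairwise set $\{B,C\}$ of 20
reads and a triple set of 23 reads, the pairwise stage leaves B and C at
$6 + 20/3 = 12.66667$ and $12 + 40/3 = 25.33333$; the triple stage then
uses $P_A = 7/45 = 0.15556$, $P_B = 0.28148$, $P_C = 0.56296$ and yields
final counts $10.57778$, $19.14074$, $38.28148$ — identical to resolving
the family on its (known) duplication tree, which is why the tree is never
needed.

```{r worked-example}
res <- progressiveAllocate(
  c(A = 7, B = 6, C = 12),
  list(list(genes = c("B", "C"), count = 20),
       list(genes = c("A", "B", "C"), count = 23)))
round(allocatedCounts(res), 5)
round(sharedProportions(res)[["A+B+C"]], 5)
```

One design point was genuinely open: when several shared sets have the
same size, sequential updating would make the result depend on processing
order.  paraquant computes all same-size proportions from the state at
stage entry and applies the increments together, which makes the result
invariant to the order of equal-size sets (and to gene permutation).

Two alternative weightings are provided for reads whose candidate hits are
strong but *not* exactly tied: proportional to bit score,
$P_i = \mathrm{BitScore}_i / \sum_j \mathrm{BitScore}_j$, which is close to
an equal split because near-tied bit scores are similar; and proportional
to $\min(E)/E_i$ (normalized), which is far more biased toward the best
hit because e-values spread over orders of magnitude.  E-values reported
as zero are clamped to $10^{-180}$ before weighting.

Allocated counts are conserved exactly: the per-gene totals plus the
unmapped tally always equal the total copy number entering the table (the
allocator asserts this to $10^{-9}$ relative, the accumulation being plain
double arithmetic).

## Matching and family construction

The built-in matcher is an exact k-mer seed (default $k = 15$) with
ungapped extension, scoring one point per matching base, over both strands
(the reverse complement of each gene is indexed).  A hit is retained when
at least `minInGene = 25` read bases fall inside the gene, so a read
overhanging a gene's 3' end still counts to that gene — the situation that
makes naive transcript-interval counters drop thousands of legitimate
reads.  Ungapped extension is deliberate: the allocation mathematics
consumes only scores and tie structure, and indel-tolerant alignment would
add complexity the downstream method never uses.  A read is a *unique
match* iff exactly one gene attains the top score; ties require exact
score equality (and exact e-value equality when e-values are the score
source, as with imported BLAST tabular hits, where bit score is used).

Families are the connected components of the co-best-hit graph (genes
joined whenever some read's best-hit set contains both), so a shared read
can never straddle two families by construction.

## Quantification

The report has one row per reference gene: allocated count $N_i$
(fractional in general; printed at 5 decimals), Count/Kb
$= 1000\,N_i/L_i$ and FPKM $= N_i \cdot 10^9/(L_i \cdot T)$ (both at 3
decimals).  The per-million denominator $T$ defaults to the total
*allocated* count — unmapped reads are excluded — and can be overridden,
since the "mapped reads" population is a convention that differs between
tools.

## The synthetic data generator

Recovery tests need ground truth, so the package ships a simulator rather
than fixtures.  `makeFamily()` draws a uniform-random ancestor and mutates
each member independently at a per-site substitution rate (substitution
only — no indels, matching the ungapped matcher; adding indels would test
the aligner, not the allocation).  Its segmented mode reproduces the
canonical three-gene topology: identical middle third (reads shared by all
three), first third identical between B and C only, last third diverged in
every member.  `simulateReads()` draws per-gene read totals as Poisson at
the configured expected abundance, uniform fragment starts, optional
per-copy substitution errors, and Zipf-distributed fragment multiplicities
(exponent `dupSkew`, capped at 1000 copies) emulating PCR duplication — a
handful of dominant fragments among many singletons, which is exactly the
redundancy the collapsed format exploits.  Qualities are drawn near Phred
40 in the high regime and with a mean decaying from 38 to 20 along the
read in the low regime.

Two regime notes matter for interpreting the tests:

* Sequencing errors are applied per *copy*, after duplication, so raising
  the error rate fragments the duplicate structure: the collapse-ratio
  tests assert that the size ratio at error rate 0 is no worse than at
  0.05 on the same transcript pool, reproducing the observation that
  collapse efficiency is a read-quality phenomenon.
* The parameter-recovery tests (counts within 3 binomial standard errors
  of truth; relative error below 5% at divergences 5–20%) run the
  simulator with `dupSkew = 0`.  The binomial sampling-error oracle
  assumes independent reads; under heavy Zipf duplication reads cluster
  into few fragments and the effective sample size is the fragment count,
  so that oracle is simply not valid there.  Duplication-enabled
  simulations are used where the oracle is exact counting (conservation,
  compression, roundtrip).

What the simulator does *not* emulate: positional coverage bias, quality-
dependent error profiles, indels, rRNA contamination, and paired-end
structure (each mate of a pair is processed as an independent file
throughout the package).  Passing tests therefore demonstrate the
correctness of the collapse and allocation arithmetic under the stated
model, not end-to-end accuracy on arbitrary real libraries.

## Problem sizes and numerical choices

The test suite works at desk scale by design: families of 2–3 genes of
300–600 nt, read sets of 300 to 20,000 reads, k = 15, `minInGene` = 25.
The collapse dictionary holds all unique sequences in memory (exact
match on the full base string — near-duplicate merging would make the
format lossy).  Proportion vectors are checked to sum to 1 within
$10^{-12}$; read conservation is exact for integer inputs and within
$10^{-9}$ relative for fractional accumulations.  Ties in the canonical
output order are broken lexicographically; ties in alignment score are
never broken silently — they are the definition of a shared read.

## Known limitations

* Exact-identity collapse only: a single sequencing error creates a new
  record, so low-quality libraries collapse poorly (this is a property of
  the format, reported by `sizeRatio`, not a failure mode).
* The matcher is a desk-scale substitute for a production aligner; for
  large references, import BLAST tabular hits via `loadTabularHits()`
  instead.
* Gene ids containing `"+"` would collide with the shared-set key
  separator in reports; avoid them.
* FPKM is within-sample only; no TPM, no cross-sample normalization, no
  differential testing.
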