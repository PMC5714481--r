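## Fixture builders shared across test files.  Everything is generated in
## code; nothing is read from stored data files.

writeFastqFixture <- function(ids, seqs, quals, path = tempfile(fileext = ".fastq")) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

writeFastaFixture <- function(ids, seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

## Tabular (BLAST outfmt-6 style) encoding of the two-paralog cold-shock
## worked example: 264 reads unique to cspF, 58 unique to cspH, 27 shared
## reads matching cspF better, 28 matching cspH better, 12 exact ties.
cspTabularFixture <- function(path = tempfile(fileext = ".tsv")) {
  row <- function(q, s, ev, bs)
    paste(q, s, "100.00", "50", "0", "0", "1", "50", "1", "50", ev, bs,
          sep = "\t")
  writeLines(c(
    row("U1_264", "cspF", "1e-20", "98.0"),
    row("U2_58",  "cspH", "1e-20", "98.0"),
    row("B1_27",  "cspF", "1e-20", "98.0"),
    row("B1_27",  "cspH", "1e-18", "93.0"),
    row("B2_28",  "cspH", "1e-20", "98.0"),
    row("B2_28",  "cspF", "1e-18", "93.0"),
    row("T1_12",  "cspF", "1e-19", "95.5"),
    row("T1_12",  "cspH", "1e-19", "95.5")
  ), path)
  path
}

## Two genes sharing an identical first half, diverged second half: reads
## from the first half are shared, reads from the second half are unique.
halfSharedPair <- function(seed = 42, len = 400) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  common <- sample(bases, len / 2, replace = TRUE)
  g1 <- paste(c(common, sample(bases, len / 2, replace = TRUE)), collapse = "")
  g2 <- paste(c(common, sample(bases, len / 2, replace = TRUE)), collapse = "")
  Biostrings::DNAStringSet(c(gene1 = g1, gene2 = g2))
}
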