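# Fixtures built in code: tiny alignments, a toy preference table, trees.

# alignment from named sequence strings
alnFromStrings <- function(seqs, speciesOf, roles) {
  sampleAlignment(seqs, speciesOf, roles)
}

# a single-exon annotation covering L columns
exonAnn <- function(L) regionAnnotation(0L, as.integer(L), "exon")

# toy preference table over the full code: for each multi-codon family the
# alphabetically first codon is preferred, the rest unpreferred
toyPrefTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- sort(names(gc))
  aa <- gc[codons]
  status <- character(length(codons))
  for (a in unique(aa)) {
    idx <- which(aa == a)
    if (a %in% c("M", "W", "*")) status[idx] <- "not_applicable"
    else { status[idx] <- "unpreferred"; status[idx[1]] <- "preferred" }
  }
  data.frame(codon = codons, amino_acid = unname(aa), status = status)
}

# brute-force two-tailed Fisher p by full enumeration of tables with the
# observed margins (point-probability rule)
bruteFisher2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  x <- max(0, r1 + c1 - N):min(r1, c1)
  pr <- stats::dhyper(x, c1, N - c1, r1)
  pObs <- stats::dhyper(a, c1, N - c1, r1)
  sum(pr[pr <= pObs * (1 + 1e-7)])
}

# closed-form Pearson chi-square for a 2x2 table
handChisq2x2 <- function(a, b, c, d) {
  N <- a + b + c + d
  N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# small rooted 6-taxon tree with branch lengths
balancedTree6 <- function(len = 0.1) {
  ape::read.tree(text = sprintf(
    "(((t1:%g,t2:%g):%g,(t3:%g,t4:%g):%g):%g,(t5:%g,t6:%g):%g);",
    len, len, len, len, len, len, len, 2 * len, 2 * len, len))
}

randomSenseCodons <- function(n) {
  gc <- Biostrings::GENETIC_CODE
  sample(names(gc)[gc != "*"], n, replace = TRUE)
}
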