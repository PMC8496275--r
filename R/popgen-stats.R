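# Diversity and divergence summaries: Watterson's theta, pi, uncorrected
# divergence, singleton counts, Tajima's D and Fay & Wu's H.

harmonicNumber <- function(n, power = 1) sum(1 / (seq_len(n - 1))^power)

#' Watterson's theta per site
#'
#' `theta_W = S / (a_n * L)` with `a_n = sum_{i=1}^{n-1} 1/i`.
#'
#' @param S number of segregating sites
#' @param n sample size (>= 2)
#' @param L effective number of sites
#' @return theta per site
#' @export
wattersonTheta <- function(S, n, L) {
  if (n < 2) stop("n must be >= 2")
  if (L <= 0) stop("L must be > 0")
  S / (harmonicNumber(n) * L)
}

#' Nucleotide diversity from a sample of sequences
#'
#' Average pairwise difference over all `choose(n, 2)` sequence pairs.
#' Columns with a gap or `N` in any analyzed row are dropped listwise
#' before counting (complete deletion).
#'
#' @param mat character matrix (rows = sequences) or 0/1 integer matrix of
#'   haplotypes
#' @return list with `piTotal` (per locus), `piPerSite`, `Leff` (columns
#'   retained), `S` (segregating sites among retained columns)
#' @export
nucleotideDiversity <- function(mat) {
  n <- nrow(mat)
  if (n < 2) stop("need at least two sequences")
  if (is.character(mat)) {
    keep <- apply(mat, 2L, function(x) all(x %in% BASES))
    mat <- mat[, keep, drop = FALSE]
  }
  L <- ncol(mat)
  diffs <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
    diffs <- diffs + sum(mat[i, ] != mat[j, ])
  piTotal <- diffs / choose(n, 2)
  S <- sum(apply(mat, 2L, function(x) length(unique(x)) > 1L))
  list(piTotal = piTotal,
       piPerSite = if (L > 0) piTotal / L else NA_real_,
       Leff = L, S = S)
}

#' Tajima's D
#'
#' `D = (pi_total - S/a_1) / sqrt(e1*S + e2*S*(S-1))` with the 1989
#' variance constants. Undefined at `S = 0` (returns `NA` with a reason
#' attribute).
#'
#' @param S segregating sites
#' @param piTotal total (per-locus) nucleotide diversity
#' @param n sample size
#' @return numeric D
#' @export
tajimasD <- function(S, piTotal, n) {
  if (S == 0) {
    out <- NA_real_
    attr(out, "reason") <- "undefined at S = 0"
    return(out)
  }
  a1 <- harmonicNumber(n)
  a2 <- harmonicNumber(n, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (piTotal - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fay and Wu's H (unnormalized)
#'
#' `H = theta_pi - theta_H` computed from the polarized site frequency
#' spectrum: `theta_pi = sum S_i * 2 i (n-i) / (n (n-1))`,
#' `theta_H = sum S_i * 2 i^2 / (n (n-1))`. Reported on the unnormalized
#' per-locus scale.
#'
#' @param derivedCounts integer vector of derived-allele counts, one entry
#'   per polarized variant (each in `1..n-1`)
#' @param n sample size
#' @return list with `H`, `thetaPi`, `thetaH`
#' @export
fayWuH <- function(derivedCounts, n) {
  if (length(derivedCounts) &&
      (any(derivedCounts < 1) || any(derivedCounts > n - 1)))
    stop("derived counts must lie in 1..n-1")
  i <- derivedCounts
  thetaPi <- sum(2 * i * (n - i)) / (n * (n - 1))
  thetaH <- sum(2 * i^2) / (n * (n - 1))
  list(H = thetaPi - thetaH, thetaPi = thetaPi, thetaH = thetaH)
}

#' Uncorrected divergence between two species
#'
#' Mean proportion of differing sites over all between-species sequence
#' pairs, restricted to the given columns; per pair, columns with a gap or
#' `N` in either sequence are dropped for that pair only. No multiple-hit
#' correction.
#'
#' @param aln a [SampleAlignment-class]
#' @param speciesA,speciesB species names
#' @param columns alignment columns to use (default all)
#' @return mean per-site divergence
#' @export
divergence <- function(aln, speciesA, speciesB,
                       columns = seq_len(alignmentWidth(aln))) {
  m <- alnMatrix(aln)
  ra <- speciesRows(aln, speciesA)
  rb <- speciesRows(aln, speciesB)
  if (!length(ra) || !length(rb)) stop("species not present in alignment")
  props <- c()
  for (i in ra) for (j in rb) {
    a <- m[i, columns]; b <- m[j, columns]
    ok <- a %in% BASES & b %in% BASES
    if (!any(ok)) next
    props <- c(props, sum(a[ok] != b[ok]) / sum(ok))
  }
  if (!length(props)) stop("no comparable sites between species")
  mean(props)
}

#' Singleton count and fraction
#'
#' A singleton is a variant whose minor allele occurs in exactly one
#' sampled sequence (folded definition); with `folded = FALSE` the derived
#' allele count must be exactly 1.
#'
#' @param counts vector of derived (or minor) allele counts per variant
#' @param n sample size
#' @param folded fold the spectrum before counting (default)
#' @return list with `count` and `fraction` (`NA` when there are no
#'   variants)
#' @export
singletonFraction <- function(counts, n, folded = TRUE) {
  if (folded) counts <- pmin(counts, n - counts)
  cnt <- sum(counts == 1)
  list(count = cnt,
       fraction = if (length(counts)) cnt / length(counts) else NA_real_)
}

#' Codon-wise synonymous/nonsynonymous divergence between two species
#'
#' For every between-species sequence pair and every complete, gap-free
#' codon, single-nucleotide codon differences are classified synonymous or
#' nonsynonymous; codons differing at more than one position are excluded
#' (no pathway averaging). Numerators are divided by the pair-averaged
#' Nei-Gojobori site counts and the proportions are averaged over pairs.
#'
#' @param aln a [SampleAlignment-class]
#' @param speciesA,speciesB species names
#' @param codonMap output of [buildCodonMap()]
#' @return named numeric vector `synDiv`, `nonsynDiv`
#' @export
codonDivergence <- function(aln, speciesA, speciesB, codonMap) {
  m <- alnMatrix(aln)
  ra <- speciesRows(aln, speciesA)
  rb <- speciesRows(aln, speciesB)
  if (!length(ra) || !length(rb)) stop("species not present in alignment")
  gc <- geneticCode()
  map <- codonMap[codonMap$complete, , drop = FALSE]
  codCols <- lapply(split(map, map$codon), function(d)
    d$column[order(d$pos)])
  sd <- nd <- numeric(0)
  for (i in ra) for (j in rb) {
    synDiff <- nonsynDiff <- synSites <- nonsynSites <- 0
    for (cols in codCols) {
      ca <- m[i, cols]; cb <- m[j, cols]
      if (any(!c(ca, cb) %in% BASES)) next
      sa <- paste(ca, collapse = ""); sb <- paste(cb, collapse = "")
      if (gc[[sa]] == "*" || gc[[sb]] == "*") next
      cs <- countSites(c(sa, sb))
      diffs <- sum(ca != cb)
      if (diffs > 1L) next             # ambiguous pathway: excluded
      synSites <- synSites + mean(cs$synSites)
      nonsynSites <- nonsynSites + mean(cs$nonsynSites)
      if (diffs == 1L) {
        if (gc[[sa]] == gc[[sb]]) synDiff <- synDiff + 1
        else nonsynDiff <- nonsynDiff + 1
      }
    }
    sd <- c(sd, if (synSites > 0) synDiff / synSites else NA_real_)
    nd <- c(nd, if (nonsynSites > 0) nonsynDiff / nonsynSites else
      NA_real_)
  }
  c(synDiv = mean(sd, na.rm = TRUE), nonsynDiv = mean(nd, na.rm = TRUE))
}

#' Per-site-class diversity and divergence summary
#'
#' Computes, for one focal species, the per-class (synonymous,
#' nonsynonymous, intron) segregating sites, singleton counts, Watterson's
#' theta, pi and uncorrected divergence, plus whole-region Tajima's D and
#' (when outgroups allow polarization) Fay and Wu's H. Effective lengths
#' per class are the summed Nei-Gojobori fractional sites for
#' synonymous/nonsynonymous and the intact intron columns for introns.
#'
#' @param aln a [SampleAlignment-class]
#' @param ann a [RegionAnnotation-class]
#' @param species focal ingroup species
#' @param divergenceSpecies species against which divergence is computed
#'   (optional)
#' @param outgroupSpecies species used to polarize for H (default: role
#'   `outgroup`)
#' @return object of class `summaryStatistics`: list with `perClass`
#'   data.frame, `tajimaD`, `fayWuH`, `S`, `piTotal`, `n`, `singletons`
#' @export
summaryStatistics <- function(aln, ann, species, divergenceSpecies = NULL,
                              outgroupSpecies = NULL) {
  rows <- speciesRows(aln, species)
  if (length(rows) < 2) stop("need >= 2 samples of the focal species")
  map <- buildCodonMap(ann)
  sct <- classifyColumns(aln, map, species = species,
                         intronCols = intronColumns(ann))
  cc <- columnClasses(sct)
  m <- alnMatrix(aln)[rows, , drop = FALSE]
  n <- length(rows)

  usable <- apply(m, 2L, function(x) all(x %in% BASES))  # listwise
  varcol <- usable & apply(m, 2L, function(x) length(unique(x)) > 1L)

  classes <- c("synonymous", "nonsynonymous", "intron")
  per <- lapply(classes, function(cl) {
    if (cl == "intron") {
      cols <- which(cc$class == "intron" & usable)
      Leff <- length(cols)
    } else {
      # variable columns of this effect class; effective length from
      # fractional site counts
      cols <- which(cc$class == cl & usable)
      cs <- codonSiteCounts(sct)
      Leff <- sum(if (cl == "synonymous") cs$synSites else cs$nonsynSites,
                  na.rm = TRUE)
    }
    S <- sum(varcol[cols])
    minor <- vapply(which(varcol[cols] == TRUE), function(k) {
      tb <- table(m[, cols[k]])
      min(tb)
    }, numeric(1))
    pi <- if (length(cols))
      nucleotideDiversity(m[, cols, drop = FALSE]) else
      list(piTotal = 0, piPerSite = NA_real_, Leff = 0)
    div <- if (is.null(divergenceSpecies)) NA_real_
           else if (cl == "intron") {
             if (length(cols))
               divergence(aln, species, divergenceSpecies, cols)
             else NA_real_
           } else {
             cd <- codonDivergence(aln, species, divergenceSpecies, map)
             unname(cd[[if (cl == "synonymous") "synDiv" else "nonsynDiv"]])
           }
    data.frame(class = cl, S = S, singletons = sum(minor == 1),
               Leff = Leff,
               thetaW = if (S > 0 && Leff > 0)
                 wattersonTheta(S, n, Leff) else 0,
               piPerSite = if (Leff > 0) pi$piTotal / Leff else NA_real_,
               divergence = div)
  })
  per <- do.call(rbind, per)

  # whole-region statistics over all usable annotated columns
  allCols <- which(usable & cc$class != "excluded")
  wr <- nucleotideDiversity(m[, allCols, drop = FALSE])
  D <- tajimasD(wr$S, wr$piTotal, n)
  pol <- polarize(aln, species, outgroupSpecies)
  pol <- pol[pol$polarized & pol$column %in% allCols, , drop = FALSE]
  H <- if (nrow(pol)) fayWuH(pol$i, n)$H else NA_real_
  minorAll <- vapply(allCols[apply(m[, allCols, drop = FALSE], 2L,
                                   function(x) length(unique(x)) > 1L)],
                     function(cl) min(table(m[, cl])), numeric(1))
  structure(list(perClass = per, tajimaD = as.numeric(D), fayWuH = H,
                 S = wr$S, piTotal = wr$piTotal, n = n,
                 singletons = singletonFraction(minorAll, n)$count,
                 polarized = pol),
            class = "summaryStatistics")
}

#' @export
print.summaryStatistics <- function(x, ...) {
  cat("Summary statistics (n =", x$n, ")\n")
  print(x$perClass, row.names = FALSE, digits = 4)
  cat("whole region: S =", x$S, " pi =", round(x$piTotal, 3),
      " Tajima's D =", round(x$tajimaD, 3),
      " Fay & Wu's H =", round(x$fayWuH, 3), "\n")
  invisible(x)
}
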