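# McDonald-Kreitman tables: site classification, table construction,
# low-frequency variant filtering, Fisher exact testing.

#' Classify alignment sites for the McDonald-Kreitman test
#'
#' A site is `polymorphic` when any species in `polymorphismSpecies`
#' segregates more than one nucleotide in its population sample; it is
#' `fixed_divergent` when all alleles of one species differ from all
#' alleles of the other species. Sites that are both polymorphic and
#' divergent count as polymorphic only. Sites where a species has only
#' gaps/`N` are excluded and logged; gap/`N` rows are otherwise dropped
#' per site.
#'
#' @param aln a [SampleAlignment-class]
#' @param polymorphismSpecies species whose within-sample variation counts
#'   as polymorphism
#' @param species all species participating in the comparison (default:
#'   every species in the alignment)
#' @return data.frame with `column`, `status` (`invariant`, `polymorphic`,
#'   `fixed_divergent`, `excluded`), `divergentSpecies` (the species whose
#'   lineage carries the fixed difference, else `NA`)
#' @export
classifySitesMK <- function(aln, polymorphismSpecies, species = NULL) {
  if (is.null(species)) species <- unique(speciesOf(aln))
  stopifnot(all(polymorphismSpecies %in% species))
  m <- alnMatrix(aln)
  rowsBySp <- lapply(species, function(s) speciesRows(aln, s))
  names(rowsBySp) <- species
  out <- data.frame(column = seq_len(ncol(m)), status = "invariant",
                    divergentSpecies = NA_character_)
  for (col in seq_len(ncol(m))) {
    alleles <- lapply(rowsBySp, function(r) {
      x <- m[r, col]
      unique(x[x %in% BASES])
    })
    if (any(lengths(alleles) == 0L)) {
      out$status[col] <- "excluded"
      next
    }
    poly <- any(lengths(alleles[polymorphismSpecies]) > 1L)
    if (poly) {
      out$status[col] <- "polymorphic"
      next
    }
    for (s in species) {
      others <- unique(unlist(alleles[setdiff(species, s)]))
      if (!length(intersect(alleles[[s]], others))) {
        out$status[col] <- "fixed_divergent"
        out$divergentSpecies[col] <- s
        break
      }
    }
  }
  out
}

#' Assemble a McDonald-Kreitman 2x2 table
#'
#' Cross-tabulates the MK site classification against the
#' synonymous/nonsynonymous column classes and tests the table with the
#' two-tailed Fisher exact test.
#'
#' @param classified output of [classifySitesMK()] (possibly filtered by
#'   [fwwFilter()])
#' @param siteClasses a [SiteClassTable-class] computed over all species in
#'   the comparison
#' @param speciesPolymorphism,divergenceLineage,filterApplied provenance
#'   strings stored in the table
#' @return an [MKTable-class]
#' @export
buildMKTable <- function(classified, siteClasses,
                         speciesPolymorphism = "",
                         divergenceLineage = "",
                         filterApplied = "none") {
  cc <- columnClasses(siteClasses)
  cls <- cc$class[match(classified$column, cc$column)]
  cnt <- function(status, class)
    sum(classified$status == status & cls == class, na.rm = TRUE)
  counts <- c(synPoly = cnt("polymorphic", "synonymous"),
              nonsynPoly = cnt("polymorphic", "nonsynonymous"),
              synFixed = cnt("fixed_divergent", "synonymous"),
              nonsynFixed = cnt("fixed_divergent", "nonsynonymous"))
  p <- fisherExact2x2(counts[1], counts[2], counts[3], counts[4])
  new("MKTable", counts = vapply(counts, as.integer, integer(1)),
      speciesPolymorphism = paste(speciesPolymorphism, collapse = "+"),
      divergenceLineage = divergenceLineage,
      filterApplied = filterApplied, pValue = p)
}

#' Construct an MKTable directly from its four cells
#'
#' @param synPoly,nonsynPoly,synFixed,nonsynFixed table cells
#' @param ... provenance arguments passed to the class
#' @return an [MKTable-class]
#' @export
mkTable <- function(synPoly, nonsynPoly, synFixed, nonsynFixed, ...) {
  counts <- c(synPoly = as.integer(synPoly),
              nonsynPoly = as.integer(nonsynPoly),
              synFixed = as.integer(synFixed),
              nonsynFixed = as.integer(nonsynFixed))
  prov <- list(...)
  new("MKTable", counts = counts,
      speciesPolymorphism = prov$speciesPolymorphism %||% "",
      divergenceLineage = prov$divergenceLineage %||% "",
      filterApplied = prov$filterApplied %||% "none",
      pValue = fisherExact2x2(counts[1], counts[2], counts[3], counts[4]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname tableCounts
#' @export
setMethod("tableCounts", "MKTable", function(x) x@counts)

#' @rdname pValue
#' @export
setMethod("pValue", "MKTable", function(x) x@pValue)

setMethod("show", "MKTable", function(object) {
  cnt <- object@counts
  cat("McDonald-Kreitman table",
      if (nzchar(object@speciesPolymorphism))
        paste0("(polymorphism: ", object@speciesPolymorphism, ")") else "",
      "\n")
  tab <- matrix(cnt, 2, byrow = TRUE,
                dimnames = list(c("Polymorphic", "Fixed divergent"),
                                c("Synonymous", "Nonsynonymous")))
  print(tab)
  if (object@filterApplied != "none")
    cat("filter:", object@filterApplied, "\n")
  cat("Fisher exact P =", signif(object@pValue, 3), "\n")
})

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric computation with the two-tailed point-probability
#' rule: the p-value sums the probabilities of all tables with the
#' observed margins whose probability does not exceed that of the observed
#' table. A table with a zero margin has p = 1.
#'
#' @param a,b,c,d cell counts, row-wise
#'   (`a b` = polymorphic syn/nonsyn, `c d` = fixed syn/nonsyn)
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#' @return the p-value
#' @examples
#' fisherExact2x2(19, 0, 19, 7)   # 0.0156
#' @export
fisherExact2x2 <- function(a, b, c, d, alternative = "two.sided") {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  fisher.test(m, alternative = alternative)$p.value
}

#' Remove low-frequency polymorphisms before the MKT
#'
#' The segregating-deleterious-variant filter: polymorphic sites whose
#' derived-allele frequency (or minor-allele frequency when the site
#' cannot be polarized and `mode = "minor"`) is below `minFreq` are
#' removed from the polymorphism cells. Fixed-divergent sites are never
#' touched.
#'
#' @param classified output of [classifySitesMK()]
#' @param polarized output of [polarize()] for the polymorphism sample
#'   (needs `column`, `i`, `n`, `polarized`)
#' @param minFreq frequency threshold (default 0.15)
#' @param mode `"derived"` (default; unpolarizable variants are excluded
#'   and logged) or `"minor"`
#' @return list with `classified` (filtered), `removed` (columns dropped),
#'   `unresolved` (polymorphic columns lacking frequency information)
#' @export
fwwFilter <- function(classified, polarized, minFreq = 0.15,
                      mode = c("derived", "minor")) {
  mode <- match.arg(mode)
  polyCols <- classified$column[classified$status == "polymorphic"]
  removed <- integer()
  unresolved <- integer()
  if (minFreq <= 0)
    return(list(classified = classified, removed = removed,
                unresolved = unresolved, mode = mode, minFreq = minFreq))
  for (col in polyCols) {
    rec <- polarized[polarized$column == col, , drop = FALSE]
    if (!nrow(rec)) { unresolved <- c(unresolved, col); next }
    freq <- if (mode == "derived") {
      if (!rec$polarized[1]) { unresolved <- c(unresolved, col); next }
      rec$i[1] / rec$n[1]
    } else {
      min(rec$i[1], rec$n[1] - rec$i[1]) / rec$n[1]
    }
    if (!is.na(freq) && freq < minFreq) removed <- c(removed, col)
  }
  drop <- classified$column %in% c(removed, unresolved)
  classified$status[drop & classified$status == "polymorphic"] <- "excluded"
  list(classified = classified, removed = removed, unresolved = unresolved,
       mode = mode, minFreq = minFreq)
}
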