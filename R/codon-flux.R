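# The CF test: fixed synonymous substitutions toward preferred vs
# unpreferred codons along a lineage, against the per-direction site
# opportunities.

#' Assign fixed synonymous changes to a focal lineage by outgroup parsimony
#'
#' A codon-level fixed difference is assigned to the focal lineage iff the
#' focal species is fixed for one codon state and both outgroups share the
#' alternative state (unpolarized two-outgroup parsimony). Assigned changes
#' differing at a single nucleotide are labeled `to_preferred`,
#' `to_unpreferred` or `none` via [preferenceDirection()] using the
#' outgroup codon as ancestral. Changes at codons where the outgroups
#' disagree, the focal sample segregates, a gap/`N` intervenes, or more
#' than one position differs are logged unassigned.
#'
#' @param aln a [SampleAlignment-class]
#' @param focalSpecies focal species name
#' @param outgroupSpecies exactly two outgroup species
#' @param codonMap output of [buildCodonMap()]
#' @param prefTable codon preference table
#' @return data.frame with one row per complete codon carrying a focal vs
#'   outgroup difference: `codon`, `from` (outgroup state), `to` (focal
#'   state), `nDiff`, `synonymous`, `direction`, `assigned`, `reason`
#' @export
assignLineageFixations <- function(aln, focalSpecies, outgroupSpecies,
                                   codonMap, prefTable) {
  stopifnot(length(outgroupSpecies) == 2L)
  m <- alnMatrix(aln)
  focal <- speciesRows(aln, focalSpecies)
  o1 <- speciesRows(aln, outgroupSpecies[1])
  o2 <- speciesRows(aln, outgroupSpecies[2])
  if (!length(focal) || !length(o1) || !length(o2))
    stop("focal or outgroup species missing from alignment")
  gc <- geneticCode()
  map <- codonMap[codonMap$complete, , drop = FALSE]
  res <- list()
  fixedState <- function(rows, cols) {
    sub <- m[rows, cols, drop = FALSE]
    if (any(!sub %in% BASES)) return(NA_character_)
    cs <- unique(apply(sub, 1L, paste, collapse = ""))
    if (length(cs) == 1L) cs else NA_character_
  }
  for (ci in unique(map$codon)) {
    cols <- map$column[map$codon == ci][order(map$pos[map$codon == ci])]
    fc <- fixedState(focal, cols)
    c1 <- fixedState(o1, cols)
    c2 <- fixedState(o2, cols)
    rec <- data.frame(codon = ci, from = NA_character_, to = NA_character_,
                      nDiff = NA_integer_, synonymous = NA,
                      direction = NA_character_, assigned = FALSE,
                      reason = NA_character_)
    if (is.na(fc)) { rec$reason <- "focal_not_fixed"; }
    else if (is.na(c1) || is.na(c2)) { rec$reason <- "outgroup_not_fixed" }
    else if (c1 != c2) { rec$reason <- "outgroup_disagreement" }
    else if (fc == c1) next                       # no change on the lineage
    else {
      nd <- sum(strsplit(fc, "")[[1]] != strsplit(c1, "")[[1]])
      rec$from <- c1; rec$to <- fc; rec$nDiff <- nd
      if (nd > 1L) { rec$reason <- "multi_position" }
      else if (gc[[fc]] == "*" || gc[[c1]] == "*") { rec$reason <- "stop" }
      else {
        rec$synonymous <- gc[[fc]] == gc[[c1]]
        rec$direction <- if (rec$synonymous)
          preferenceDirection(c1, fc, prefTable) else "none"
        rec$assigned <- TRUE
      }
    }
    if (!is.na(rec$reason) || rec$assigned) res[[length(res) + 1L]] <- rec
  }
  if (!length(res))
    return(data.frame(codon = integer(), from = character(),
                      to = character(), nDiff = integer(),
                      synonymous = logical(), direction = character(),
                      assigned = logical(), reason = character()))
  do.call(rbind, res)
}

#' Count preferred/unpreferred substitution opportunities
#'
#' "Sites" in the CF sense are current-state opportunity counts on the
#' focal sequence: a codon that is currently preferred is one opportunity
#' for a change toward unpreferred, and a codon that is currently
#' unpreferred (in a family that has a preferred codon) is one opportunity
#' for a change toward preferred. Codons of single-codon families (Met,
#' Trp) contribute to neither.
#'
#' @param codons character vector of gap-free focal (consensus) codons
#' @param prefTable codon preference table
#' @return named numeric vector `unprefSites` (currently preferred codons)
#'   and `prefSites` (currently unpreferred codons)
#' @export
countCFSites <- function(codons, prefTable) {
  st <- prefStatus(codons, prefTable)
  c(unprefSites = sum(st == "preferred", na.rm = TRUE),
    prefSites = sum(st == "unpreferred", na.rm = TRUE))
}

#' Construct a CFTable
#'
#' @param lineage focal lineage label
#' @param unprefSubs,prefSubs fixed substitutions toward
#'   unpreferred/preferred codons
#' @param unprefSites,prefSites opportunity counts from [countCFSites()]
#' @param method `"chi_square"` (Pearson, no continuity correction;
#'   default) or `"fisher"`
#' @return a [CFTable-class] with the test applied
#' @examples
#' cfTable("example", 6, 11, 174, 29)
#' @export
cfTable <- function(lineage, unprefSubs, prefSubs, unprefSites, prefSites,
                    method = c("chi_square", "fisher")) {
  method <- match.arg(method)
  counts <- c(unprefSubs = unprefSubs, prefSubs = prefSubs,
              unprefSites = unprefSites, prefSites = prefSites)
  tab <- matrix(counts, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(new("CFTable", lineage = lineage, counts = counts,
               testUsed = method, pValue = 1, statistic = NA_real_,
               direction = "No preference"))
  }
  if (method == "chi_square") {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    p <- ct$p.value
    stat <- unname(ct$statistic)
  } else {
    p <- fisherExact2x2(counts[1], counts[2], counts[3], counts[4])
    stat <- NA_real_
  }
  prefRate <- counts["prefSubs"] / counts["prefSites"]
  unprefRate <- counts["unprefSubs"] / counts["unprefSites"]
  direction <- if (p >= 0.05) "No preference"
               else if (prefRate > unprefRate) "Preferred codons favored"
               else "Unpreferred codons favored"
  new("CFTable", lineage = lineage, counts = counts, testUsed = method,
      pValue = p, statistic = stat, direction = direction)
}

#' Re-test an existing CFTable
#'
#' @param table a [CFTable-class]
#' @param method `"chi_square"` or `"fisher"`
#' @return the p-value (the refreshed table is in attribute `"table"`)
#' @export
cfTest <- function(table, method = c("chi_square", "fisher")) {
  method <- match.arg(method)
  cnt <- table@counts
  out <- cfTable(table@lineage, cnt[1], cnt[2], cnt[3], cnt[4], method)
  structure(out@pValue, table = out)
}

#' @rdname tableCounts
#' @export
setMethod("tableCounts", "CFTable", function(x) x@counts)

#' @rdname pValue
#' @export
setMethod("pValue", "CFTable", function(x) x@pValue)

setMethod("show", "CFTable", function(object) {
  cnt <- object@counts
  cat("CF test, lineage:", object@lineage, "\n")
  tab <- matrix(cnt, 2, byrow = TRUE,
                dimnames = list(c("Fixed substitutions", "Sites"),
                                c("Unpreferred", "Preferred")))
  print(tab)
  cat(if (object@testUsed == "chi_square") "chi-square" else "Fisher exact",
      "P =", signif(object@pValue, 3), "--", object@direction, "\n")
})

#' Run the CF test for one focal lineage of an alignment
#'
#' Composes [assignLineageFixations()], [countCFSites()] on the focal
#' species' consensus codons, and [cfTable()].
#'
#' @inheritParams assignLineageFixations
#' @param method test variant, see [cfTable()]
#' @return a [CFTable-class]
#' @export
cfAnalysis <- function(aln, focalSpecies, outgroupSpecies, codonMap,
                       prefTable, method = c("chi_square", "fisher")) {
  fx <- assignLineageFixations(aln, focalSpecies, outgroupSpecies,
                               codonMap, prefTable)
  syn <- fx[fx$assigned & fx$synonymous %in% TRUE, , drop = FALSE]
  m <- alnMatrix(aln)[speciesRows(aln, focalSpecies), , drop = FALSE]
  map <- codonMap[codonMap$complete, , drop = FALSE]
  cons <- vapply(unique(map$codon), function(ci) {
    cols <- map$column[map$codon == ci][order(map$pos[map$codon == ci])]
    sub <- m[, cols, drop = FALSE]
    if (any(!sub %in% BASES)) return(NA_character_)
    # column-wise majority consensus of the focal sample
    paste(apply(sub, 2L, function(x) names(which.max(table(x)))),
          collapse = "")
  }, character(1))
  sites <- countCFSites(cons[!is.na(cons)], prefTable)
  cfTable(focalSpecies,
          sum(syn$direction == "to_unpreferred"),
          sum(syn$direction == "to_preferred"),
          sites[["unprefSites"]], sites[["prefSites"]],
          method = match.arg(method))
}
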