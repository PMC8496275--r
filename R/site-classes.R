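# Synonymous/nonsynonymous/intron site classification, Nei-Gojobori site
# counting, outgroup polarization, and codon-preference direction calls.

geneticCode <- function() Biostrings::GENETIC_CODE

translateCodon <- function(codons) {
  unname(geneticCode()[codons])
}

BASES <- c("A", "C", "G", "T")

# all single-nucleotide neighbours of a codon
codonNeighbours <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (p in 1:3) for (b in setdiff(BASES, ch[p])) {
    x <- ch; x[p] <- b
    out <- c(out, paste(x, collapse = ""))
  }
  out
}

#' Nei-Gojobori fractional synonymous and nonsynonymous site counts
#'
#' Each codon position contributes the fraction of its three possible point
#' mutations that are synonymous; the three positions of a codon therefore
#' always sum to 3 sites. Mutations creating stop codons count as
#' nonsynonymous (equal-weight counting, no transition/transversion bias).
#'
#' @param codons character vector of gap-free sense codons
#' @return data.frame with `codon`, `synSites`, `nonsynSites`; stop codons
#'   yield `NA` rows with a warning.
#' @examples
#' countSites("GGG")  # 1 synonymous, 2 nonsynonymous
#' @export
countSites <- function(codons) {
  gc <- geneticCode()
  one <- function(codon) {
    aa <- gc[[codon]]
    if (is.na(aa) || aa == "*") return(c(NA_real_, NA_real_))
    syn <- 0
    for (p in 1:3) {
      ch <- strsplit(codon, "")[[1]]
      for (b in setdiff(BASES, ch[p])) {
        x <- ch; x[p] <- b
        if (gc[[paste(x, collapse = "")]] == aa) syn <- syn + 1 / 3
      }
    }
    c(syn, 3 - syn)
  }
  bad <- codons[translateCodon(codons) %in% "*"]
  if (length(bad))
    warning("stop codon(s) excluded from site counting: ",
            paste(unique(bad), collapse = ", "))
  res <- t(vapply(codons, one, numeric(2)))
  data.frame(codon = codons, synSites = res[, 1], nonsynSites = res[, 2],
             row.names = NULL)
}

#' Classify alignment columns by mutational effect
#'
#' Labels every alignment column: `intron`, `invariant` (exon, no variation
#' among analyzed rows), `synonymous` (all observed codon variants at the
#' column encode the same amino acid, holding the other codon positions at
#' their observed context), `nonsynonymous`, or `excluded`. Codons
#' segregating at more than one position, codons with mixed
#' synonymous/nonsynonymous variant effects, codons containing an alignment
#' gap in any analyzed row, and observed stop codons are excluded and
#' logged. Rows with `N` inside a codon are dropped for that codon only.
#' Also returns per-codon Nei-Gojobori fractional site counts averaged over
#' the analyzed rows.
#'
#' @param aln a [SampleAlignment-class]
#' @param codonMap output of [buildCodonMap()]
#' @param species restrict the analyzed rows to these species (default: all
#'   rows)
#' @param intronCols intron column indices (1-based); taken from the codon
#'   map complement by default, so pass `intronColumns`-style indices when
#'   the annotation has introns.
#' @return a [SiteClassTable-class]
#' @export
classifyColumns <- function(aln, codonMap, species = NULL,
                            intronCols = integer()) {
  rows <- speciesRows(aln, species)
  m <- alnMatrix(aln)[rows, , drop = FALSE]
  gc <- geneticCode()
  cls <- rep("excluded", alignmentWidth(aln))
  cls[intronCols] <- "intron"
  excl <- list()
  note <- function(unit, id, reason)
    excl[[length(excl) + 1L]] <<- data.frame(unit = unit, id = id,
                                             reason = reason)
  map <- codonMap[codonMap$complete, , drop = FALSE]
  codonIds <- unique(map$codon)
  synSites <- nonsynSites <- rep(NA_real_, length(codonIds))
  names(synSites) <- names(nonsynSites) <- codonIds

  for (ci in codonIds) {
    cols <- map$column[map$codon == ci][order(map$pos[map$codon == ci])]
    sub <- m[, cols, drop = FALSE]
    if (any(sub == "-")) {
      cls[cols] <- "excluded"; note("codon", ci, "gap"); next
    }
    keep <- !apply(sub == "N", 1L, any)
    if (!any(keep)) { cls[cols] <- "excluded"; note("codon", ci, "all_N"); next }
    sub <- sub[keep, , drop = FALSE]
    cstr <- apply(sub, 1L, paste, collapse = "")
    if (any(gc[cstr] == "*")) {
      warning("stop codon observed in codon ", ci, "; codon excluded")
      cls[cols] <- "excluded"; note("codon", ci, "stop"); next
    }
    cs <- countSites(unique(cstr))
    w <- table(cstr)[cs$codon]
    synSites[as.character(ci)] <- sum(cs$synSites * w) / sum(w)
    nonsynSites[as.character(ci)] <- sum(cs$nonsynSites * w) / sum(w)
    varPos <- which(vapply(1:3, function(p) length(unique(sub[, p])) > 1L,
                           logical(1)))
    if (length(varPos) == 0L) { cls[cols] <- "invariant"; next }
    if (length(varPos) > 1L) {
      cls[cols] <- "excluded"; note("codon", ci, "multi_position"); next
    }
    variants <- unique(cstr)
    aas <- unique(gc[variants])
    cls[cols] <- "invariant"
    if (length(aas) == 1L) {
      cls[cols[varPos]] <- "synonymous"
    } else if (length(aas) == length(variants)) {
      cls[cols[varPos]] <- "nonsynonymous"
    } else {
      cls[cols] <- "excluded"; note("codon", ci, "mixed_effect")
    }
  }
  excl <- if (length(excl)) do.call(rbind, excl) else
    data.frame(unit = character(), id = integer(), reason = character())
  new("SiteClassTable",
      columns = data.frame(column = seq_len(alignmentWidth(aln)),
                           class = cls),
      codonSites = data.frame(codon = codonIds,
                              synSites = unname(synSites),
                              nonsynSites = unname(nonsynSites)),
      excluded = excl)
}

setMethod("show", "SiteClassTable", function(object) {
  cat("SiteClassTable\n")
  print(table(object@columns$class))
  cat("effective sites: synonymous ",
      round(sum(object@codonSites$synSites, na.rm = TRUE), 2),
      ", nonsynonymous ",
      round(sum(object@codonSites$nonsynSites, na.rm = TRUE), 2), "\n",
      sep = "")
})

#' @rdname SiteClassTable-class
#' @param x a `SiteClassTable`
#' @export
columnClasses <- function(x) x@columns

#' @rdname SiteClassTable-class
#' @export
codonSiteCounts <- function(x) x@codonSites

#' Polarize ingroup variants against outgroup sequences
#'
#' For every biallelic variable column in one species' population sample,
#' infers the ancestral state as the outgroup state when all outgroup
#' sequences covering the column agree and that state matches one of the
#' two ingroup alleles. Columns failing these rules are returned flagged
#' `polarized = FALSE` with a reason and are excluded from polarized
#' statistics. Ingroup columns are used listwise: any gap or `N` in the
#' focal sample drops the column.
#'
#' @param aln a [SampleAlignment-class]
#' @param species focal ingroup species
#' @param outgroupSpecies species to polarize against (default: all species
#'   with role `"outgroup"`)
#' @param requireTwoOutgroups if `TRUE`, at least two outgroup sequences
#'   must cover and agree at the column
#' @return data.frame with `column`, `ancestral`, `derived`, `i` (derived
#'   allele count), `n` (sample size used), `polarized`, `reason`
#' @export
polarize <- function(aln, species, outgroupSpecies = NULL,
                     requireTwoOutgroups = FALSE) {
  if (is.null(outgroupSpecies)) {
    r <- speciesRoles(aln)
    outgroupSpecies <- names(r)[r == "outgroup"]
  }
  if (!length(outgroupSpecies)) stop("no outgroup species available")
  ing <- alnMatrix(aln)[speciesRows(aln, species), , drop = FALSE]
  out <- alnMatrix(aln)[speciesRows(aln, outgroupSpecies), , drop = FALSE]
  res <- list()
  for (col in seq_len(ncol(ing))) {
    a <- ing[, col]
    if (any(!a %in% BASES)) next           # listwise: gap/N in the sample
    alleles <- unique(a)
    if (length(alleles) < 2L) next
    rec <- data.frame(column = col, ancestral = NA_character_,
                      derived = NA_character_, i = NA_integer_,
                      n = length(a), polarized = FALSE,
                      reason = NA_character_)
    if (length(alleles) > 2L) {
      rec$reason <- "multiallelic"
    } else {
      ob <- out[, col]
      ob <- ob[ob %in% BASES]
      if (length(ob) == 0L) {
        rec$reason <- "no_outgroup"
      } else if (length(unique(ob)) > 1L) {
        rec$reason <- "outgroup_disagreement"
      } else if (requireTwoOutgroups && length(ob) < 2L) {
        rec$reason <- "single_outgroup"
      } else if (!unique(ob) %in% alleles) {
        rec$reason <- "outgroup_mismatch"
      } else {
        anc <- unique(ob)
        der <- setdiff(alleles, anc)
        rec$ancestral <- anc
        rec$derived <- der
        rec$i <- sum(a == der)
        rec$polarized <- TRUE
      }
    }
    res[[length(res) + 1L]] <- rec
  }
  if (!length(res))
    return(data.frame(column = integer(), ancestral = character(),
                      derived = character(), i = integer(), n = integer(),
                      polarized = logical(), reason = character()))
  do.call(rbind, res)
}

#' Read a codon-preference table
#'
#' TSV with columns `codon`, `amino_acid`, `status` where status is
#' `preferred`, `unpreferred` or `not_applicable` (single-codon families
#' and stops).
#'
#' @param path TSV file path
#' @return validated preference data.frame
#' @export
readPreferenceTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  validatePreferenceTable(d)
}

validatePreferenceTable <- function(d) {
  stopifnot(all(c("codon", "amino_acid", "status") %in% names(d)))
  gc <- geneticCode()
  sense <- names(gc)[gc != "*"]
  missing <- setdiff(sense, d$codon)
  if (length(missing))
    stop("preference table misses sense codons: ",
         paste(missing, collapse = ", "))
  if (!all(d$status %in% c("preferred", "unpreferred", "not_applicable")))
    stop("invalid status values in preference table")
  fam <- split(d[d$codon %in% sense, ], d$amino_acid[d$codon %in% sense])
  for (f in fam) {
    if (all(f$status == "not_applicable")) next
    if (!any(f$status == "preferred"))
      stop("amino-acid family ", f$amino_acid[1], " has no preferred codon")
  }
  d
}

#' The bundled Drosophila melanogaster major-codon preference table
#'
#' One preferred (major) codon per amino-acid family, the remaining sense
#' codons unpreferred; Met and Trp are `not_applicable`. Shipped as plain
#' TSV config data (`inst/extdata/dmel_preference.tsv`); analyses record
#' the species tag of whichever table they were given.
#'
#' @return preference data.frame (see [readPreferenceTable()])
#' @export
defaultPreferenceTable <- function() {
  readPreferenceTable(system.file("extdata", "dmel_preference.tsv",
                                  package = "PopGenFlux", mustWork = TRUE))
}

prefStatus <- function(codons, prefTable) {
  prefTable$status[match(codons, prefTable$codon)]
}

#' Direction of a synonymous codon change under a preference table
#'
#' @param fromCodon,toCodon ancestral and derived codons (character
#'   vectors, recycled)
#' @param prefTable preference table (see [readPreferenceTable()])
#' @return character vector in `to_preferred`, `to_unpreferred`, `none`
#'   (`none` when both codons share a preference category or the family is
#'   not applicable)
#' @export
preferenceDirection <- function(fromCodon, toCodon, prefTable) {
  from <- prefStatus(fromCodon, prefTable)
  to <- prefStatus(toCodon, prefTable)
  out <- rep("none", length(to))
  ok <- !is.na(from) & !is.na(to) & from != "not_applicable" &
    to != "not_applicable" & from != to
  out[ok & to == "preferred"] <- "to_preferred"
  out[ok & to == "unpreferred"] <- "to_unpreferred"
  out
}
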