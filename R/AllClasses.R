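#' @import methods
#' @importFrom stats chisq.test fisher.test rpois runif setNames var sd
#' @importFrom utils read.delim write.table packageVersion
NULL

setOldClass("phylo")

ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' SampleAlignment: a multi-species population alignment
#'
#' Holds an aligned set of DNA sequences with per-sample species labels and
#' per-species roles (`ingroup_population` or `outgroup`). Rows are samples,
#' columns are alignment positions; the alphabet is restricted to
#' `A,C,G,T,N,-`. This is the coordinate frame on which every downstream
#' count (site classes, polymorphism, divergence, MK and CF tables) is
#' defined.
#'
#' @slot matrix character matrix, one row per sample, single upper-case
#'   IUPAC characters from `A,C,G,T,N,-`; rownames are sample labels.
#' @slot speciesOf named character vector mapping sample label to species.
#' @slot roles named character vector mapping species to role, one of
#'   `"ingroup_population"` or `"outgroup"`.
#'
#' @seealso [readAlignment()], [sampleAlignment()]
#' @export
setClass("SampleAlignment",
  representation(matrix = "matrix", speciesOf = "character",
                 roles = "character"))

setValidity("SampleAlignment", function(object) {
  m <- object@matrix
  msgs <- character()
  if (!is.character(m)) msgs <- c(msgs, "alignment matrix must be character")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msgs <- c(msgs, "rows must carry unique sample labels")
  bad <- setdiff(unique(as.vector(m)), ALN_ALPHABET)
  if (length(bad))
    msgs <- c(msgs, paste0("invalid characters in alignment: ",
                           paste(bad, collapse = ", ")))
  if (!all(rownames(m) %in% names(object@speciesOf)))
    msgs <- c(msgs, "speciesOf must cover every sample label")
  sp <- unique(unname(object@speciesOf[rownames(m)]))
  if (!all(sp %in% names(object@roles)))
    msgs <- c(msgs, "roles must cover every species present")
  if (length(object@roles) &&
      !all(object@roles %in% c("ingroup_population", "outgroup")))
    msgs <- c(msgs, "roles must be 'ingroup_population' or 'outgroup'")
  if (length(msgs)) msgs else TRUE
})

#' RegionAnnotation: exon/intron segmentation of an alignment
#'
#' Ordered, non-overlapping segments partitioning (part of) the alignment
#' into exons and introns. Coordinates are 0-based half-open internally;
#' human-readable reports render 1-based inclusive.
#'
#' @slot segments data.frame with columns `start`, `end` (0-based half-open),
#'   `kind` (`"exon"` or `"intron"`) and `phase` (0/1/2 for exons: the
#'   position-in-codon of the first exon column; `NA` for introns).
#' @export
setClass("RegionAnnotation", representation(segments = "data.frame"))

setValidity("RegionAnnotation", function(object) {
  s <- object@segments
  msgs <- character()
  need <- c("start", "end", "kind", "phase")
  if (!all(need %in% names(s)))
    return("segments needs columns start, end, kind, phase")
  if (nrow(s)) {
    if (any(s$end <= s$start)) msgs <- c(msgs, "empty or inverted segment")
    if (any(s$start < 0)) msgs <- c(msgs, "negative coordinate")
    if (is.unsorted(s$start, strictly = TRUE))
      msgs <- c(msgs, "segments must be sorted by start")
    if (any(s$start[-1] < s$end[-nrow(s)]))
      msgs <- c(msgs, "segments overlap")
    if (!all(s$kind %in% c("exon", "intron")))
      msgs <- c(msgs, "kind must be exon or intron")
    ph <- s$phase[s$kind == "exon"]
    if (any(!ph %in% 0:2)) msgs <- c(msgs, "exon phase must be 0, 1 or 2")
  }
  if (length(msgs)) msgs else TRUE
})

#' SiteClassTable: per-column classes and per-codon site counts
#'
#' @slot columns data.frame with `column` (1-based alignment column) and
#'   `class` in `synonymous`, `nonsynonymous`, `intron`, `invariant`,
#'   `excluded`.
#' @slot codonSites data.frame with `codon` (0-based index), `synSites`,
#'   `nonsynSites` (Nei-Gojobori fractional counts averaged over analyzed
#'   rows; `NA` for excluded codons).
#' @slot excluded data.frame logging excluded codons/columns with reasons.
#' @export
setClass("SiteClassTable",
  representation(columns = "data.frame", codonSites = "data.frame",
                 excluded = "data.frame"))

#' MKTable: a McDonald-Kreitman 2x2 contingency table
#'
#' @slot counts named integer vector: `synPoly`, `nonsynPoly`, `synFixed`,
#'   `nonsynFixed`.
#' @slot speciesPolymorphism species whose polymorphism fills the table.
#' @slot divergenceLineage free-text description of the divergence lineage.
#' @slot filterApplied description of any variant-frequency filter.
#' @slot pValue two-tailed Fisher exact p-value.
#' @export
setClass("MKTable",
  representation(counts = "integer", speciesPolymorphism = "character",
                 divergenceLineage = "character", filterApplied = "character",
                 pValue = "numeric"))

setValidity("MKTable", function(object) {
  msgs <- character()
  if (!identical(names(object@counts),
                 c("synPoly", "nonsynPoly", "synFixed", "nonsynFixed")))
    msgs <- c(msgs, "counts must be synPoly, nonsynPoly, synFixed, nonsynFixed")
  if (any(object@counts < 0)) msgs <- c(msgs, "counts must be non-negative")
  if (length(object@pValue) &&
      (object@pValue < 0 || object@pValue > 1 + 1e-12))
    msgs <- c(msgs, "p-value out of [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' CFTable: preferred/unpreferred substitution flux table for one lineage
#'
#' @slot lineage focal lineage label.
#' @slot counts named numeric vector: `unprefSubs`, `prefSubs`,
#'   `unprefSites`, `prefSites`.
#' @slot testUsed `"chi_square"` or `"fisher"`.
#' @slot pValue test p-value.
#' @slot statistic chi-square statistic (`NA` for Fisher).
#' @slot direction direction of departure, as rendered in reports.
#' @export
setClass("CFTable",
  representation(lineage = "character", counts = "numeric",
                 testUsed = "character", pValue = "numeric",
                 statistic = "numeric", direction = "character"))

setValidity("CFTable", function(object) {
  msgs <- character()
  if (!identical(names(object@counts),
                 c("unprefSubs", "prefSubs", "unprefSites", "prefSites")))
    msgs <- c(msgs, "counts must be unprefSubs, prefSubs, unprefSites, prefSites")
  if (any(object@counts < 0)) msgs <- c(msgs, "counts must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' SubstitutionMap: parsimony-mapped amino-acid substitutions on a tree
#'
#' @slot tree rooted `phylo` tree whose tips match the alignment taxa.
#' @slot events data.frame, one row per inferred substitution: `branch`
#'   (label of the child node of the edge), `codon` (1-based codon index),
#'   `from`, `to` (amino acids), `ambiguous` (logical: alternative equally
#'   parsimonious placements exist).
#' @slot codonCounts integer vector of per-codon parsimony scores (`NA` for
#'   codons excluded because of alignment gaps).
#' @export
setClass("SubstitutionMap",
  representation(tree = "phylo", events = "data.frame",
                 codonCounts = "integer"))

#' DemographicModel: population-size history for the coalescent simulator
#'
#' Piecewise-exponential history in coalescent units (time in units of 2N0
#' generations, sizes relative to the present-day size N0). Within an epoch
#' starting at `start` with `size` s and `growth` g, the relative size at
#' time t (backwards) is `s * exp(-g * (t - start))`.
#'
#' @slot kind one of `"equilibrium"`, `"exponential_growth"`,
#'   `"three_epoch_bottleneck"`.
#' @slot epochs data.frame with `start`, `size`, `growth`.
#' @slot params named numeric vector of the kind-specific parameters used to
#'   build `epochs` (empty for equilibrium).
#' @export
setClass("DemographicModel",
  representation(kind = "character", epochs = "data.frame",
                 params = "numeric"))

setValidity("DemographicModel", function(object) {
  e <- object@epochs
  msgs <- character()
  if (!all(c("start", "size", "growth") %in% names(e)))
    return("epochs needs columns start, size, growth")
  if (e$start[1] != 0) msgs <- c(msgs, "first epoch must start at 0")
  if (is.unsorted(e$start, strictly = TRUE))
    msgs <- c(msgs, "epoch start times must be strictly increasing")
  if (any(e$size <= 0)) msgs <- c(msgs, "relative sizes must be > 0")
  if (e$growth[nrow(e)] < 0)
    msgs <- c(msgs, "final epoch growth must be >= 0 (lineages must coalesce)")
  if (length(msgs)) msgs else TRUE
})

#' SimulationConfig: one coalescent simulation setting
#'
#' @slot n sample size (haploid sequences).
#' @slot L number of sites the locus maps onto (used when threading
#'   mutations onto sequences and for per-site rates).
#' @slot thetaPerSite population mutation rate per site (theta_locus =
#'   thetaPerSite * L).
#' @slot R population recombination parameter for the whole region.
#' @slot model a [DemographicModel-class].
#' @slot replicates default replicate count for null distributions.
#' @export
setClass("SimulationConfig",
  representation(n = "integer", L = "integer", thetaPerSite = "numeric",
                 R = "numeric", model = "DemographicModel",
                 replicates = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@n < 2L) msgs <- c(msgs, "n must be >= 2")
  if (object@L < 1L) msgs <- c(msgs, "L must be >= 1")
  if (object@thetaPerSite <= 0) msgs <- c(msgs, "thetaPerSite must be > 0")
  if (object@R < 0) msgs <- c(msgs, "R must be >= 0")
  if (object@replicates < 1L) msgs <- c(msgs, "replicates must be >= 1")
  if (length(msgs)) msgs else TRUE
})
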