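# High-level runners composing the module operations into the standard
# reports, with manifest-logged reproducible output. These are the
# programmatic entry points; inst/scripts/popgenflux.R exposes them to the
# shell.

writeManifest <- function(out, config, seed = NULL) {
  manifest <- list(config = config, seed = seed,
                   package = "PopGenFlux",
                   version = as.character(packageVersion("PopGenFlux")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

ensureOut <- function(out) {
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  out
}

#' Per-class diversity/divergence report for one species
#'
#' Composes [summaryStatistics()] and renders the standard report layout
#' (rows: site class; columns: theta, pi, divergence) plus the
#' whole-region Tajima's D and Fay and Wu's H, as TSV and JSON.
#'
#' @param aln a [SampleAlignment-class]
#' @param ann a [RegionAnnotation-class]
#' @param species focal ingroup species
#' @param divergenceSpecies optional species for the divergence column
#' @param outgroupSpecies optional polarization outgroups (default: role)
#' @param out optional output directory; when given, writes
#'   `sumstats.tsv`, `sumstats.json` and `manifest.json`
#' @return the `summaryStatistics` object, invisibly when writing
#' @export
runSumstats <- function(aln, ann, species, divergenceSpecies = NULL,
                        outgroupSpecies = NULL, out = NULL) {
  st <- summaryStatistics(aln, ann, species, divergenceSpecies,
                          outgroupSpecies)
  if (!is.null(out)) {
    ensureOut(out)
    write.table(st$perClass, file.path(out, "sumstats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(perClass = st$perClass, tajimaD = st$tajimaD,
           fayWuH = st$fayWuH, S = st$S, piTotal = st$piTotal, n = st$n,
           singletons = st$singletons),
      file.path(out, "sumstats.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    writeManifest(out, list(species = species,
                            divergenceSpecies = divergenceSpecies))
    return(invisible(st))
  }
  st
}

#' Empirical p-values of observed statistics under simulated scenarios
#'
#' For each named demographic scenario, simulates a null distribution per
#' statistic and converts the observed values into empirical p-values
#' (lower tail for negative observations, upper for positive), with
#' Bonferroni-adjusted decisions across the statistics within each
#' scenario.
#'
#' @param observed named numeric vector of observed statistics; names must
#'   be `"D"` and/or `"H"`
#' @param scenarios named list of [SimulationConfig-class] objects
#' @param priors optional named list of prior bounds shared by all
#'   scenarios (see [nullDistribution()])
#' @param replicates overrides each config's replicate count
#' @param familyAlpha Bonferroni family level (default 0.025 per tail
#'   family)
#' @param seed optional RNG seed
#' @param out optional output directory
#' @return data.frame with one row per statistic x scenario: `statistic`,
#'   `scenario`, `observed`, `tail`, `p`, `display`, `cutoff`, `reject`
#' @export
runNeutrality <- function(observed, scenarios, priors = NULL,
                          replicates = NULL, familyAlpha = 0.025,
                          seed = NULL, out = NULL) {
  if (!is.null(seed)) set.seed(seed)
  statFns <- list(
    D = function(sim, n) { s <- simStats(sim, n); s[["D"]] },
    H = function(sim, n) { s <- simStats(sim, n); s[["H"]] })
  stopifnot(all(names(observed) %in% names(statFns)))
  rows <- list()
  for (sc in names(scenarios)) {
    ps <- numeric(0)
    for (st in names(observed)) {
      nd <- nullDistribution(scenarios[[sc]], statFns[[st]],
                             priors = priors, replicates = replicates)
      tail <- if (observed[[st]] < 0) "lower" else "upper"
      ep <- empiricalPValue(observed[[st]], nd, tail)
      rows[[length(rows) + 1L]] <- data.frame(
        statistic = st, scenario = sc, observed = observed[[st]],
        tail = tail, p = ep$p, display = ep$display)
      ps <- c(ps, ep$p)
    }
    k <- length(ps)
    bf <- bonferroni(ps, familyAlpha, k)
    idx <- seq.int(length(rows) - k + 1L, length(rows))
    for (j in seq_len(k)) {
      rows[[idx[j]]]$cutoff <- bf$cutoff[j]
      rows[[idx[j]]]$reject <- bf$reject[j]
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(out)) {
    ensureOut(out)
    write.table(res, file.path(out, "neutrality.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(res, file.path(out, "neutrality.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeManifest(out, list(observed = as.list(observed),
                            scenarios = names(scenarios),
                            familyAlpha = familyAlpha), seed)
  }
  res
}

#' McDonald-Kreitman test report
#'
#' Composes [classifySitesMK()], [classifyColumns()], optionally
#' [fwwFilter()], and [buildMKTable()].
#'
#' @param aln a [SampleAlignment-class]
#' @param ann a [RegionAnnotation-class]
#' @param polymorphismSpecies species contributing polymorphism (one, or
#'   two for the combined-polymorphism variant)
#' @param species all species in the comparison (default: all in `aln`)
#' @param fwwMinFreq when non-`NULL`, apply the low-frequency filter at
#'   this threshold (0.15 is customary)
#' @param out optional output directory
#' @return an [MKTable-class]
#' @export
runMKT <- function(aln, ann, polymorphismSpecies, species = NULL,
                   fwwMinFreq = NULL, out = NULL) {
  map <- buildCodonMap(ann)
  sct <- classifyColumns(aln, map, intronCols = intronColumns(ann))
  cls <- classifySitesMK(aln, polymorphismSpecies, species)
  filterDesc <- "none"
  if (!is.null(fwwMinFreq)) {
    pol <- do.call(rbind, lapply(polymorphismSpecies, function(sp)
      polarize(aln, sp)))
    fl <- fwwFilter(cls, pol, fwwMinFreq)
    cls <- fl$classified
    filterDesc <- sprintf("derived frequency < %g removed", fwwMinFreq)
  }
  tab <- buildMKTable(cls, sct,
                      speciesPolymorphism = polymorphismSpecies,
                      divergenceLineage = paste(
                        setdiff(unique(speciesOf(aln)),
                                polymorphismSpecies), collapse = "+"),
                      filterApplied = filterDesc)
  if (!is.null(out)) {
    ensureOut(out)
    cnt <- tableCounts(tab)
    d <- data.frame(row = c("Polymorphic", "Fixed divergent"),
                    Synonymous = cnt[c("synPoly", "synFixed")],
                    Nonsynonymous = cnt[c("nonsynPoly", "nonsynFixed")],
                    p = c(NA, pValue(tab)))
    write.table(d, file.path(out, "mkt.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(list(counts = as.list(cnt), p = pValue(tab),
                              filter = filterDesc),
                         file.path(out, "mkt.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    writeManifest(out, list(polymorphismSpecies = polymorphismSpecies,
                            fwwMinFreq = fwwMinFreq))
  }
  tab
}

#' CF test report for one or more focal lineages
#'
#' @param aln a [SampleAlignment-class]
#' @param ann a [RegionAnnotation-class]
#' @param lineages named list: each element `c(focal, outgroup1,
#'   outgroup2)`
#' @param prefTable preference table (default: bundled table)
#' @param method `"chi_square"` or `"fisher"`
#' @param out optional output directory
#' @return named list of [CFTable-class] objects
#' @export
runCF <- function(aln, ann, lineages, prefTable = NULL,
                  method = c("chi_square", "fisher"), out = NULL) {
  method <- match.arg(method)
  if (is.null(prefTable)) prefTable <- defaultPreferenceTable()
  map <- buildCodonMap(ann)
  res <- lapply(lineages, function(tri)
    cfAnalysis(aln, tri[1], tri[2:3], map, prefTable, method))
  names(res) <- names(lineages)
  if (!is.null(out)) {
    ensureOut(out)
    d <- do.call(rbind, lapply(names(res), function(nm) {
      cnt <- tableCounts(res[[nm]])
      data.frame(lineage = nm, unprefSubs = cnt[1], prefSubs = cnt[2],
                 unprefSites = cnt[3], prefSites = cnt[4],
                 p = pValue(res[[nm]]), direction = res[[nm]]@direction)
    }))
    write.table(d, file.path(out, "cf.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeManifest(out, list(lineages = lineages, method = method))
  }
  res
}

#' Substitution-map report
#'
#' Composes [fitchCount()], [multipleHitSummary()] and
#' [regionHeterogeneityTest()].
#'
#' @param tree rooted `phylo`
#' @param codonMat taxa x codons character matrix of codons
#' @param partition output of [regionPartition()] (or `NULL` to skip the
#'   heterogeneity test)
#' @param out optional output directory
#' @return list with `map`, `multipleHits`, `heterogeneity`
#' @export
runSubstMap <- function(tree, codonMat, partition = regionPartition(),
                        out = NULL) {
  map <- fitchCount(tree, translateCodonMatrix(codonMat))
  mh <- multipleHitSummary(map)
  het <- if (!is.null(partition))
    regionHeterogeneityTest(map, partition) else NULL
  if (!is.null(out)) {
    ensureOut(out)
    write.table(substEvents(map), file.path(out, "substitutions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(
      totalSubstitutions = sum(codonHits(map), na.rm = TRUE),
      codonsHit = mh$codonsHit, codonsHitMultiply = mh$codonsHitMultiply,
      heterogeneity = if (!is.null(het))
        list(chisq = het$statistic, p = het$p) else NULL),
      file.path(out, "substmap.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    writeManifest(out, list(partition = partition))
  }
  list(map = map, multipleHits = mh, heterogeneity = het)
}
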