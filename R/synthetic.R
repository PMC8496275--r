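# Seed-deterministic synthetic data with complete truth logs: coalescent
# population samples threaded onto codon-structured loci, tree-evolved
# codon sequences, and exact-count MK fixtures.

# enumerate plantable point mutations of a given effect class
availableSites <- function(ancestral, ann, codonMap) {
  gc <- geneticCode()
  map <- codonMap[codonMap$complete, , drop = FALSE]
  out <- list()
  for (ci in unique(map$codon)) {
    cols <- map$column[map$codon == ci][order(map$pos[map$codon == ci])]
    cod <- paste(ancestral[cols], collapse = "")
    if (is.na(gc[cod]) || gc[cod] == "*") next
    for (p in 1:3) for (b in setdiff(BASES, ancestral[cols[p]])) {
      ch <- strsplit(cod, "")[[1]]; ch[p] <- b
      alt <- paste(ch, collapse = "")
      if (gc[alt] == "*") next
      cls <- if (gc[alt] == gc[cod]) "synonymous" else "nonsynonymous"
      out[[length(out) + 1L]] <- data.frame(
        column = cols[p], class = cls, ancestral = ancestral[cols[p]],
        derived = b)
    }
  }
  for (col in intronColumns(ann)) {
    for (b in setdiff(BASES, ancestral[col]))
      out[[length(out) + 1L]] <- data.frame(
        column = col, class = "intron", ancestral = ancestral[col],
        derived = b)
  }
  do.call(rbind, out)
}

#' Generate a population alignment with known truth
#'
#' Simulates coalescent haplotypes under `cfg` and threads the resulting
#' infinite-sites mutations onto an ancestral codon-structured sequence,
#' drawing each variant's site class (synonymous / nonsynonymous / intron)
#' from `classMix` and placing it at an unused column where such a change
#' is possible. Outgroup sequences are emitted from the ancestral state,
#' optionally with additional fixed differences on the outgroup lineage.
#' The truth log records every planted variant exactly once.
#'
#' @param cfg a [SimulationConfig-class] (`cfg@L` must equal the ancestral
#'   length)
#' @param ancestralSeq ancestral sequence (single string or character
#'   vector)
#' @param ann a [RegionAnnotation-class] for the ancestral sequence
#' @param classMix named probabilities for `synonymous`, `nonsynonymous`,
#'   `intron` (need not sum to 1; classes with no available sites must
#'   have weight 0)
#' @param nOutgroup number of outgroup sequences (identical by design)
#' @param outgroupDivergence number of extra fixed differences planted on
#'   the outgroup lineage (0 keeps outgroups exactly ancestral)
#' @param seed optional RNG seed (`set.seed`)
#' @return list with `alignment` ([SampleAlignment-class]; ingroup species
#'   `"popA"`, outgroup `"outA"`), `truth` (data.frame: `column`, `class`,
#'   `ancestral`, `derived`, `i`, `lineage`), `annotation`
#' @export
makePopulationAlignment <- function(cfg, ancestralSeq, ann,
                                    classMix = c(synonymous = 0.3,
                                                 nonsynonymous = 0.1,
                                                 intron = 0.6),
                                    nOutgroup = 1, outgroupDivergence = 0,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  anc <- if (length(ancestralSeq) == 1L) strsplit(ancestralSeq, "")[[1]]
         else ancestralSeq
  stopifnot(cfg@L == length(anc))
  map <- buildCodonMap(ann)
  pool <- availableSites(anc, ann, map)
  sim <- simulateReplicate(cfg)
  S <- sim$S
  nOutMut <- outgroupDivergence
  truth <- list()
  usedCols <- integer()
  drawSite <- function(wanted) {
    cand <- pool[pool$class == wanted & !pool$column %in% usedCols, ,
                 drop = FALSE]
    if (!nrow(cand))
      stop("requested variants exceed available ", wanted, " sites")
    # one variant per column (infinite sites): pick a column, then a change
    col <- sample(unique(cand$column), 1L)
    cand <- cand[cand$column == col, , drop = FALSE]
    cand[sample(nrow(cand), 1L), , drop = FALSE]
  }
  classes <- names(classMix)
  ingroupSites <- list()
  for (s in seq_len(S)) {
    wanted <- sample(classes, 1L, prob = classMix)
    site <- drawSite(wanted)
    usedCols <- c(usedCols, site$column)
    ingroupSites[[s]] <- site
  }
  n <- cfg@n
  mat <- matrix(rep(anc, n), nrow = n, byrow = TRUE)
  for (s in seq_len(S)) {
    site <- ingroupSites[[s]]
    carriers <- sim$genotypes[, s] == 1L
    mat[carriers, site$column] <- site$derived
    truth[[length(truth) + 1L]] <- cbind(site, i = sum(carriers),
                                         lineage = "ingroup")
  }
  outSeq <- anc
  for (s in seq_len(nOutMut)) {
    wanted <- sample(classes, 1L, prob = classMix)
    site <- drawSite(wanted)
    usedCols <- c(usedCols, site$column)
    outSeq[site$column] <- site$derived
    truth[[length(truth) + 1L]] <- cbind(site, i = NA_integer_,
                                         lineage = "outgroup")
  }
  labels <- c(paste0("popA_", seq_len(n)),
              if (nOutgroup > 0) paste0("outA_", seq_len(nOutgroup)))
  full <- rbind(mat,
                matrix(rep(outSeq, nOutgroup), nrow = nOutgroup,
                       byrow = TRUE))
  rownames(full) <- labels
  speciesOf <- setNames(c(rep("popA", n), rep("outA", nOutgroup)), labels)
  aln <- sampleAlignment(full, speciesOf,
                         c(popA = "ingroup_population", outA = "outgroup"))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(column = integer(), class = character(),
               ancestral = character(), derived = character(),
               i = integer(), lineage = character())
  list(alignment = aln, truth = truth, annotation = ann)
}

#' Evolve codon sequences along a tree with a logged event history
#'
#' Markov codon substitution along each branch: events arrive at rate
#' `rates["nonsynonymous"] + rates["synonymous"]` per codon per unit
#' branch length; each event picks a random codon and replaces it with a
#' random single-nucleotide neighbour of the requested effect class
#' (synonymous moves are drawn toward a preferred codon with probability
#' `prefBias` when both directions are available). Every applied event is
#' logged with its branch and codon.
#'
#' @param tree rooted `phylo` with branch lengths
#' @param ancestralCodons character vector of sense codons at the root
#' @param rates named numeric: `nonsynonymous`, `synonymous` (events per
#'   codon per unit branch length)
#' @param prefBias probability that a synonymous event moves toward a
#'   preferred codon when a choice exists (0.5 = symmetric flux)
#' @param prefTable preference table (only needed when `prefBias != 0.5`
#'   or for direction logging; defaults to the bundled table)
#' @param seed optional RNG seed
#' @return list with `tipCodons` (taxa x codons character matrix),
#'   `events` (data.frame: `branch` = child node label, `codon`,
#'   `fromCodon`, `toCodon`, `fromAA`, `toAA`, `type`, `direction`)
#' @export
evolveOnTree <- function(tree, ancestralCodons,
                         rates = c(nonsynonymous = 0.02,
                                   synonymous = 0.05),
                         prefBias = 0.5, prefTable = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            all(rates >= 0))
  if (is.null(prefTable)) prefTable <- defaultPreferenceTable()
  gc <- geneticCode()
  ntip <- length(tree$tip.label)
  nodeLabel <- function(v) if (v <= ntip) tree$tip.label[v]
                           else paste0("node_", v)
  nCodon <- length(ancestralCodons)
  seqs <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  seqs[[root]] <- ancestralCodons
  events <- list()
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(seq_len(nrow(po$edge)))       # preorder traversal
  for (e in ord) {
    par <- po$edge[e, 1]; child <- po$edge[e, 2]
    len <- po$edge.length[e]
    cur <- seqs[[par]]
    total <- len * nCodon * sum(rates)
    k <- if (total > 0) rpois(1, total) else 0L
    for (ev in seq_len(k)) {
      type <- sample(names(rates), 1L, prob = rates)
      for (try in 1:50) {
        ci <- sample.int(nCodon, 1L)
        cod <- cur[ci]
        nb <- codonNeighbours(cod)
        nb <- nb[gc[nb] != "*"]
        cand <- if (type == "synonymous") nb[gc[nb] == gc[cod]]
                else nb[gc[nb] != gc[cod]]
        if (!length(cand)) next
        if (type == "synonymous" && length(cand) > 1L) {
          dir <- preferenceDirection(cod, cand, prefTable)
          toPref <- cand[dir == "to_preferred"]
          toUnpref <- cand[dir != "to_preferred"]
          cand <- if (length(toPref) && runif(1) < prefBias) toPref
                  else if (length(toUnpref)) toUnpref else toPref
        }
        to <- cand[sample.int(length(cand), 1L)]
        events[[length(events) + 1L]] <- data.frame(
          branch = nodeLabel(child), codon = ci, fromCodon = cod,
          toCodon = to, fromAA = unname(gc[cod]), toAA = unname(gc[to]),
          type = type,
          direction = preferenceDirection(cod, to, prefTable))
        cur[ci] <- to
        break
      }
    }
    seqs[[child]] <- cur
  }
  tips <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(tips) <- tree$tip.label
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(branch = character(), codon = integer(),
               fromCodon = character(), toCodon = character(),
               fromAA = character(), toAA = character(),
               type = character(), direction = character())
  list(tipCodons = tips, events = events)
}

#' Build a three-species alignment with exact MK table counts
#'
#' Constructs an alignment of three species (`spA` with a population
#' sample, `spB` and `spC` single or multi-sequence) whose
#' [classifySitesMK()] + [buildMKTable()] output recovers the requested
#' cell counts exactly. Each planted event occupies its own codon; one
#' buffer invariant codon separates events.
#'
#' @param counts named or positional vector `(synPoly, nonsynPoly,
#'   synFixed, nonsynFixed)`
#' @param nPerSpecies samples per species, length 3 (first entry >= 2)
#' @param seed optional RNG seed
#' @return list with `alignment`, `annotation`, `counts`,
#'   `polymorphismSpecies` (= `"spA"`)
#' @export
makeMKFixture <- function(counts, nPerSpecies = c(6L, 2L, 1L),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- setNames(as.integer(counts),
                     c("synPoly", "nonsynPoly", "synFixed", "nonsynFixed"))
  stopifnot(all(counts >= 0), length(nPerSpecies) == 3L,
            nPerSpecies[1] >= 2L)
  gc <- geneticCode()
  # codons offering both a synonymous and a nonsynonymous one-step change
  base <- names(gc)[gc != "*"]
  versatile <- base[vapply(base, function(cod) {
    nb <- codonNeighbours(cod)
    nb <- nb[gc[nb] != "*"]
    any(gc[nb] == gc[cod]) && any(gc[nb] != gc[cod])
  }, logical(1))]
  nEvents <- sum(counts)
  nCodon <- nEvents + 2L
  anc <- sample(versatile, nCodon, replace = TRUE)
  plan <- rep(names(counts), counts)
  if (length(plan)) plan <- sample(plan)          # shuffle event order
  nA <- nPerSpecies[1]; nB <- nPerSpecies[2]; nC <- nPerSpecies[3]
  seqA <- matrix(rep(anc, nA), nrow = nA, byrow = TRUE)
  seqB <- matrix(rep(anc, nB), nrow = nB, byrow = TRUE)
  seqC <- matrix(rep(anc, nC), nrow = nC, byrow = TRUE)
  pickAlt <- function(cod, syn) {
    nb <- codonNeighbours(cod)
    nb <- nb[gc[nb] != "*"]
    cand <- if (syn) nb[gc[nb] == gc[cod]] else nb[gc[nb] != gc[cod]]
    cand[sample.int(length(cand), 1L)]
  }
  for (k in seq_along(plan)) {
    ci <- k                               # one codon per event
    syn <- plan[k] %in% c("synPoly", "synFixed")
    alt <- pickAlt(anc[ci], syn)
    if (plan[k] %in% c("synPoly", "nonsynPoly")) {
      carriers <- sample.int(nA, sample.int(nA - 1L, 1L))
      seqA[carriers, ci] <- alt
    } else {
      seqA[, ci] <- alt                   # fixed on the spA lineage
    }
  }
  toBases <- function(m) {
    out <- do.call(cbind, lapply(seq_len(ncol(m)), function(j)
      do.call(rbind, strsplit(m[, j], ""))))
    out
  }
  full <- rbind(toBases(seqA), toBases(seqB), toBases(seqC))
  labels <- c(paste0("spA_", seq_len(nA)), paste0("spB_", seq_len(nB)),
              paste0("spC_", seq_len(nC)))
  rownames(full) <- labels
  speciesOf <- setNames(rep(c("spA", "spB", "spC"), c(nA, nB, nC)), labels)
  aln <- sampleAlignment(full, speciesOf,
                         c(spA = "ingroup_population", spB = "outgroup",
                           spC = "outgroup"))
  ann <- regionAnnotation(0L, 3L * nCodon, "exon")
  list(alignment = aln, annotation = ann, counts = counts,
       polymorphismSpecies = "spA")
}
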