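# Parsimony mapping of amino-acid substitutions onto a species tree and
# regional heterogeneity tests.

#' Translate a codon matrix to amino acids
#'
#' @param codonMat character matrix of codons (taxa x codon positions);
#'   entries containing gaps or ambiguity characters translate to `NA`
#' @return character matrix of single-letter amino acids
#' @export
translateCodonMatrix <- function(codonMat) {
  gc <- geneticCode()
  out <- matrix(gc[codonMat], nrow = nrow(codonMat),
                dimnames = dimnames(codonMat))
  out
}

#' Map amino-acid substitutions onto a tree by Fitch parsimony
#'
#' For every codon, computes the Fitch parsimony minimum number of
#' amino-acid substitutions on the rooted tree and assigns each
#' substitution to a branch using one deterministic minimal resolution:
#' state sets are built tip-to-root (intersection where non-empty, union
#' otherwise), then states are fixed root-to-tip, a node inheriting its
#' parent's state whenever that state is in the node's set and otherwise
#' taking the alphabetically first member (which places changes as deep in
#' the tree as the minimum allows). Placements where a state set held more
#' than one candidate are flagged `ambiguous`. Codons with a gap or
#' untranslatable state in any taxon are excluded symmetrically.
#'
#' @param tree rooted binary `phylo` object; tip labels must match the
#'   rownames of `aaMat`
#' @param aaMat character matrix of single-letter amino acids (taxa x
#'   codons), e.g. from [translateCodonMatrix()]
#' @return a [SubstitutionMap-class]
#' @export
fitchCount <- function(tree, aaMat) {
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  missing <- setdiff(tree$tip.label, rownames(aaMat))
  if (length(missing))
    stop("no sequence for tip(s): ", paste(missing, collapse = ", "))
  aaMat <- aaMat[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  postorder <- ape::reorder.phylo(tree, "postorder")$edge
  root <- ntip + 1L
  nCodon <- ncol(aaMat)
  codonCounts <- rep(NA_integer_, nCodon)
  events <- list()

  for (cd in seq_len(nCodon)) {
    tipStates <- aaMat[, cd]
    if (any(is.na(tipStates) | tipStates %in% c("-", "X", "*"))) next
    sets <- vector("list", ntip + nnode)
    for (i in seq_len(ntip)) sets[[i]] <- tipStates[i]
    score <- 0L
    for (e in seq_len(nrow(postorder))) {
      par <- postorder[e, 1]; child <- postorder[e, 2]
      if (is.null(sets[[par]])) {
        sets[[par]] <- sets[[child]]
      } else {
        inter <- intersect(sets[[par]], sets[[child]])
        if (length(inter)) sets[[par]] <- inter
        else { sets[[par]] <- union(sets[[par]], sets[[child]])
               score <- score + 1L }
      }
    }
    codonCounts[cd] <- score
    if (score == 0L) next
    # root-to-tip state assignment (one minimal resolution)
    state <- character(ntip + nnode)
    rs <- sort(sets[[root]])
    state[root] <- rs[1]
    amb <- logical(ntip + nnode)
    amb[root] <- length(rs) > 1L
    preorder <- postorder[rev(seq_len(nrow(postorder))), , drop = FALSE]
    for (e in seq_len(nrow(preorder))) {
      par <- preorder[e, 1]; child <- preorder[e, 2]
      s <- sets[[child]]
      if (state[par] %in% s) {
        state[child] <- state[par]
        amb[child] <- FALSE
      } else {
        ss <- sort(s)
        state[child] <- ss[1]
        amb[child] <- length(ss) > 1L
        events[[length(events) + 1L]] <- data.frame(
          branch = if (child <= ntip) tree$tip.label[child]
                   else paste0("node_", child),
          codon = cd, from = state[par], to = state[child],
          ambiguous = amb[child] || amb[par])
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(branch = character(), codon = integer(), from = character(),
               to = character(), ambiguous = logical())
  new("SubstitutionMap", tree = tree, events = events,
      codonCounts = codonCounts)
}

#' @rdname substEvents
#' @export
setMethod("substEvents", "SubstitutionMap", function(x) x@events)

#' @rdname codonHits
#' @export
setMethod("codonHits", "SubstitutionMap", function(x) x@codonCounts)

setMethod("show", "SubstitutionMap", function(object) {
  cc <- object@codonCounts
  cat("SubstitutionMap:", sum(cc, na.rm = TRUE), "substitutions at",
      sum(cc > 0, na.rm = TRUE), "of", sum(!is.na(cc)),
      "analyzed codons (", sum(is.na(cc)), "excluded )\n")
})

#' Multiple-hit summary of a substitution map
#'
#' @param map a [SubstitutionMap-class]
#' @return list with `codonsHit` (codons with >= 1 substitution),
#'   `codonsHitMultiply` (>= 2), `fraction` (multiply hit among hit; `NA`
#'   when nothing was hit)
#' @export
multipleHitSummary <- function(map) {
  cc <- codonHits(map)
  hit <- sum(cc >= 1, na.rm = TRUE)
  multi <- sum(cc >= 2, na.rm = TRUE)
  list(codonsHit = hit, codonsHitMultiply = multi,
       fraction = if (hit > 0) multi / hit else NA_real_)
}

#' Define protein region boundaries in codon coordinates
#'
#' Intervals are 1-based inclusive codon indices (converted internally as
#' needed). Defaults follow the usual three-part layout of an
#' RRM-containing protein: N-terminal region, RNA-binding domain,
#' C-terminal region.
#'
#' @param N_terminal,RNA_binding,C_terminal `c(startCodon, endCodon)`
#' @return data.frame with `region`, `startCodon`, `endCodon`
#' @export
regionPartition <- function(N_terminal = c(1, 136),
                            RNA_binding = c(137, 303),
                            C_terminal = c(304, 373)) {
  d <- data.frame(region = c("N_terminal", "RNA_binding", "C_terminal"),
                  startCodon = c(N_terminal[1], RNA_binding[1],
                                 C_terminal[1]),
                  endCodon = c(N_terminal[2], RNA_binding[2],
                               C_terminal[2]))
  if (any(d$endCodon < d$startCodon)) stop("inverted region interval")
  d
}

#' Pearson chi-square on a 2x2 contingency table (no continuity correction)
#'
#' Equals the closed form `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with a
#' chi-square df = 1 p-value.
#'
#' @param tab 2x2 numeric matrix
#' @return list with `statistic` and `p`
#' @export
contingencyChisq <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value)
}

#' Test heterogeneity of substitution density between two regions
#'
#' 2x2 comparison (codons substituted vs not) x (region A vs region B),
#' Pearson chi-square without continuity correction. Codons excluded from
#' the map (alignment gaps) are dropped from the region totals.
#'
#' @param map a [SubstitutionMap-class]
#' @param partition output of [regionPartition()]
#' @param regions character vector of two region names to compare
#' @return list with `statistic`, `p`, `table` (the 2x2 counts)
#' @export
regionHeterogeneityTest <- function(map, partition,
                                    regions = c("N_terminal",
                                                "C_terminal")) {
  stopifnot(length(regions) == 2L, all(regions %in% partition$region))
  cc <- codonHits(map)
  cnt <- lapply(regions, function(r) {
    b <- partition[partition$region == r, ]
    idx <- seq.int(b$startCodon, min(b$endCodon, length(cc)))
    v <- cc[idx]
    v <- v[!is.na(v)]
    if (!length(v)) stop("region ", r, " holds no analyzed codons")
    c(hit = sum(v > 0), tot = length(v))
  })
  tab <- rbind(c(cnt[[1]]["hit"], cnt[[1]]["tot"] - cnt[[1]]["hit"]),
               c(cnt[[2]]["hit"], cnt[[2]]["tot"] - cnt[[2]]["hit"]))
  dimnames(tab) <- list(regions, c("substituted", "not"))
  res <- contingencyChisq(tab)
  list(statistic = res$statistic, p = res$p, table = tab)
}
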