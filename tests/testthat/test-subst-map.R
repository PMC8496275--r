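# Fitch parsimony substitution mapping and region heterogeneity.

test_that("invariant and forced-placement codons map as expected", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  aa <- matrix(c("K", "K", "K", "K",
                 "K", "K", "R", "R"), 4, 2,
               dimnames = list(c("A", "B", "C", "D"), NULL))
  m <- fitchCount(tr, aa)
  expect_equal(codonHits(m), c(0L, 1L))
  ev <- substEvents(m)
  expect_equal(nrow(ev), 1L)
  # the single change lies on an internal branch
  expect_match(ev$branch, "^node_")
  # gap-containing codons are excluded symmetrically
  aa2 <- cbind(aa, c("K", "-", "K", "K"))
  expect_equal(codonHits(fitchCount(tr, aa2))[3], NA_integer_)
})

test_that("Fitch scores are invariant to leaf rotation", {
  set.seed(61)
  tr <- balancedTree6()
  aa <- matrix(sample(c("A", "R", "N", "D"), 6 * 40, replace = TRUE),
               6, 40, dimnames = list(tr$tip.label, NULL))
  base <- codonHits(fitchCount(tr, aa))
  for (k in 1:5) {
    rot <- ape::rotateConstr(tr, sample(tr$tip.label))
    expect_equal(codonHits(fitchCount(rot, aa)), base)
  }
})

test_that("Fitch scores agree with an independent parsimony oracle", {
  skip_if_not_installed("phangorn")
  set.seed(71)
  tr <- ape::rtree(12)
  aa <- matrix(sample(c("A", "R", "N", "D", "C", "E"), 12 * 60,
                      replace = TRUE), 12, 60,
               dimnames = list(tr$tip.label, NULL))
  m <- fitchCount(tr, aa)
  pd <- phangorn::phyDat(aa, type = "USER",
                         levels = c("A", "R", "N", "D", "C", "E"))
  oracle <- phangorn::parsimony(tr, pd, method = "fitch", site = "site")
  expect_equal(unname(codonHits(m)), as.integer(oracle))
})

test_that("mapped counts equal logged truth at homoplasy-free codons", {
  set.seed(41)
  tr <- balancedTree6(0.08)
  anc <- randomSenseCodons(1000)
  ev <- evolveOnTree(tr, anc, rates = c(nonsynonymous = 0.25,
                                        synonymous = 0), seed = 41)
  m <- fitchCount(tr, translateCodonMatrix(ev$tipCodons))
  truth <- tabulate(ev$events$codon, nbins = 1000)
  counts <- codonHits(m)
  # parsimony is a lower bound on the true event count everywhere
  expect_true(all(counts <= truth))
  # homoplasy-free codons: every state in the codon's history is distinct
  # and no branch carries two events (else the intermediate state never
  # reaches a tip and parsimony sees one change fewer)
  hf <- vapply(seq_len(1000), function(ci) {
    evc <- ev$events[ev$events$codon == ci, ]
    !anyDuplicated(c(unname(Biostrings::GENETIC_CODE[anc[ci]]),
                     evc$toAA)) && !anyDuplicated(evc$branch)
  }, logical(1))
  expect_gt(sum(hf & truth > 0), 50)     # the check is not vacuous
  expect_equal(counts[hf], truth[hf])
})

test_that("single-branch events are placed on that branch", {
  tr <- balancedTree6(0)
  # plant events on one pendant branch only by giving it all the length
  tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "t3")] <- 3
  set.seed(52)
  anc <- randomSenseCodons(300)
  ev <- evolveOnTree(tr, anc, rates = c(nonsynonymous = 0.1,
                                        synonymous = 0), seed = 52)
  expect_true(all(ev$events$branch == "t3"))
  m <- fitchCount(tr, translateCodonMatrix(ev$tipCodons))
  hits <- table(ev$events$codon)
  oneHit <- as.integer(names(hits)[hits == 1])
  got <- substEvents(m)
  got1 <- got[got$codon %in% oneHit, ]
  expect_true(all(got1$branch == "t3"))
  truth1 <- ev$events[ev$events$codon %in% oneHit, ]
  expect_equal(sort(got1$codon), sort(truth1$codon))
})

test_that("multiple-hit summaries count hit and multiply-hit codons", {
  m <- new("SubstitutionMap", tree = ape::rtree(3),
           events = data.frame(), codonCounts = c(3L, 1L, 0L, NA, 0L))
  s <- multipleHitSummary(m)
  expect_equal(s$codonsHit, 2L)
  expect_equal(s$codonsHitMultiply, 1L)
  expect_equal(s$fraction, 0.5)
  empty <- new("SubstitutionMap", tree = ape::rtree(3),
               events = data.frame(), codonCounts = c(0L, 0L))
  expect_true(is.na(multipleHitSummary(empty)$fraction))
  # ratio check: 20 of 53
  m2 <- new("SubstitutionMap", tree = ape::rtree(3), events = data.frame(),
            codonCounts = as.integer(c(rep(2, 20), rep(1, 33), rep(0, 10))))
  expect_equal(multipleHitSummary(m2)$fraction, 20 / 53, tolerance = 1e-12)
})

test_that("region heterogeneity chi-square equals the closed form", {
  # region layout: codons 1..137 vs 138..207 with planted hit patterns
  counts <- integer(207)
  counts[sample.int(137, 24)] <- 1L
  counts[137 + sample.int(70, 27)] <- 1L
  m <- new("SubstitutionMap", tree = ape::rtree(3), events = data.frame(),
           codonCounts = counts)
  part <- regionPartition(N_terminal = c(1, 137), RNA_binding = c(0, 0),
                          C_terminal = c(138, 207))
  het <- regionHeterogeneityTest(m, part)
  expect_equal(het$statistic, handChisq2x2(24, 113, 27, 43),
               tolerance = 1e-10)
  expect_equal(het$statistic, 11.06, tolerance = 0.01)
  expect_equal(het$p, 0.001, tolerance = 0.15)
  # equal proportions -> statistic 0
  eq <- new("SubstitutionMap", tree = ape::rtree(3), events = data.frame(),
            codonCounts = as.integer(c(rep(1, 5), rep(0, 5),
                                       rep(1, 5), rep(0, 5))))
  partEq <- regionPartition(N_terminal = c(1, 10), RNA_binding = c(0, 0),
                            C_terminal = c(11, 20))
  expect_equal(regionHeterogeneityTest(eq, partEq)$statistic, 0,
               tolerance = 1e-12)
})
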