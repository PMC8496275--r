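# CF test: lineage fixation assignment, opportunity counting, and the
# 2x2 comparison.

cfAln <- function(focalCodons, out1Codons, out2Codons, nFocal = 3) {
  # nFocal identical focal sequences plus one sequence per outgroup
  f <- paste(focalCodons, collapse = "")
  seqs <- c(setNames(rep(f, nFocal), paste0("f", 1:nFocal)),
            o1 = paste(out1Codons, collapse = ""),
            o2 = paste(out2Codons, collapse = ""))
  sampleAlignment(seqs,
                  setNames(c(rep("F", nFocal), "O1", "O2"), names(seqs)),
                  c(F = "ingroup_population", O1 = "outgroup",
                    O2 = "outgroup"))
}

test_that("fixations are assigned only with agreeing outgroups", {
  pref <- toyPrefTable()
  # focal fixed GGG, both outgroups GGA -> focal-lineage synonymous change
  aln <- cfAln(c("GGG", "AAA"), c("GGA", "AAA"), c("GGA", "AAA"))
  map <- buildCodonMap(exonAnn(6))
  fx <- assignLineageFixations(aln, "F", c("O1", "O2"), map, pref)
  expect_equal(nrow(fx), 1L)
  expect_true(fx$assigned)
  expect_true(fx$synonymous)
  expect_equal(fx$direction, "to_unpreferred")  # GGA preferred in fixture
  # outgroups disagree -> unassigned
  aln2 <- cfAln(c("GGG", "AAA"), c("GGA", "AAA"), c("GGT", "AAA"))
  fx2 <- assignLineageFixations(aln2, "F", c("O1", "O2"), map, pref)
  expect_false(any(fx2$assigned))
  expect_equal(fx2$reason, "outgroup_disagreement")
  # focal segregating -> not a fixation
  seqs <- c(f1 = "GGGAAA", f2 = "GGAAAA", o1 = "GGAAAA", o2 = "GGAAAA")
  aln3 <- sampleAlignment(seqs, setNames(c("F", "F", "O1", "O2"),
                                         names(seqs)),
                          c(F = "ingroup_population", O1 = "outgroup",
                            O2 = "outgroup"))
  fx3 <- assignLineageFixations(aln3, "F", c("O1", "O2"), map, pref)
  expect_false(any(fx3$assigned))
  # two-position codon differences are logged unassigned
  aln4 <- cfAln("GGG", "GCA", "GCA")
  fx4 <- assignLineageFixations(aln4, "F", c("O1", "O2"),
                                buildCodonMap(exonAnn(3)), pref)
  expect_equal(fx4$reason, "multi_position")
})

test_that("tree-evolved fixations land on the true lineage", {
  # evolve with events allowed everywhere, then verify assignment for the
  # focal tip against the truth log restricted to homoplasy-free codons
  tr <- ape::read.tree(text = "((F:0.4,O1:0.4):0.2,O2:0.6);")
  set.seed(12)
  anc <- randomSenseCodons(150)
  ev <- evolveOnTree(tr, anc, rates = c(nonsynonymous = 0,
                                        synonymous = 0.15),
                     prefTable = toyPrefTable(), seed = 12)
  tips <- ev$tipCodons
  seqs <- c(F = paste(tips["F", ], collapse = ""),
            O1 = paste(tips["O1", ], collapse = ""),
            O2 = paste(tips["O2", ], collapse = ""))
  aln <- sampleAlignment(seqs, setNames(c("F", "O1", "O2"), names(seqs)),
                         c(F = "ingroup_population", O1 = "outgroup",
                           O2 = "outgroup"))
  pref <- toyPrefTable()
  fx <- assignLineageFixations(aln, "F", c("O1", "O2"),
                               buildCodonMap(exonAnn(450)), pref)
  hits <- table(ev$events$codon)
  oneHit <- as.integer(names(hits)[hits == 1])
  focalTruth <- ev$events[ev$events$branch == "F" &
                            ev$events$codon %in% oneHit, ]
  got <- fx[fx$assigned, ]
  # every single-hit focal-branch event is recovered with its direction
  expect_true(all(focalTruth$codon %in% (got$codon + 1L)))
  for (k in seq_len(nrow(focalTruth))) {
    row <- got[got$codon + 1L == focalTruth$codon[k], ]
    expect_equal(row$to, focalTruth$toCodon[k])
    expect_equal(row$direction, focalTruth$direction[k])
  }
  # single-hit events on other branches are never assigned to the focal tip
  otherTruth <- ev$events[ev$events$branch != "F" &
                            ev$events$codon %in% oneHit, ]
  expect_false(any(otherTruth$codon %in% (got$codon + 1L)))
})

test_that("CF opportunity counts follow the current-state definition", {
  pref <- toyPrefTable()
  st <- setNames(pref$status, pref$codon)
  codons <- c("GGA", "GGT", "GGG", "ATG", "TGG", "AAA", "AAG", "CCA",
              "CCC", "CCG")
  sites <- countCFSites(codons, pref)
  expect_equal(unname(sites["unprefSites"]),
               sum(st[codons] == "preferred"))
  expect_equal(unname(sites["prefSites"]),
               sum(st[codons] == "unpreferred"))
  # Met/Trp contribute to neither
  expect_equal(unname(countCFSites(c("ATG", "TGG"), pref)),
               c(0, 0))
  # all-preferred input leaves no preferred-direction opportunities
  allPref <- pref$codon[pref$status == "preferred"]
  expect_equal(unname(countCFSites(allPref, pref)["prefSites"]), 0)
})

test_that("the chi-square CF test equals the closed form and is symmetric", {
  for (cnt in list(c(6, 11, 174, 29), c(1, 3, 154, 31), c(5, 0, 150, 31),
                   c(1, 2, 150, 31), c(4, 4, 80, 80))) {
    tab <- cfTable("x", cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(tab@statistic,
                 handChisq2x2(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-10)
    # swapping the preferred/unpreferred columns leaves p unchanged
    sw <- cfTable("x", cnt[2], cnt[1], cnt[4], cnt[3])
    expect_equal(pValue(sw), pValue(tab), tolerance = 1e-12)
  }
  # hand-checked case: chi-square about 9.0, p about 0.003
  t2 <- cfTable("pse", 1, 3, 154, 31)
  expect_equal(t2@statistic, 9.0, tolerance = 0.01)
  expect_equal(pValue(t2), 0.0027, tolerance = 0.05)
  expect_equal(t2@direction, "Preferred codons favored")
})

test_that("zero-margin CF tables report no preference", {
  t0 <- cfTable("x", 0, 0, 150, 31)
  expect_equal(pValue(t0), 1)
  expect_equal(t0@direction, "No preference")
  expect_true(is.na(t0@statistic))
})

test_that("CF type-I error is near nominal under symmetric flux", {
  # simulated 2x2 tables under a symmetric substitution process
  set.seed(88)
  rejections <- 0L
  nTab <- 1000
  for (k in seq_len(nTab)) {
    sitesU <- 150; sitesP <- 40
    # symmetric per-site rate: expected subs proportional to sites
    rate <- 0.04
    u <- rpois(1, sitesU * rate)
    p <- rpois(1, sitesP * rate)
    tab <- cfTable("sim", u, p, sitesU, sitesP)
    if (pValue(tab) < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections / nTab, 0.075)
})

test_that("cfAnalysis composes assignment, sites and the test", {
  pref <- toyPrefTable()
  aln <- cfAln(c("GGG", "AAA", "CCA"), c("GGA", "AAA", "CCA"),
               c("GGA", "AAA", "CCA"))
  res <- cfAnalysis(aln, "F", c("O1", "O2"), buildCodonMap(exonAnn(9)),
                    pref)
  cnt <- tableCounts(res)
  expect_equal(unname(cnt["unprefSubs"]), 1)   # GGA -> GGG unpreferred
  expect_equal(unname(cnt["prefSubs"]), 0)
  st <- setNames(pref$status, pref$codon)
  expect_equal(unname(cnt["unprefSites"]),
               sum(st[c("GGG", "AAA", "CCA")] == "preferred"))
})
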