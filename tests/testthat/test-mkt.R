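# McDonald-Kreitman site classification, table building, frequency
# filtering and the Fisher exact test.

threeSpecies <- function(colsA, colsB, colsC) {
  # build an alignment column-wise from per-species base lists
  nA <- length(colsA[[1]]); nB <- length(colsB[[1]]); nC <- length(colsC[[1]])
  m <- rbind(do.call(cbind, colsA), do.call(cbind, colsB),
             do.call(cbind, colsC))
  labs <- c(paste0("a", 1:nA), paste0("b", 1:nB), paste0("c", 1:nC))
  rownames(m) <- labs
  sampleAlignment(m, setNames(rep(c("A", "B", "C"), c(nA, nB, nC)), labs),
                  c(A = "ingroup_population", B = "outgroup",
                    C = "outgroup"))
}

test_that("site status follows the polymorphism/divergence rules", {
  # A = {A,A,G}, B = {A,A}, C = {A} -> polymorphic
  aln <- threeSpecies(list(c("A", "A", "G")), list(c("A", "A")), list("A"))
  expect_equal(classifySitesMK(aln, "A")$status, "polymorphic")
  # A = {G,G,G}, B = {A,A}, C = {A} -> fixed divergent on the A lineage
  aln2 <- threeSpecies(list(c("G", "G", "G")), list(c("A", "A")), list("A"))
  cl2 <- classifySitesMK(aln2, "A")
  expect_equal(cl2$status, "fixed_divergent")
  expect_equal(cl2$divergentSpecies, "A")
  # A = {A,G,G}, B = {G,G}, C = {G} -> polymorphic wins over divergence
  aln3 <- threeSpecies(list(c("A", "G", "G")), list(c("G", "G")), list("G"))
  expect_equal(classifySitesMK(aln3, "A")$status, "polymorphic")
  # a species with only missing data excludes the site
  aln4 <- threeSpecies(list(c("A", "A", "A")), list(c("N", "N")), list("A"))
  expect_equal(classifySitesMK(aln4, "A")$status, "excluded")
  # divergence on a non-polymorphism lineage still counts
  aln5 <- threeSpecies(list(c("A", "A", "A")), list(c("G", "G")), list("A"))
  cl5 <- classifySitesMK(aln5, "A")
  expect_equal(cl5$status, "fixed_divergent")
  expect_equal(cl5$divergentSpecies, "B")
})

test_that("rule precedence holds over enumerated three-species patterns", {
  # exhaustive check against a direct restatement of the rules for
  # two-allele patterns with sample sizes 3/2/1
  combos <- expand.grid(a1 = c("A", "G"), a2 = c("A", "G"),
                        a3 = c("A", "G"), b1 = c("A", "G"),
                        b2 = c("A", "G"), cc = c("A", "G"),
                        stringsAsFactors = FALSE)
  for (k in seq_len(nrow(combos))) {
    x <- combos[k, ]
    aln <- threeSpecies(list(c(x$a1, x$a2, x$a3)), list(c(x$b1, x$b2)),
                        list(x$cc))
    got <- classifySitesMK(aln, "A")$status
    aset <- unique(c(x$a1, x$a2, x$a3))
    bset <- unique(c(x$b1, x$b2)); cset <- x$cc
    want <- if (length(aset) > 1) "polymorphic"
    else {
      sets <- list(A = aset, B = bset, C = cset)
      div <- FALSE
      for (s in names(sets)) {
        others <- unique(unlist(sets[setdiff(names(sets), s)]))
        if (!length(intersect(sets[[s]], others))) div <- TRUE
      }
      if (div) "fixed_divergent" else "invariant"
    }
    expect_equal(got, want)
  }
})

test_that("Fisher exact reproduces the printed MK p-values", {
  expect_lt(abs(fisherExact2x2(19, 0, 19, 7) - 0.015), 1e-3)
  expect_equal(fisherExact2x2(8, 0, 44, 2), 1.00, tolerance = 1e-6)
  expect_equal(round(fisherExact2x2(9, 1, 14, 0), 3), 0.417)
  # margin of zero -> p = 1
  expect_equal(fisherExact2x2(0, 0, 5, 3), 1)
})

test_that("Fisher exact equals exhaustive enumeration over many margins", {
  set.seed(17)
  for (k in 1:150) {
    cells <- sample(0:60, 4, replace = TRUE)
    p <- fisherExact2x2(cells[1], cells[2], cells[3], cells[4])
    q <- bruteFisher2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p, q, tolerance = 1e-9)
  }
})

test_that("MK tables assemble from classification and site classes", {
  fx <- makeMKFixture(c(19, 0, 19, 7), seed = 42)
  cls <- classifySitesMK(fx$alignment, fx$polymorphismSpecies)
  sct <- classifyColumns(fx$alignment, buildCodonMap(fx$annotation))
  tab <- buildMKTable(cls, sct, fx$polymorphismSpecies)
  expect_equal(unname(tableCounts(tab)), c(19L, 0L, 19L, 7L))
  expect_equal(pValue(tab), fisherExact2x2(19, 0, 19, 7))
  # no variation -> all-zero table with p = 1
  fx0 <- makeMKFixture(c(0, 0, 0, 0), seed = 1)
  tab0 <- buildMKTable(classifySitesMK(fx0$alignment, "spA"),
                       classifyColumns(fx0$alignment,
                                       buildCodonMap(fx0$annotation)))
  expect_equal(unname(tableCounts(tab0)), rep(0L, 4))
  expect_equal(pValue(tab0), 1)
})

test_that("combined polymorphism reduces to single species at n = 1", {
  # with spB reduced to a single sequence, pooling spA+spB polymorphism
  # equals the spA-only table on the same alignment
  fx <- makeMKFixture(c(6, 2, 5, 3), nPerSpecies = c(5L, 1L, 1L),
                      seed = 9)
  sct <- classifyColumns(fx$alignment, buildCodonMap(fx$annotation))
  single <- buildMKTable(classifySitesMK(fx$alignment, "spA"), sct)
  combined <- buildMKTable(classifySitesMK(fx$alignment, c("spA", "spB")),
                           sct)
  expect_equal(tableCounts(single), tableCounts(combined))
})

test_that("the low-frequency filter drops only sub-threshold polymorphism", {
  # population of 10: one singleton (10%) and one variant at 2/10
  cols <- list(c(rep("A", 9), "G"), c(rep("C", 8), "T", "T"),
               rep("A", 10))
  m <- do.call(cbind, cols)
  rownames(m) <- paste0("p", 1:10)
  out <- matrix(c("A", "C", "A"), 1, dimnames = list("o1", NULL))
  aln <- sampleAlignment(rbind(m, out),
                         setNames(c(rep("P", 10), "O"), c(rownames(m),
                                                          "o1")),
                         c(P = "ingroup_population", O = "outgroup"))
  cls <- classifySitesMK(aln, "P")
  expect_equal(cls$status[1:2], c("polymorphic", "polymorphic"))
  pol <- polarize(aln, "P")
  fl <- fwwFilter(cls, pol, minFreq = 0.15)
  expect_equal(fl$removed, 1L)                     # 0.10 < 0.15 removed
  expect_equal(fl$classified$status[1], "excluded")
  expect_equal(fl$classified$status[2], "polymorphic")  # 0.20 retained
  # identity at threshold zero
  fl0 <- fwwFilter(cls, pol, minFreq = 0)
  expect_identical(fl0$classified, cls)
  # fixed-divergent sites are never touched
  expect_identical(fl$classified$status[cls$status == "fixed_divergent"],
                   cls$status[cls$status == "fixed_divergent"])
})

test_that("MK fixtures round-trip exact counts across random tables", {
  set.seed(31)
  for (k in 1:100) {
    counts <- c(sample(0:20, 1), sample(0:5, 1), sample(0:20, 1),
                sample(0:8, 1))
    fx <- makeMKFixture(counts, seed = 1000 + k)
    tab <- buildMKTable(
      classifySitesMK(fx$alignment, fx$polymorphismSpecies),
      classifyColumns(fx$alignment, buildCodonMap(fx$annotation)))
    expect_equal(unname(tableCounts(tab)), as.integer(counts))
  }
})
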