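# Site classification, Nei-Gojobori counting, polarization, preference
# direction.

test_that("Nei-Gojobori fractional site counts match the code table", {
  gg <- countSites("GGG")           # 4-fold third position
  expect_equal(gg$synSites, 1)
  expect_equal(gg$nonsynSites, 2)
  atg <- countSites("ATG")          # Met: single-codon family
  expect_equal(atg$synSites, 0)
  expect_equal(atg$nonsynSites, 3)
  # conservation: every sense codon sums to exactly 3 sites
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  cs <- countSites(sense)
  expect_equal(cs$synSites + cs$nonsynSites, rep(3, length(sense)))
  expect_warning(countSites("TAA"), "stop")
})

test_that("column classification follows the single-variant codon rule", {
  roles <- c(A = "ingroup_population")
  sp <- c(a = "A", b = "A", c = "A")
  # GGA/GGG third position (Gly): synonymous
  # TTA/CTA first position (both Leu): synonymous
  # GCT/GTT second position: nonsynonymous
  aln <- sampleAlignment(c(a = "GGATTAGCT", b = "GGGCTAGCT",
                           c = "GGACTAGTT"), sp, roles)
  sct <- classifyColumns(aln, buildCodonMap(exonAnn(9)))
  cls <- columnClasses(sct)$class
  expect_equal(cls[3], "synonymous")
  expect_equal(cls[4], "synonymous")
  expect_equal(cls[8], "nonsynonymous")
  expect_equal(cls[c(1, 2, 5, 6, 7, 9)],
               c("invariant", "invariant", "invariant", "invariant",
                 "invariant", "invariant"))
  # deterministic and row-order independent
  aln2 <- sampleAlignment(c(c = "GGACTAGTT", a = "GGATTAGCT",
                            b = "GGGCTAGCT"), sp, roles)
  sct2 <- classifyColumns(aln2, buildCodonMap(exonAnn(9)))
  expect_equal(columnClasses(sct2)$class, cls)
})

test_that("codons variable at two positions are excluded and logged", {
  aln <- sampleAlignment(c(a = "GGA", b = "GCG"),
                         c(a = "A", b = "A"), c(A = "ingroup_population"))
  sct <- classifyColumns(aln, buildCodonMap(exonAnn(3)))
  expect_true(all(columnClasses(sct)$class == "excluded"))
  expect_equal(sct@excluded$reason, "multi_position")
})

test_that("observed stop codons exclude the codon with a warning", {
  aln <- sampleAlignment(c(a = "TAAGGG", b = "TACGGG"),
                         c(a = "A", b = "A"), c(A = "ingroup_population"))
  expect_warning(
    sct <- classifyColumns(aln, buildCodonMap(exonAnn(6))), "stop")
  expect_equal(columnClasses(sct)$class[1:3], rep("excluded", 3))
})

test_that("polarization requires unanimous matching outgroups", {
  roles <- c(P = "ingroup_population", O = "outgroup")
  mk <- function(ing, out) {
    seqs <- c(setNames(ing, paste0("i", seq_along(ing))),
              setNames(out, paste0("o", seq_along(out))))
    sampleAlignment(seqs, setNames(c(rep("P", length(ing)),
                                     rep("O", length(out))), names(seqs)),
                    roles)
  }
  # 9 A : 1 G with outgroup A -> derived G at count 1
  p1 <- polarize(mk(c(rep("A", 9), "G"), "A"), "P")
  expect_true(p1$polarized)
  expect_equal(p1$derived, "G")
  expect_equal(p1$i, 1L)
  # 5 A : 5 G with outgroup G -> derived A at count 5
  p2 <- polarize(mk(c(rep("A", 5), rep("G", 5)), "G"), "P")
  expect_equal(p2$derived, "A")
  expect_equal(p2$i, 5L)
  # outgroup matching neither allele -> unpolarized
  p3 <- polarize(mk(c(rep("A", 5), rep("G", 5)), "T"), "P")
  expect_false(p3$polarized)
  expect_equal(p3$reason, "outgroup_mismatch")
  # disagreeing outgroups -> unpolarized
  p4 <- polarize(mk(c(rep("A", 5), rep("G", 5)), c("A", "G")), "P")
  expect_false(p4$polarized)
  # missing outgroup data -> unpolarized
  p5 <- polarize(mk(c(rep("A", 5), rep("G", 5)), "N"), "P")
  expect_equal(p5$reason, "no_outgroup")
})

test_that("preference direction matches exhaustive enumeration on a fixture", {
  pref <- toyPrefTable()
  expect_equal(preferenceDirection("GGT", "GGA", pref), "to_preferred")
  expect_equal(preferenceDirection("GGA", "GGT", pref), "to_unpreferred")
  # both unpreferred, and not_applicable families -> none
  expect_equal(preferenceDirection("GGT", "GGC", pref), "none")
  expect_equal(preferenceDirection("ATG", "ATG", pref), "none")
  # batch agreement with a direct hand rule over every synonymous pair
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  st <- setNames(pref$status, pref$codon)
  for (a in sense) {
    syn <- sense[gc[sense] == gc[[a]] & sense != a]
    for (b in syn) {
      want <- if (st[[a]] == "not_applicable" || st[[a]] == st[[b]]) "none"
              else if (st[[b]] == "preferred") "to_preferred"
              else "to_unpreferred"
      expect_equal(preferenceDirection(a, b, pref), want)
    }
  }
})

test_that("the bundled preference table is structurally valid", {
  pref <- defaultPreferenceTable()
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  expect_true(all(sense %in% pref$codon))
  st <- setNames(pref$status, pref$codon)
  expect_equal(unname(st[c("ATG", "TGG")]),
               c("not_applicable", "not_applicable"))
  for (a in setdiff(unique(gc[sense]), c("M", "W"))) {
    fam <- sense[gc[sense] == a]
    expect_equal(sum(st[fam] == "preferred"), 1L)
  }
})
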