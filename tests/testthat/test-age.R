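# MRD / DCA / SCA age assignment and the 16-group frequency tables.

test_that("singleton genes fall back to the root (SCA) age", {
  tr <- ape::read.tree(text = "(g1,og);")
  gt <- geneTree(tr, ages = 400, events = "speciation")
  a <- assignAges(gt, "g1")
  expect_equal(a$mrd_sca_age, 400)
  expect_equal(a$dca_sca_age, 400)
  expect_equal(a$mrd_group, "Euteleostomi")
  expect_equal(a$dca_group, "Euteleostomi")
  expect_true(a$is_singleton)
})

test_that("MRD is the nearest and DCA the farthest duplication ancestor", {
  ## g1 under duplications at 167 (near) and 937 (far), root speciation 1215
  tr <- ape::read.tree(text = "(((g1,p1),p2),og);")
  gt <- geneTree(tr, ages = c(1215, 937, 167),
                 events = c("speciation", "duplication", "duplication"))
  a <- assignAges(gt, "g1")
  expect_equal(a$mrd_sca_age, 167)
  expect_equal(a$dca_sca_age, 937)
  expect_equal(a$mrd_group, "Mammalia")
  expect_equal(a$dca_group, "Bilateria")
  expect_false(a$is_singleton)
  ## a leaf outside the duplication clade is a singleton at the root age
  b <- assignAges(gt, "og")
  expect_true(b$is_singleton)
  expect_equal(b$mrd_sca_age, 1215)

  ## degenerate equality: duplication parent and duplication root, same age
  tr2 <- ape::read.tree(text = "((g1,p1),p2);")
  gt2 <- geneTree(tr2, ages = c(104, 104),
                  events = c("duplication", "duplication"))
  a2 <- assignAges(gt2, "g1")
  expect_equal(a2$mrd_sca_age, 104)
  expect_equal(a2$dca_sca_age, 104)

  expect_error(assignAges(gt, "nope"), "not a leaf")
})

test_that("non-taxon ages error unless snapping is requested", {
  tr <- ape::read.tree(text = "(g1,og);")
  gt <- geneTree(tr, ages = 399, events = "speciation")
  expect_error(assignAges(gt, "g1"), "snap")
  a <- assignAges(gt, "g1", snapAges = TRUE)
  expect_equal(a$mrd_group, "Euteleostomi")
})

test_that("gene trees reject inverted age ordering", {
  tr <- ape::read.tree(text = "((g1,p1),og);")
  expect_error(validObject(geneTree(tr, ages = c(100, 400),
                                    events = c("speciation", "duplication"))),
               "non-increasing")
})

test_that("DCA >= MRD holds across generated cohorts and DCA grows with older duplications", {
  coh <- generateCohort(cohortConfig(nEssential = 60L, nViable = 60L,
                                     seed = 14L), parts = "trees")
  assg <- assignAgesAll(cohortTrees(coh))
  expect_true(all(assg$dca_sca_age >= assg$mrd_sca_age))
  expect_true(all(assg$mrd_group %in% taxonAgeTable()$taxon))

  ## grafting an older duplication above raises DCA, leaves MRD alone
  tr <- ape::read.tree(text = "((g1,p1),og);")
  gt <- geneTree(tr, ages = c(535, 167),
                 events = c("speciation", "duplication"))
  base <- assignAges(gt, "g1")
  tr2 <- ape::read.tree(text = "(((g1,p1),p2),og);")
  gt2 <- geneTree(tr2, ages = c(722, 535, 167),
                  events = c("speciation", "duplication", "duplication"))
  grown <- assignAges(gt2, "g1")
  expect_equal(grown$mrd_sca_age, base$mrd_sca_age)
  expect_gt(grown$dca_sca_age, base$dca_sca_age)
})

test_that("age-group frequency columns sum to 100 and flag shifted rows", {
  ## all genes in one group: a single 100% row
  trs <- lapply(sprintf("g%02d", 1:10), function(id) {
    tr <- ape::read.tree(text = sprintf("(%s,og);", id))
    geneTree(tr, ages = 937, events = "speciation")
  })
  names(trs) <- sprintf("g%02d", 1:10)
  lab <- setNames(rep(c("essential", "viable"), 5), names(trs))
  assg <- assignAgesAll(trs)
  tab <- ageGroupFrequencies(assg, lab, mode = "MRD")
  expect_equal(nrow(tab), 16L)
  expect_equal(tab$pct_essential[tab$taxon == "Bilateria"], 100)
  expect_equal(sum(tab$pct_essential), 100)
  expect_equal(sum(tab$pct_viable), 100)
  expect_equal(tab$threshold, rep(0.003125, 16))

  ## paper-direction shift: old-age rows significant at n = 800/group
  coh <- generateCohort(cohortConfig(nEssential = 800L, nViable = 800L,
                                     seed = 3L), parts = "trees")
  tabs <- ageGroupFrequencies(assignAgesAll(cohortTrees(coh)),
                              cohortLabels(coh), mode = "MRD")
  old <- tabs[tabs$taxon %in% c("Bilateria", "Opisthokonta"), ]
  expect_true(all(old$pct_essential > old$pct_viable))
  expect_true(any(old$significant))

  ## identical groups: no significant row under a fixed seed
  cohN <- generateCohort(nullCohortConfig(nEssential = 300L, nViable = 300L,
                                          seed = 6L), parts = "trees")
  tabN <- ageGroupFrequencies(assignAgesAll(cohortTrees(cohN)),
                              cohortLabels(cohN), mode = "MRD")
  expect_false(any(tabN$significant))

  expect_error(ageGroupFrequencies(assg, lab[lab == "essential"], "MRD"),
               "labelled")
})

test_that("annotated Newick files round-trip through the tree reader", {
  coh <- generateCohort(cohortConfig(nEssential = 8L, nViable = 8L,
                                     seed = 2L), parts = "trees")
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines(vapply(cohortTrees(coh), essprofile:::.newickWithComments,
                    character(1)), f)
  back <- readGeneTrees(f, names(cohortLabels(coh)))
  expect_setequal(names(back), names(cohortTrees(coh)))
  for (id in names(back)) {
    expect_identical(back[[id]]@ages, cohortTrees(coh)[[id]]@ages)
    expect_identical(back[[id]]@events, cohortTrees(coh)[[id]]@events)
  }
  ## missing annotation is a parse error
  expect_error(essprofile:::.parseGeneTree("((g1,p1),og);"), "annotation")
})
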