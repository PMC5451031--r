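# Cohort generator: determinism, configuration validation, calibration of
# the configured medians, and lossless round-trip serialisation.

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(cohortConfig(nEssential = -1), "nEssential")
  expect_error(cohortConfig(gcMean = c(1.2, 0.5)), "gcMean")
  bad_alpha <- matrix(1, 20, 2); bad_alpha[3, 1] <- 0
  expect_error(cohortConfig(aaDirichletAlpha = bad_alpha), "aaDirichletAlpha")
  ar <- essprofile:::.ANNOTATION_RATES_DEFAULT
  ar$essential[1] <- 1.5
  expect_error(cohortConfig(annotationRates = ar), "annotationRates")
  expect_error(cohortConfig(treeDuplicationProb = 2), "treeDuplicationProb")
})

test_that("the same seed reproduces an identical cohort", {
  cfg <- cohortConfig(nEssential = 25L, nViable = 30L, seed = 11L)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(cohortGenes(a), cohortGenes(b))
  expect_identical(as.character(cohortProteins(a)),
                   as.character(cohortProteins(b)))
  expect_identical(estCounts(a), estCounts(b))
  expect_identical(igraph::as_edgelist(cohortPPI(a)),
                   igraph::as_edgelist(cohortPPI(b)))
  expect_identical(lapply(cohortTrees(a), function(t) t@ages),
                   lapply(cohortTrees(b), function(t) t@ages))
  c2 <- generateCohort(cohortConfig(nEssential = 25L, nViable = 30L,
                                    seed = 12L))
  expect_false(identical(cohortGenes(a)$gene_length,
                         cohortGenes(c2)$gene_length))
})

test_that("configured gene-length medians are recovered within 10%", {
  ## Monte-Carlo over 20 seeds at n = 500/group under the study's
  ## 28913 / 21629 bp configuration
  medsE <- medsV <- numeric(20)
  for (s in 1:20) {
    cfg <- cohortConfig(nEssential = 500L, nViable = 500L, seed = s)
    coh <- generateCohort(cfg, parts = "genes")
    gf <- geneFeatures(cohortGenes(coh))
    lab <- cohortLabels(coh)[gf$gene_id]
    medsE[s] <- median(gf$gene_length[lab == "essential"])
    medsV[s] <- median(gf$gene_length[lab == "viable"])
  }
  expect_lt(abs(mean(medsE) - 28913) / 28913, 0.10)
  expect_lt(abs(mean(medsV) - 21629) / 21629, 0.10)
})

test_that("generated cohorts satisfy structural invariants", {
  coh <- generateCohort(cohortConfig(nEssential = 40L, nViable = 60L,
                                     seed = 5L))
  lab <- cohortLabels(coh)
  expect_equal(unname(table(lab)[c("essential", "viable")]),
               c(40L, 60L), ignore_attr = TRUE)
  expect_setequal(names(cohortProteins(coh)), names(lab))
  gf <- geneFeatures(cohortGenes(coh))
  expect_true(all(gf$intron_length >= 0))
  expect_true(all(gf$exon_length <= gf$gene_length))
  expect_true(all(Biostrings::width(cohortProteins(coh)) >= 30))
  expect_true(all(estCounts(coh) >= 0))
  expect_false(any(igraph::which_loop(cohortPPI(coh))))
  expect_false(any(igraph::which_multiple(cohortPPI(coh))))
})

test_that("write/read round-trips a cohort losslessly", {
  coh <- generateCohort(cohortConfig(nEssential = 12L, nViable = 15L,
                                     seed = 21L))
  dir <- withr::local_tempdir()
  manifest <- writeCohort(coh, dir)
  expect_equal(nrow(manifest), 7L)
  expect_setequal(manifest$file,
                  c("proteins.fasta", "trees.nwk", "gene_models.tsv",
                    "expression.tsv", "annotations.tsv", "labels.tsv",
                    "ppi_edges.tsv"))
  back <- readCohort(dir)
  expect_identical(cohortLabels(back)[names(cohortLabels(coh))],
                   cohortLabels(coh))
  expect_identical(as.character(cohortProteins(back)[names(cohortProteins(coh))]),
                   as.character(cohortProteins(coh)))
  expect_equal(cohortGenes(back), cohortGenes(coh))
  expect_identical(estCounts(back), estCounts(coh))
  gsort <- function(g) {
    el <- igraph::as_edgelist(g)
    el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  expect_identical(gsort(cohortPPI(back)), gsort(cohortPPI(coh)))
  ta <- cohortTrees(coh); tb <- cohortTrees(back)[names(ta)]
  expect_identical(lapply(ta, function(t) t@ages),
                   lapply(tb, function(t) t@ages))
  expect_identical(lapply(ta, function(t) t@events),
                   lapply(tb, function(t) t@events))
})

test_that("an empty cohort writes valid empty files", {
  coh <- generateCohort(cohortConfig(nEssential = 0L, nViable = 0L,
                                     seed = 1L))
  dir <- withr::local_tempdir()
  manifest <- writeCohort(coh, dir)
  expect_equal(nrow(manifest), 7L)
  expect_true(all(manifest$records == 0))
  expect_true(all(file.exists(file.path(dir, manifest$file))))
  ## header survives
  gm <- read.delim(file.path(dir, "gene_models.tsv"))
  expect_equal(nrow(gm), 0L)
  expect_true("gene_id" %in% names(gm))
})

test_that("trees carry valid age annotations at the 16 taxon ages", {
  coh <- generateCohort(cohortConfig(nEssential = 30L, nViable = 30L,
                                     seed = 8L), parts = "trees")
  ages <- taxonAgeTable()$age
  for (gt in cohortTrees(coh)) {
    expect_true(all(gt@ages %in% ages))
    expect_true(all(gt@events %in% c("duplication", "speciation")))
  }
})
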