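smallSpec <- function(...) {
  phantomSpec(dim = c(64, 64, 48), spacing = c(4, 4, 8),
              bodySemiMm = c(110, 120), lungSemiMm = c(95, 58, 190),
              lungColOffsetMm = 60, hyperinflation = 1.2,
              heightM = 1.70, sex = "male", ...)
}

test_that("a lesion-free phantom matches the analytic normal-tail LAA", {
  p <- generatePhantom(smallSpec(
    classFractions = c(Emph = 0, GGO = 0, CP_LO = 0, Consolidation = 0),
    seed = 31))
  expect_equal(unname(p@classCounts[c("Emph", "GGO", "CP_LO", "Consolidation")]),
               rep(0, 4))
  nLung <- sum(p@classCounts)
  # HU are rounded to integers, so voxels at or below -950 are those whose
  # continuous draw fell below -949.5
  tail <- pnorm(-949.5, mean = -860, sd = 45)
  expect_lt(abs(p@laaFraction - tail),
            4 * sqrt(tail * (1 - tail) / nLung) + 2e-4)
  # truth fraction equals direct counting on the volume
  expect_equal(p@laaFraction,
               sum(laaMask(p@volume, p@lungMask)) / nLung, tolerance = 1e-12)
})

test_that("requested class fractions are hit at voxel resolution", {
  p <- generatePhantom(smallSpec(
    classFractions = c(Emph = 0.25, GGO = 0, CP_LO = 0, Consolidation = 0),
    seed = 32))
  share <- p@classCounts[["Emph"]] / sum(p@classCounts)
  expect_equal(share, 0.25, tolerance = 0.005)
  expect_equal(sum(p@classCounts), sum(labels(p@lungMask) > 0))
  # class map and counts agree
  expect_equal(unname(p@classCounts),
               unname(tabulate(labels(p@classMap)[labels(p@classMap) > 0], 5)))
})

test_that("phantom generation is bit-identical per seed", {
  a <- generatePhantom(smallSpec(seed = 33))
  b <- generatePhantom(smallSpec(seed = 33))
  expect_identical(voxels(a@volume), voxels(b@volume))
  expect_identical(labels(a@classMap), labels(b@classMap))
  c <- generatePhantom(smallSpec(seed = 34))
  expect_false(identical(voxels(a@volume), voxels(c@volume)))
})

test_that("the hyperinflation knob scales CT_LV and leaves P_LV fixed", {
  p1 <- generatePhantom(smallSpec(seed = 35))                   # 1.2x
  spec2 <- smallSpec(seed = 35); spec2$hyperinflation <- 1.44
  p2 <- generatePhantom(spec2)
  i1 <- computeIndices(p1@volume, p1@lungMask)
  i2 <- computeIndices(p2@volume, p2@lungMask)
  expect_equal(i1@pLvMl, i2@pLvMl)
  expect_equal(i2@ctLvMl / i1@ctLvMl, 1.2, tolerance = 0.01)
  expect_equal(i1@ctLvMl / i1@pLvMl, 1.2, tolerance = 0.01)
})

test_that("infeasible specs are rejected", {
  s <- smallSpec(seed = 36); s$hyperinflation <- 6
  expect_error(generatePhantom(s), "infeasible")
  expect_error(phantomSpec(classFractions = c(Emph = 0.9, GGO = 0.3)), "sum")
  expect_error(phantomSpec(hyperinflation = -1), "positive")
})

test_that("adjacent class HU distributions overlap as real densities do", {
  p <- finePhantom()
  hu <- voxels(p@volume); cls <- labels(p@classMap)
  emph <- hu[cls == 1L]; normal <- hu[cls == 2L]; ggo <- hu[cls == 3L]
  # overlap mass: the emphysema upper tail reaches past the normal lower tail
  expect_gt(max(emph), min(normal))
  expect_gt(mean(emph > quantile(normal, 0.01)), 0)
  expect_gt(max(normal), min(ggo))
})

test_that("placement modes shift emphysema along the cranio-caudal axis", {
  api <- generatePhantom(smallSpec(mode = "apical", seed = 37))
  bas <- generatePhantom(smallSpec(mode = "basal", seed = 37))
  sliceOf <- function(p) mean(slice.index(labels(p@classMap), 3)[labels(p@classMap) == 1L])
  expect_lt(sliceOf(api), sliceOf(bas))   # lower slice index = cranial
})

test_that("cohort generation is seeded, ordered and complete", {
  co1 <- generateCohort(n = 3, dim = c(64, 64, 48), spacing = c(4, 4, 8),
                        seed = 38)
  co2 <- generateCohort(n = 3, dim = c(64, 64, 48), spacing = c(4, 4, 8),
                        seed = 38)
  expect_identical(co1$table, co2$table)
  expect_equal(nrow(co1$table), 3L)
  expect_true(all(diff(co1$table$emph_frac_target) > 0))
  expect_true(all(diff(co1$table$hyperinflation_target) > 0))
  f <- withr::local_tempfile(fileext = ".csv")
  writeCohortCsv(co1, f)
  expect_equal(nrow(read.csv(f)), 3L)
  one <- generateCohort(n = 1, dim = c(64, 64, 48), spacing = c(4, 4, 8),
                        seed = 39)
  expect_equal(nrow(one$table), 1L)
  kept <- generateCohort(n = 1, dim = c(64, 64, 48), spacing = c(4, 4, 8),
                         keepVolumes = TRUE, seed = 39)
  expect_s4_class(kept$subjects[[1]], "PhantomTruth")
  expect_identical(one$table, kept$table)
})

test_that("ROI corpora are balanced, ordered by density, and train well", {
  p <- finePhantom()
  corpus <- roiCorpus(p, perClass = 100, seed = 41)
  expect_equal(nrow(corpus), 500L)
  expect_true(all(table(corpus$label) == 100L))
  med <- tapply(corpus$p50, corpus$label, median)
  expect_lt(med[["Emph"]], med[["Normal"]])
  expect_lt(med[["Normal"]], med[["GGO"]])
  expect_lt(med[["GGO"]], med[["CP_LO"]])
  expect_lt(med[["CP_LO"]], med[["Consolidation"]])
  # end-to-end: corpus -> balance -> split -> train -> evaluate
  big <- roiCorpus(p, perClass = 260, seed = 42)
  s <- splitDataset(balanceClasses(big, seed = 1), seed = 2)
  m <- trainClassifier(s, seed = 3)
  expect_gte(evaluateClassifier(m, s$test)$accuracy, 0.95)
})

test_that("a class with too few usable centres reduces the corpus with a warning", {
  p <- generatePhantom(phantomSpec(
    dim = c(128, 128, 24), spacing = c(0.7, 0.7, 5),
    bodySemiMm = c(42, 42), lungSemiMm = c(30, 17, 55), lungColOffsetMm = 19,
    hyperinflation = 0.05, heightM = 1.60, sex = "female", blobSigmaMm = 5,
    classFractions = c(Emph = 0.1, GGO = 0.05, CP_LO = 0.04,
                       Consolidation = 0.0005),
    seed = 43))
  expect_warning(corpus <- roiCorpus(p, perClass = 200, seed = 44),
                 "Consolidation")
  expect_lt(sum(corpus$label == "Consolidation"), 200)
})
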