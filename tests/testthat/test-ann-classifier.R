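# A hand-built classifier whose output depends only on the bias: always
# predicts the class with the largest b2 entry.
constantModel <- function(favoured = "Emph") {
  b2 <- numeric(5); b2[match(favoured, patternClasses())] <- 5
  new("PatternClassifier", W1 = matrix(0, 5, 2), b1 = numeric(2),
      W2 = matrix(0, 2, 5), b2 = b2,
      center = setNames(numeric(5), c("p2_5", "p25", "p50", "p75", "p97_5")),
      scale = setNames(rep(1, 5), c("p2_5", "p25", "p50", "p75", "p97_5")),
      classes = patternClasses(), history = data.frame(),
      bestEpoch = 1L, seed = 0L)
}

test_that("training separable classes reaches near-perfect accuracy", {
  ft <- separableFeatures(200, seed = 1)
  s <- splitDataset(ft, seed = 2)
  m <- trainClassifier(s, seed = 3)
  ev <- evaluateClassifier(m, s$test)
  expect_gte(ev$accuracy, 0.99)
  expect_true(all(ev$auc >= 0.99))
  # posterior at a class's training centroid is confident
  for (cl in patternClasses()) {
    centroid <- colMeans(s$train[s$train$label == cl,
                                 c("p2_5", "p25", "p50", "p75", "p97_5")])
    post <- predict(m, as.numeric(centroid))$posterior
    expect_gt(post[1, cl], 0.9)
  }
})

test_that("posteriors are proper and batch prediction stacks single predictions", {
  ft <- separableFeatures(40, seed = 4)
  s <- splitDataset(ft, seed = 5)
  m <- trainClassifier(s, maxEpochs = 60, seed = 6)
  X <- as.matrix(s$test[, c("p2_5", "p25", "p50", "p75", "p97_5")])
  batch <- predict(m, X)
  expect_equal(unname(rowSums(batch$posterior)), rep(1, nrow(X)),
               tolerance = 1e-9)
  singles <- t(vapply(seq_len(nrow(X)),
                      function(i) predict(m, X[i, ])$posterior[1, ],
                      numeric(5)))
  expect_equal(unname(batch$posterior), unname(singles), tolerance = 1e-12)
  expect_error(predict(m, c(1, 2, NA, 4, 5)), "non-finite")
})

test_that("seeded training is reproducible and best epoch minimizes validation loss", {
  ft <- separableFeatures(60, seed = 7)
  s <- splitDataset(ft, seed = 8)
  m1 <- trainClassifier(s, maxEpochs = 80, seed = 9)
  m2 <- trainClassifier(s, maxEpochs = 80, seed = 9)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  expect_identical(m1@W1, m2@W1)
  h <- trainingHistory(m1)
  expect_equal(h$validation[bestEpoch(m1)], min(h$validation))
})

test_that("evaluation counts match hand enumeration and degenerate ROC is chance", {
  m <- constantModel("Emph")
  samples <- data.frame(label = c("Emph", "Normal", "GGO"),
                        p2_5 = 0, p25 = 0, p50 = 0, p75 = 0, p97_5 = 0)
  ev <- evaluateClassifier(m, samples)
  expect_equal(unname(ev$confusion["Emph", "Emph"]), 1)
  expect_equal(unname(ev$confusion["Normal", "Emph"]), 1)
  expect_equal(unname(ev$confusion["GGO", "Emph"]), 1)
  expect_equal(sum(ev$confusion), 3)
  expect_equal(ev$accuracy, 1 / 3)
  expect_equal(unname(ev$recall["Emph"]), 1)
  expect_equal(unname(ev$recall["Normal"]), 0)
  expect_true(is.na(ev$recall["CP_LO"]))       # absent class: missing, not zero
  expect_true(is.na(ev$auc["CP_LO"]))
  # constant posteriors: one ROC segment, AUC exactly 1/2
  expect_equal(unname(ev$auc["Emph"]), 0.5)
})

test_that("posteriors unrelated to the labels give chance-level AUC", {
  ft <- separableFeatures(80, seed = 10)
  s <- splitDataset(ft, seed = 11)
  m <- trainClassifier(s, maxEpochs = 60, seed = 12)
  shuffled <- s$test
  shuffled$label <- withr::with_seed(13, sample(shuffled$label))
  ev <- evaluateClassifier(m, shuffled)
  expect_true(all(abs(ev$auc - 0.5) < 0.2))
})

test_that("classifyVolume equals the per-voxel feature/predict composition", {
  p <- finePhantom()
  m <- trainClassifier(splitDataset(separableFeatures(60, seed = 14), seed = 1),
                       maxEpochs = 60, seed = 2)
  sub <- CTVolume(voxels(p@volume)[, , 10:11], pixelSpacing(p@volume),
                  sliceThickness(p@volume))
  subMask <- LungLabelMap(labels(p@lungMask)[, , 10:11])
  cm <- classifyVolume(sub, subMask, m)
  idx <- which(labels(subMask) > 0L, arr.ind = TRUE)
  pick <- idx[seq(1, nrow(idx), by = 37), , drop = FALSE]
  for (i in seq_len(nrow(pick))) {
    roi <- extractROI(sub, subMask, pick[i, ], radiusMm = 4, minVoxels = 1L)
    lab <- predict(m, roiFeatures(roi))$label
    expect_identical(patternClasses()[labels(cm)[pick[i, , drop = FALSE]]], lab)
  }
})

test_that("classifyVolume handles homogeneous lungs, empty masks and strides", {
  p <- finePhantom()
  corpus <- roiCorpus(p, perClass = 120, seed = 15)
  m <- trainClassifier(splitDataset(balanceClasses(corpus, seed = 1), seed = 1),
                       seed = 3)
  # homogeneous emphysematous lung
  hu <- array(round(rnorm(40 * 40 * 4, -980, 20)), c(40, 40, 4))
  v <- CTVolume(hu, c(0.7, 0.7), 5)
  lab <- array(0L, dim(hu)); lab[8:32, 8:32, ] <- 1L
  mask <- LungLabelMap(lab)
  cm <- classifyVolume(v, mask, m)
  expect_gte(mean(labels(cm)[lab > 0L] == 1L), 0.99)
  # mask of zeros
  cm0 <- classifyVolume(v, LungLabelMap(array(0L, dim(hu))), m)
  expect_true(all(labels(cm0) == 0L))
  # strided classification stays close to dense classification
  cm2 <- classifyVolume(v, mask, m, stride = 2L)
  expect_gte(mean(labels(cm2)[lab > 0L] == labels(cm)[lab > 0L]), 0.95)
})

test_that("an emphysema blob is recovered up to a boundary band", {
  p <- finePhantom()
  corpus <- roiCorpus(p, perClass = 120, seed = 16)
  m <- trainClassifier(splitDataset(balanceClasses(corpus, seed = 1), seed = 1),
                       seed = 4)
  hu <- array(round(rnorm(48 * 48 * 3, -860, 45)), c(48, 48, 3))
  blob <- array(FALSE, dim(hu)); blob[15:34, 15:34, ] <- TRUE
  hu[blob] <- round(rnorm(sum(blob), -980, 20))
  v <- CTVolume(hu, c(0.7, 0.7), 5)
  lab <- array(1L, dim(hu))
  mask <- LungLabelMap(lab)
  cm <- classifyVolume(v, mask, m)
  interior <- array(FALSE, dim(hu)); interior[22:28, 22:28, ] <- TRUE
  expect_gte(mean(labels(cm)[interior] == 1L), 0.95)
  outside <- !blob & slice.index(hu, 1) %in% 5:44 & slice.index(hu, 2) %in% 5:44
  farOutside <- outside & !(slice.index(hu, 1) %in% 9:40 &
                            slice.index(hu, 2) %in% 9:40)
  expect_gte(mean(labels(cm)[farOutside] == 2L), 0.90)
})

test_that("serialized models restore to round-off precision", {
  ft <- separableFeatures(50, seed = 17)
  s <- splitDataset(ft, seed = 18)
  m <- trainClassifier(s, maxEpochs = 60, seed = 19)
  f <- withr::local_tempfile(fileext = ".json")
  writeClassifier(m, f)
  r <- readClassifier(f)
  X <- as.matrix(s$test[, c("p2_5", "p25", "p50", "p75", "p97_5")])
  expect_equal(predict(r, X)$posterior, predict(m, X)$posterior,
               tolerance = 1e-12)
  expect_identical(r@bestEpoch, m@bestEpoch)
  expect_equal(trainingHistory(r)$validation, trainingHistory(m)$validation,
               tolerance = 1e-12)
})

test_that("an independent single-layer net agrees on the separable problem", {
  skip_if_not_installed("nnet")
  ft <- separableFeatures(100, seed = 20)
  s <- splitDataset(ft, seed = 21)
  m <- trainClassifier(s, seed = 22)
  featCols <- c("p2_5", "p25", "p50", "p75", "p97_5")
  ctr <- colMeans(s$train[, featCols]); scl <- sapply(s$train[, featCols], sd)
  trainStd <- cbind(label = s$train["label"],
                    scale(s$train[, featCols], ctr, scl))
  testStd <- as.data.frame(scale(s$test[, featCols], ctr, scl))
  set.seed(23)
  fit <- nnet::nnet(factor(label, levels = patternClasses()) ~ .,
                    data = trainStd, size = 10, decay = 1e-4, maxit = 400,
                    trace = FALSE)
  ref <- as.character(predict(fit, testStd, type = "class"))
  ours <- predict(m, s$test)$label
  expect_gte(mean(ref == s$test$label), 0.99)
  expect_gte(mean(ours == ref), 0.98)
})
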