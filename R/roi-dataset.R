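#' @include AllClasses.R utils.R
NULL

.FEATNAMES <- c("p2_5", "p25", "p50", "p75", "p97_5")
.FEATPROBS <- c(0.025, 0.25, 0.50, 0.75, 0.975)

#' Extract a circular region of interest
#'
#' Collects the HU values of in-mask voxels on a single slice whose
#' in-plane Euclidean distance (in mm, using the pixel spacing) from the
#' centre voxel is at most `radiusMm`. ROIs are in-plane discs, matching
#' how labelled regions are drawn on individual CT sections.
#'
#' @param v a [CTVolume-class].
#' @param mask a [LungLabelMap-class] on the same grid.
#' @param center integer(3) voxel index (row, col, slice), inside the mask.
#' @param radiusMm disc radius in mm (default 4).
#' @param minVoxels smallest acceptable disc (default 5 in-mask voxels).
#' @return A list of class `ROISample`: `center`, `radiusMm`, `huValues`,
#'   `label` (`NA` until assigned).
#' @export
extractROI <- function(v, mask, center, radiusMm = 4, minVoxels = 5L) {
  stopifnot(is(v, "CTVolume"), is(mask, "LungLabelMap"), length(center) == 3L)
  checkGrid(mask@labels, v@voxels)
  if (radiusMm <= 0) stopf("radiusMm must be positive")
  d <- dim(v@voxels)
  center <- as.integer(center)
  if (any(center < 1L) || any(center > d))
    stopf("ROI centre (%s) outside the volume", paste(center, collapse = ","))
  if (mask@labels[center[1], center[2], center[3]] == 0L)
    stopf("ROI centre (%s) is not inside the lung mask", paste(center, collapse = ","))
  off <- discOffsets(radiusMm, v@pixelSpacing)
  rr <- center[1] + off$dr
  cc <- center[2] + off$dc
  ok <- rr >= 1L & rr <= d[1] & cc >= 1L & cc <= d[2]
  rr <- rr[ok]; cc <- cc[ok]
  idx <- cbind(rr, cc, center[3])
  inMask <- mask@labels[idx] > 0L
  hu <- v@voxels[idx[inMask, , drop = FALSE]]
  if (length(hu) < minVoxels)
    stopf("ROI at (%s) covers only %d in-mask voxel(s); at least %d required",
          paste(center, collapse = ","), length(hu), minVoxels)
  structure(list(center = center, radiusMm = radiusMm, huValues = hu,
                 label = NA_character_),
            class = "ROISample")
}

#' Percentile density features of an ROI
#'
#' The 2.5, 25, 50, 75 and 97.5 percent quantiles of the ROI's HU
#' histogram, computed with linear interpolation between closest ranks
#' (`stats::quantile` type 7). The five values are non-decreasing by
#' construction.
#'
#' @param roi an `ROISample` from [extractROI()], or a numeric vector of HU.
#' @return Named numeric(5): `p2_5`, `p25`, `p50`, `p75`, `p97_5`.
#' @examples
#' roiFeatures(1:100)[["p50"]]  # 50.5 under linear interpolation
#' @export
roiFeatures <- function(roi) {
  hu <- if (inherits(roi, "ROISample")) roi$huValues else as.numeric(roi)
  if (length(hu) == 0L) stopf("empty ROI: no HU values")
  setNames(as.numeric(quantile(hu, probs = .FEATPROBS, type = 7, names = FALSE)),
           .FEATNAMES)
}

.checkFeatureTable <- function(x) {
  need <- c("label", .FEATNAMES)
  miss <- setdiff(need, names(x))
  if (length(miss)) stopf("feature table lacks column(s): %s", paste(miss, collapse = ", "))
  bad <- setdiff(unique(x$label), .CLASSES)
  if (length(bad)) stopf("unknown class label(s): %s", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Balance a labelled feature table to its smallest class
#'
#' Subsamples every class uniformly at random, without replacement, down to
#' the size of the least-populated class, so that all five parenchymal
#' classes contribute equally to training.
#'
#' @param features data.frame with columns `label`, `p2_5` .. `p97_5` (an
#'   `id` column is preserved if present).
#' @param seed integer seed; the draw is fully reproducible.
#' @return The balanced data.frame (5 x min class count rows).
#' @export
balanceClasses <- function(features, seed = 1L) {
  .checkFeatureTable(features)
  counts <- table(factor(features$label, levels = .CLASSES))
  if (any(counts == 0L))
    stopf("class(es) missing from the feature table: %s",
          paste(names(counts)[counts == 0L], collapse = ", "))
  nMin <- min(counts)
  withr::local_seed(as.integer(seed))
  keep <- unlist(lapply(.CLASSES, function(cl) {
    rows <- which(features$label == cl)
    if (length(rows) == nMin) rows else sample(rows, nMin)
  }), use.names = FALSE)
  features[sort(keep), , drop = FALSE]
}

#' Split a balanced feature table into train / validation / test
#'
#' Held-out partition sizes are `round(p * N)` for the validation and test
#' proportions; the training partition receives the remainder. Assignment
#' is a single seeded shuffle of the pooled table (no stratification).
#'
#' @param balanced data.frame of labelled features (see [balanceClasses()]).
#' @param proportions numeric(3) summing to 1; default `c(0.70, 0.15, 0.15)`.
#' @param seed integer seed.
#' @return A list of class `SplitDataset`: data.frames `train`,
#'   `validation`, `test`; `classCounts` (per-class totals of the input);
#'   `seed`.
#' @examples
#' ft <- data.frame(label = rep(patternClasses(), each = 20),
#'                  p2_5 = 0, p25 = 0, p50 = 0, p75 = 0, p97_5 = 0)
#' s <- splitDataset(ft, seed = 7)
#' vapply(s[c("train", "validation", "test")], nrow, 1L)  # 70 / 15 / 15
#' @export
splitDataset <- function(balanced, proportions = c(0.70, 0.15, 0.15), seed = 1L) {
  .checkFeatureTable(balanced)
  if (length(proportions) != 3L || abs(sum(proportions) - 1) > 1e-9)
    stopf("proportions must be three values summing to 1")
  n <- nrow(balanced)
  nVal <- round(proportions[2] * n)
  nTest <- round(proportions[3] * n)
  nTrain <- n - nVal - nTest
  if (min(nTrain, nVal, nTest) < 1L)
    stopf("degenerate split: partition sizes %d/%d/%d from %d rows",
          nTrain, nVal, nTest, n)
  withr::local_seed(as.integer(seed))
  ord <- sample.int(n)
  idxTrain <- ord[seq_len(nTrain)]
  idxVal <- ord[nTrain + seq_len(nVal)]
  idxTest <- ord[nTrain + nVal + seq_len(nTest)]
  structure(list(train = balanced[idxTrain, , drop = FALSE],
                 validation = balanced[idxVal, , drop = FALSE],
                 test = balanced[idxTest, , drop = FALSE],
                 classCounts = table(factor(balanced$label, levels = .CLASSES)),
                 seed = as.integer(seed)),
            class = "SplitDataset")
}

#' Read / write ROI feature tables
#'
#' CSV dialect with header `id,label,p2_5,p25,p50,p75,p97_5`, UTF-8, `.`
#' decimal separator, so classifier training is possible from features
#' alone.
#'
#' @param features data.frame of labelled features.
#' @param path CSV path.
#' @return `writeROITable` returns `path` invisibly; `readROITable` the
#'   data.frame.
#' @export
writeROITable <- function(features, path) {
  .checkFeatureTable(features)
  if (is.null(features$id)) features$id <- seq_len(nrow(features))
  write.csv(features[, c("id", "label", .FEATNAMES)], path, row.names = FALSE,
            quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeROITable
#' @export
readROITable <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  .checkFeatureTable(x)
  x
}
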