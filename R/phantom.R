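#' @include AllClasses.R volume-io.R quantification.R roi-dataset.R
NULL

.HU_DEFAULTS <- list(Emph = c(-980, 20), Normal = c(-860, 45),
                     GGO = c(-600, 90), CP_LO = c(-350, 120),
                     Consolidation = c(40, 50),
                     body = c(40, 15), air = c(-1000, 10))

#' Specification of a synthetic chest-CT phantom
#'
#' Describes a soft-tissue body containing two ellipsoidal lung fields on a
#' seeded, fully reproducible grid. The lungs are sized so that the
#' measured CT lung volume equals `hyperinflation` times the predicted
#' total lung volume of the phantom's subject (height and sex). Within the
#' lungs, abnormal parenchymal classes are placed as irregular blobs --
#' smoothed random fields thresholded to hit the requested volume
#' fractions exactly at voxel resolution -- and each voxel's HU is drawn
#' from its class's Gaussian (clipped to [-1024, 100] HU). Per-class HU
#' distributions deliberately overlap (the emphysema upper tail reaches
#' into the normal-parenchyma lower tail), as real ROI density histograms
#' do.
#'
#' @param dim grid size (row, col, slice); default 96 x 96 x 96.
#' @param spacing voxel spacing in mm (row, col, slice); default 3 x 3 x 5.
#' @param classFractions named fractions of lung volume for `Emph`, `GGO`,
#'   `CP_LO`, `Consolidation` (remainder is `Normal`). Defaults mirror a
#'   moderately diseased COPD lung.
#' @param huParams named list of `c(mean, sd)` HU per class plus `body`
#'   and `air`; see defaults.
#' @param mode emphysema placement: `"homogeneous"`, `"apical"`,
#'   `"basal"`, or `"focal"` (fewer, larger blobs).
#' @param hyperinflation target ratio of CT lung volume to predicted total
#'   lung volume (default 1.31).
#' @param heightM,sex,id subject metadata feeding the predicted volume.
#' @param bodySemiMm in-plane semi-axes of the body cylinder (mm).
#' @param lungSemiMm maximal semi-axes of each lung ellipsoid (mm).
#' @param lungColOffsetMm lateral offset of each lung centre (mm).
#' @param blobSigmaMm smoothing length of the class placement fields (mm);
#'   `NULL` picks 12 mm (25 mm for `"focal"`).
#' @param seed integer seed governing all randomness in the phantom.
#' @return A list of class `PhantomSpec`.
#' @seealso [generatePhantom()], [generateCohort()]
#' @export
phantomSpec <- function(dim = c(96L, 96L, 96L), spacing = c(3, 3, 5),
                        classFractions = c(Emph = 0.12, GGO = 0.07,
                                           CP_LO = 0.06, Consolidation = 0.02),
                        huParams = .HU_DEFAULTS,
                        mode = c("homogeneous", "apical", "basal", "focal"),
                        hyperinflation = 1.31,
                        heightM = 1.70, sex = "male", id = "phantom",
                        bodySemiMm = c(120, 135), lungSemiMm = c(95, 60, 215),
                        lungColOffsetMm = 65, blobSigmaMm = NULL, seed = 1L) {
  mode <- match.arg(mode)
  abnormal <- setdiff(.CLASSES, "Normal")
  fr <- setNames(rep(0, 4L), abnormal)
  fr[names(classFractions)] <- classFractions
  if (any(fr < 0) || sum(fr) > 1)
    stopf("class fractions must be non-negative and sum to at most 1")
  if (hyperinflation <= 0) stopf("hyperinflation factor must be positive")
  if (any(dim < 16L)) stopf("phantom grid must be at least 16 voxels per axis")
  if (is.null(blobSigmaMm)) blobSigmaMm <- if (mode == "focal") 25 else 12
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 classFractions = fr, huParams = huParams, mode = mode,
                 hyperinflation = hyperinflation, heightM = heightM,
                 sex = sex, id = id, bodySemiMm = bodySemiMm,
                 lungSemiMm = lungSemiMm, lungColOffsetMm = lungColOffsetMm,
                 blobSigmaMm = blobSigmaMm, seed = as.integer(seed)),
            class = "PhantomSpec")
}

.clipHu <- function(x) pmin(pmax(x, -1024), 100)

#' Generate a synthetic CT phantom with ground truth
#'
#' Realizes a [phantomSpec()]: the CT volume, the true lung label map, the
#' true per-voxel class map, exact class bookkeeping, and the exact
#' low-attenuation fraction at -950 HU. Identical specs (including seed)
#' produce bit-identical phantoms.
#'
#' @param spec a `PhantomSpec`.
#' @return A [PhantomTruth-class].
#' @examples
#' p <- generatePhantom(phantomSpec(dim = c(48, 48, 48),
#'                                  spacing = c(6, 6, 10), seed = 7))
#' p
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  withr::local_seed(spec$seed)
  d <- spec$dim; sp <- spec$spacing
  voxMm3 <- prod(sp)
  x <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp[1]   # row axis, mm
  y <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp[2]   # col axis, mm
  z <- (seq_len(d[3]) - (d[3] + 1) / 2) * sp[3]   # slice axis, mm

  ## body: elliptic cylinder through all slices
  bodySel <- outer((x / spec$bodySemiMm[1])^2, (y / spec$bodySemiMm[2])^2, "+") <= 1
  body <- array(bodySel, d)   # recycled over slices

  ## lungs sized to hit CT_LV = hyperinflation * P_LV at voxel resolution
  pLv <- suppressMessages(predictedLungVolume(spec$heightM, spec$sex))
  if (is.na(pLv))
    stopf("phantom specs require height and sex (the lungs are sized from the predicted volume)")
  targetVox <- round(spec$hyperinflation * pLv * 1000 / voxMm3)
  perLung <- c(ceiling(targetVox / 2), floor(targetVox / 2))
  a <- spec$lungSemiMm
  lung <- array(0L, d)
  for (side in 1:2) {
    yc <- if (side == 1L) -spec$lungColOffsetMm else spec$lungColOffsetMm
    dist <- outer(outer((x / a[1])^2, ((y - yc) / a[2])^2, "+"), (z / a[3])^2, "+")
    thr <- sort(dist, partial = perLung[side])[perLung[side]]
    if (thr > 1)
      stopf("infeasible phantom: lung volume target %.0f mL exceeds the ellipsoid capacity; enlarge the grid or lungSemiMm",
            spec$hyperinflation * pLv)
    lung[dist <= thr & lung == 0L] <- side
  }
  lungIdx <- which(lung > 0L)
  nLung <- length(lungIdx)

  ## class placement: smoothed random fields thresholded at exact counts
  sigmaVox <- spec$blobSigmaMm / sp
  zn <- (slice.index(lung, 3L)[lungIdx] - (d[3] + 1) / 2) / (d[3] / 2)
  classVec <- rep(2L, nLung)                       # Normal by default
  unassigned <- rep(TRUE, nLung)
  abnormal <- c(Emph = 1L, GGO = 3L, CP_LO = 4L, Consolidation = 5L)
  for (cl in names(abnormal)) {
    nWant <- round(spec$classFractions[[cl]] * nLung)
    if (nWant == 0L) next
    field <- gaussianSmooth3d(array(rnorm(prod(d)), d), sigmaVox)[lungIdx]
    field <- (field - mean(field)) / sd(field)
    if (cl == "Emph" && spec$mode == "apical") field <- field - 2 * zn
    if (cl == "Emph" && spec$mode == "basal") field <- field + 2 * zn
    cand <- which(unassigned)
    if (length(cand) < nWant)
      stopf("infeasible phantom: class fractions exceed the lung volume")
    pick <- cand[order(field[cand], decreasing = TRUE)[seq_len(nWant)]]
    classVec[pick] <- abnormal[[cl]]
    unassigned[pick] <- FALSE
  }

  ## HU synthesis
  hu <- array(rnorm(prod(d), .HU_DEFAULTS$air[1], .HU_DEFAULTS$air[2]), d)
  hp <- spec$huParams
  hu[body] <- rnorm(sum(body), hp$body[1], hp$body[2])
  for (k in 1:5) {
    sel <- lungIdx[classVec == k]
    if (length(sel))
      hu[sel] <- rnorm(length(sel), hp[[.CLASSES[k]]][1], hp[[.CLASSES[k]]][2])
  }
  hu <- round(.clipHu(hu))

  classArr <- array(0L, d)
  classArr[lungIdx] <- classVec
  counts <- setNames(tabulate(classVec, nbins = 5L), .CLASSES)
  meta <- PatientMeta(heightM = spec$heightM, sex = spec$sex, id = spec$id)
  vol <- CTVolume(hu, pixelSpacing = sp[1:2], sliceThickness = sp[3], meta = meta)
  new("PhantomTruth", volume = vol, lungMask = LungLabelMap(lung),
      classMap = ClassMap(classArr),
      classCounts = counts, classVolumesMl = counts * voxMm3 / 1000,
      laaFraction = mean(hu[lungIdx] <= -950),
      spec = unclass(spec))
}

#' Generate a synthetic phantom cohort
#'
#' A cohort of seeded phantoms spanning mild to very severe emphysema,
#' with the hyperinflation ratio increasing alongside the emphysema
#' fraction (as measured total lung volume does across severity groups in
#' COPD cohorts). Heights and sexes are drawn per subject. Each subject's
#' exact ground-truth bookkeeping and computed emphysema indices are
#' collected in a cohort table; the full voxel data of every subject are
#' additionally retained when `keepVolumes = TRUE`.
#'
#' @param n number of subjects (>= 1).
#' @param emphRange range of emphysema lung fractions spanned (default
#'   0.02 to 0.40).
#' @param hyperRange range of hyperinflation ratios spanned, increasing
#'   with emphysema severity (default 1.1 to 1.5).
#' @param heightRange uniform range of heights in metres.
#' @param maleProb probability that a subject is male (default 0.88).
#' @param mode emphysema placement mode passed to [phantomSpec()].
#' @param dim,spacing phantom grid, passed to [phantomSpec()].
#' @param keepVolumes retain every subject's `PhantomTruth` (voxel data)
#'   in the result (default FALSE: the table alone carries all truth
#'   scalars).
#' @param seed cohort seed; all subject seeds derive from it.
#' @return A list of class `PhantomCohort`: `table` (one row per subject:
#'   metadata, targets, exact truth counts and the computed indices),
#'   `subjects` (list of [PhantomTruth-class] or `NULL`s), `seed`.
#' @export
generateCohort <- function(n = 20L, emphRange = c(0.02, 0.40),
                           hyperRange = c(1.1, 1.5),
                           heightRange = c(1.55, 1.85), maleProb = 0.88,
                           mode = "homogeneous",
                           dim = c(96L, 96L, 96L), spacing = c(3, 3, 5),
                           keepVolumes = FALSE, seed = 1L) {
  stopifnot(n >= 1L)
  withr::local_seed(as.integer(seed))
  subSeeds <- sample.int(.Machine$integer.max - 1L, n)
  heights <- runif(n, heightRange[1], heightRange[2])
  sexes <- ifelse(runif(n) < maleProb, "male", "female")
  emph <- seq(emphRange[1], emphRange[2], length.out = n)
  hyper <- seq(hyperRange[1], hyperRange[2], length.out = n)
  rows <- vector("list", n)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- phantomSpec(dim = dim, spacing = spacing,
                        classFractions = c(Emph = emph[i], GGO = 0.05,
                                           CP_LO = 0.04, Consolidation = 0.02),
                        mode = mode, hyperinflation = hyper[i],
                        heightM = heights[i], sex = sexes[i],
                        id = sprintf("S%02d", i), seed = subSeeds[i])
    truth <- generatePhantom(spec)
    idx <- suppressMessages(
      computeIndices(truth@volume, truth@lungMask, truth@classMap))
    rows[[i]] <- cbind(
      data.frame(id = spec$id, height_m = heights[i], sex = sexes[i],
                 emph_frac_target = emph[i], hyperinflation_target = hyper[i],
                 laa_fraction_true = truth@laaFraction,
                 seed = subSeeds[i]),
      indicesAsRow(idx))
    if (keepVolumes) subjects[[i]] <- truth
  }
  structure(list(table = do.call(rbind, rows),
                 subjects = if (keepVolumes) subjects else NULL,
                 seed = as.integer(seed)),
            class = "PhantomCohort")
}

#' @export
print.PhantomCohort <- function(x, ...) {
  cat(sprintf("PhantomCohort: %d subjects (seed %d)%s\n", nrow(x$table),
              x$seed, if (is.null(x$subjects)) "" else ", volumes retained"))
  print(head(x$table[, c("id", "height_m", "sex", "hyperinflation_target",
                         "ct_lv_ml", "p_lv_ml", "emph_pct_ctlv",
                         "emph_pct_plv")]), digits = 4)
  invisible(x)
}

#' Write the cohort table as CSV
#'
#' @param cohort a `PhantomCohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCohortCsv <- function(cohort, path) {
  stopifnot(inherits(cohort, "PhantomCohort"))
  write.csv(cohort$table, path, row.names = FALSE)
  invisible(path)
}

#' Sample a labelled ROI feature corpus from a phantom
#'
#' Draws ROI centres uniformly within each ground-truth class region,
#' preferring centres whose whole disc lies inside that class (falling
#' back to any in-class centre, and to a reduced per-class count with a
#' warning when a class region is too small), then extracts the percentile
#' features of each ROI. This stands in for a radiologist-labelled ROI
#' corpus when validating the classifier end to end.
#'
#' @param truth a [PhantomTruth-class].
#' @param perClass ROIs requested per class (default 100).
#' @param radiusMm ROI disc radius in mm (default 4).
#' @param seed integer seed.
#' @return A feature data.frame (`id`, `label`, `p2_5` .. `p97_5`)
#'   compatible with [balanceClasses()] and [writeROITable()].
#' @export
roiCorpus <- function(truth, perClass = 100L, radiusMm = 4, seed = 1L) {
  stopifnot(is(truth, "PhantomTruth"))
  withr::local_seed(as.integer(seed))
  cls <- truth@classMap@labels
  d <- dim(cls)
  off <- discOffsets(radiusMm, truth@volume@pixelSpacing)
  rows <- list()
  for (k in seq_along(.CLASSES)) {
    inClass <- which(cls == k, arr.ind = TRUE)
    if (nrow(inClass) == 0L)
      stopf("class %s absent from the phantom ground truth", .CLASSES[k])
    eligible <- rep(TRUE, nrow(inClass))
    for (j in seq_len(nrow(off))) {
      rr <- inClass[, 1] + off$dr[j]
      cc <- inClass[, 2] + off$dc[j]
      ok <- rr >= 1L & rr <= d[1] & cc >= 1L & cc <= d[2]
      same <- ok
      same[ok] <- cls[cbind(rr[ok], cc[ok], inClass[ok, 3])] == k
      eligible <- eligible & same
    }
    nElig <- sum(eligible)
    if (nElig >= perClass) {
      take <- sample(which(eligible), perClass)
    } else {
      extra <- which(!eligible)
      take <- c(which(eligible),
                if (length(extra))
                  sample(extra, min(length(extra), perClass - nElig)))
      take <- sample(take)
    }
    nTake <- length(take)
    if (nTake < perClass)
      warnf("class %s: only %d candidate centre(s); corpus reduced", .CLASSES[k], nTake)
    feats <- matrix(NA_real_, nTake, 5L, dimnames = list(NULL, .FEATNAMES))
    got <- 0L
    for (ci in take) {
      if (got >= nTake) break
      roi <- tryCatch(
        extractROI(truth@volume, truth@lungMask, inClass[ci, ], radiusMm),
        error = function(e) NULL)
      if (is.null(roi)) next
      got <- got + 1L
      feats[got, ] <- roiFeatures(roi)
    }
    if (got < nTake) {
      feats <- feats[seq_len(got), , drop = FALSE]
      warnf("class %s: %d of %d requested ROIs extracted", .CLASSES[k], got, nTake)
    }
    rows[[k]] <- data.frame(label = .CLASSES[k], feats)
  }
  out <- do.call(rbind, rows)
  out <- cbind(id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
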