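#' @include AllClasses.R utils.R
NULL

#' Measured CT lung volume (mL)
#'
#' Total lung volume from the segmented CT: the in-mask voxel count times
#' the in-plane pixel area times the slice thickness. The product is in
#' cubic millimetres and is divided by 1000 to report millilitres. On
#' anisotropic in-plane grids the pixel area is row spacing times column
#' spacing (identical to spacing squared when isotropic), with a warning.
#'
#' @param v a [CTVolume-class].
#' @param mask a [LungLabelMap-class] on the same grid.
#' @return Lung volume in mL (0, with a warning, for an empty mask).
#' @examples
#' v <- CTVolume(array(-900L, c(10, 10, 10)), c(1, 1), 1)
#' m <- LungLabelMap(array(1L, c(10, 10, 10)))
#' ctLungVolume(v, m)  # 1000 voxels of 1 mm^3 = 1 mL
#' @export
ctLungVolume <- function(v, mask) {
  stopifnot(is(v, "CTVolume"), is(mask, "LungLabelMap"))
  checkGrid(mask@labels, v@voxels)
  if (abs(v@pixelSpacing[1] - v@pixelSpacing[2]) > 1e-9)
    warnf("anisotropic in-plane spacing (%g x %g mm): using row x col pixel area",
          v@pixelSpacing[1], v@pixelSpacing[2])
  n <- sum(mask@labels > 0L)
  if (n == 0L) warnf("empty lung mask: CT lung volume is 0 mL")
  n * voxelVolumeMl(v)
}

#' Predicted total lung volume (mL)
#'
#' Reference total lung volume of a healthy subject lying supine in deep
#' inspiration, from height and sex:
#' `P_LV = 4808.1 * height(m) - 3602.5` mL, plus 800.6 mL for males.
#'
#' @param meta a [PatientMeta-class], or a height in metres when `sex` is
#'   given separately.
#' @param sex `"male"` or `"female"` (only when `meta` is a bare height).
#' @return Predicted volume in mL; `NA` (with a message) when height or
#'   sex is unknown, in which case predicted-volume-adjusted indices are
#'   simply omitted downstream.
#' @examples
#' predictedLungVolume(1.70, "female")  # 4571.27
#' predictedLungVolume(1.70, "male")    # 5371.87
#' @export
predictedLungVolume <- function(meta, sex = NULL) {
  if (is(meta, "PatientMeta")) {
    h <- meta@heightM; s <- meta@sex
  } else {
    h <- as.numeric(meta); s <- sex
  }
  if (is.null(s)) s <- NA_character_
  if (is.na(h) || is.na(s)) {
    message("predicted lung volume not computable: height and/or sex unknown")
    return(NA_real_)
  }
  if (h <= 0.5 || h >= 2.5) stopf("height %.3f m outside plausible range", h)
  if (!s %in% c("male", "female")) stopf("sex must be 'male' or 'female'")
  plv <- 4808.1 * h - 3602.5
  if (s == "male") plv <- plv + 800.6
  plv
}

#' Low-attenuation-area mask
#'
#' In-mask voxels with attenuation at or below the threshold (default
#' -950 HU; a voxel at exactly the threshold is included).
#'
#' @param v a [CTVolume-class].
#' @param mask a [LungLabelMap-class] on the same grid.
#' @param thresholdHu HU cut-off (default -950).
#' @return Logical 3-D array.
#' @export
laaMask <- function(v, mask, thresholdHu = -950) {
  stopifnot(is(v, "CTVolume"), is(mask, "LungLabelMap"))
  checkGrid(mask@labels, v@voxels)
  v@voxels <= thresholdHu & mask@labels > 0L
}

#' Compute all CT-derived emphysema indices
#'
#' Combines the measured CT lung volume, the predicted total lung volume
#' (when height and sex are available), low-attenuation-area percentages,
#' and -- when a class map is supplied -- per-class volumes and the
#' classifier-derived emphysema percentages adjusted to either denominator.
#' By construction `emphPctPlv * P_LV = emphPctCtlv * CT_LV` (both equal
#' 100 times the emphysema volume).
#'
#' @param v a [CTVolume-class].
#' @param mask a [LungLabelMap-class].
#' @param classMap optional [ClassMap-class]; without it only densitometric
#'   (LAA) indices are produced.
#' @param laaThreshold HU cut-off for low-attenuation areas (default -950).
#' @param fev1PctPred optional FEV1 percent-of-predicted, to attach a GOLD
#'   grade.
#' @return An [EmphysemaIndices-class].
#' @export
computeIndices <- function(v, mask, classMap = NULL, laaThreshold = -950,
                           fev1PctPred = NULL) {
  ctLv <- ctLungVolume(v, mask)
  pLv <- suppressMessages(predictedLungVolume(v@meta))
  if (is.na(pLv))
    message("height/sex unavailable: P_LV-adjusted indices omitted")
  laaMl <- sum(laaMask(v, mask, laaThreshold)) * voxelVolumeMl(v)
  laaPctCtlv <- if (ctLv > 0) 100 * laaMl / ctLv else 0
  laaPctPlv <- if (!is.na(pLv)) 100 * laaMl / pLv else NA_real_
  cv <- setNames(rep(NA_real_, 5L), .CLASSES)
  emphPctCtlv <- emphPctPlv <- NA_real_
  if (!is.null(classMap)) {
    stopifnot(is(classMap, "ClassMap"))
    checkGrid(classMap@labels, v@voxels, "class map")
    inMask <- mask@labels > 0L
    unlab <- sum(inMask & classMap@labels == 0L)
    if (unlab > 0L)
      warnf("%d in-mask voxel(s) (%.2f%%) carry no class label; class volumes cover the classified portion of the lung",
            unlab, 100 * unlab / sum(inMask))
    counts <- tabulate(classMap@labels[inMask], nbins = 5L)
    cv <- setNames(counts * voxelVolumeMl(v), .CLASSES)
    emphPctCtlv <- if (ctLv > 0) 100 * cv[["Emph"]] / ctLv else 0
    if (!is.na(pLv)) emphPctPlv <- 100 * cv[["Emph"]] / pLv
  }
  grade <- if (!is.null(fev1PctPred)) goldGrade(fev1PctPred) else NA_character_
  new("EmphysemaIndices", ctLvMl = ctLv, pLvMl = pLv,
      laaPctCtlv = laaPctCtlv, laaPctPlv = laaPctPlv,
      emphPctCtlv = unname(emphPctCtlv), emphPctPlv = unname(emphPctPlv),
      classVolumesMl = cv, goldGrade = grade)
}

#' GOLD airflow-limitation grade from FEV1 percent predicted
#'
#' Mild: FEV1 >= 80 percent of predicted; moderate: 50-79; severe: 30-49;
#' very severe: below 30. The bins partition the axis as closed-open
#' intervals.
#'
#' @param fev1PctPred FEV1 as percent of predicted (> 0).
#' @return One of `"mild"`, `"moderate"`, `"severe"`, `"very_severe"`
#'   (vectorized).
#' @examples
#' goldGrade(c(93.1, 50, 49.999, 23.6))
#' @export
goldGrade <- function(fev1PctPred) {
  if (any(!is.finite(fev1PctPred)) || any(fev1PctPred <= 0))
    stopf("FEV1 %% predicted must be positive and finite")
  cut(fev1PctPred, breaks = c(0, 30, 50, 80, Inf), right = FALSE,
      labels = c("very_severe", "severe", "moderate", "mild")) |>
    as.character()
}

#' Write emphysema indices as CSV or JSON
#'
#' One row/object per subject with columns `ct_lv_ml`, `p_lv_ml`,
#' `laa_pct_ctlv`, `laa_pct_plv`, `emph_pct_ctlv`, `emph_pct_plv`,
#' `vol_emph_ml`, `vol_normal_ml`, `vol_ggo_ml`, `vol_cplo_ml`,
#' `vol_consol_ml`.
#'
#' @param indices an [EmphysemaIndices-class] or a list of them.
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
writeIndices <- function(indices, path) {
  if (is(indices, "EmphysemaIndices")) indices <- list(indices)
  rows <- do.call(rbind, lapply(indices, indicesAsRow))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rows, path, digits = NA, na = "null")
  } else {
    write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}
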