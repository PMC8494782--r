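#' @include emphyCT-package.R
NULL

## ---- PatientMeta -----------------------------------------------------------

#' Patient metadata carried with a CT volume
#'
#' Holds the covariates needed by the predicted-total-lung-volume formula:
#' standing height in metres and sex. Either may be missing (`NA`), in which
#' case predicted-volume-adjusted indices are simply not computable.
#'
#' @slot heightM numeric(1), height in metres, or `NA`.
#' @slot sex character(1), `"male"` or `"female"`, or `NA`.
#' @slot id character(1), opaque subject identifier.
#'
#' @param heightM,sex,id see slots.
#' @return A `PatientMeta` object.
#' @examples
#' PatientMeta(heightM = 1.70, sex = "male", id = "S01")
#' @export PatientMeta
#' @exportClass PatientMeta
PatientMeta <- setClass("PatientMeta",
  representation(heightM = "numeric", sex = "character", id = "character"),
  prototype(heightM = NA_real_, sex = NA_character_, id = ""))

setValidity("PatientMeta", function(object) {
  msg <- character()
  h <- object@heightM
  if (length(h) != 1L) msg <- c(msg, "heightM must be a single value")
  else if (!is.na(h) && (h <= 0.5 || h >= 2.5))
    msg <- c(msg, sprintf("heightM = %.3f is outside the plausible range (0.5, 2.5) m", h))
  s <- object@sex
  if (length(s) != 1L) msg <- c(msg, "sex must be a single value")
  else if (!is.na(s) && !s %in% c("male", "female"))
    msg <- c(msg, "sex must be 'male', 'female' or NA")
  if (length(msg)) msg else TRUE
})

#' @param object,x a `PatientMeta`.
#' @rdname PatientMeta-class
#' @export
setMethod("show", "PatientMeta", function(object) {
  cat("PatientMeta:", if (nzchar(object@id)) object@id else "<unnamed>",
      "| height:", ifelse(is.na(object@heightM), "NA", sprintf("%.2f m", object@heightM)),
      "| sex:", ifelse(is.na(object@sex), "NA", object@sex), "\n")
})

## ---- CTVolume --------------------------------------------------------------

#' A chest CT volume in Hounsfield units
#'
#' Voxel data are stored as a 3-D array with dimensions (row, col, slice);
#' the slice index increases cranio-to-caudal. In-plane spacing is given as
#' (row, col) millimetres; slices are `sliceThickness` mm apart. All
#' geometry is asserted at construction so downstream volume arithmetic can
#' trust it.
#'
#' @slot voxels 3-D numeric array of HU.
#' @slot pixelSpacing numeric(2), in-plane (row, col) spacing in mm, > 0.
#' @slot sliceThickness numeric(1), mm, > 0.
#' @slot axisOrder character(1), fixed to `"row-col-slice"`.
#' @slot meta a [PatientMeta-class].
#'
#' @param voxels,pixelSpacing,sliceThickness,meta see slots.
#' @return A `CTVolume`.
#' @examples
#' v <- CTVolume(array(-1000, c(4, 4, 3)), pixelSpacing = c(1, 1),
#'               sliceThickness = 5)
#' voxelVolumeMl(v) * prod(dim(voxels(v)))
#' @export CTVolume
#' @exportClass CTVolume
CTVolume <- function(voxels, pixelSpacing = c(1, 1), sliceThickness = 1,
                     meta = PatientMeta()) {
  if (length(pixelSpacing) == 1L) pixelSpacing <- rep(pixelSpacing, 2L)
  new("CTVolume", voxels = voxels, pixelSpacing = as.numeric(pixelSpacing),
      sliceThickness = as.numeric(sliceThickness),
      axisOrder = "row-col-slice", meta = meta)
}

setClass("CTVolume",
  representation(voxels = "array", pixelSpacing = "numeric",
                 sliceThickness = "numeric", axisOrder = "character",
                 meta = "PatientMeta"))

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3-D array")
  else if (dim(object@voxels)[3] < 1L)
    msg <- c(msg, "volume must have at least one slice")
  if (!all(is.finite(object@voxels)))
    msg <- c(msg, "all HU values must be finite")
  if (length(object@pixelSpacing) != 2L || any(!is.finite(object@pixelSpacing)) ||
      any(object@pixelSpacing <= 0))
    msg <- c(msg, "pixelSpacing must be two positive finite values (mm)")
  if (length(object@sliceThickness) != 1L || !is.finite(object@sliceThickness) ||
      object@sliceThickness <= 0)
    msg <- c(msg, "sliceThickness must be a single positive value (mm)")
  if (!identical(object@axisOrder, "row-col-slice"))
    msg <- c(msg, "axisOrder must be 'row-col-slice'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU [%g, %g]\n",
              d[1], d[2], d[3], object@pixelSpacing[1], object@pixelSpacing[2],
              object@sliceThickness, min(object@voxels), max(object@voxels)))
  show(object@meta)
})

## ---- label-map family ------------------------------------------------------

#' Lung label map
#'
#' Integer label array on the same grid as its `CTVolume`:
#' 0 = background, 1 = right lung, 2 = left lung. The image column index
#' increases towards the patient's left, so the right lung sits at lower
#' column indices (radiological convention).
#'
#' @slot labels 3-D integer array with values in {0, 1, 2}.
#' @param labels see slot.
#' @return A `LungLabelMap`.
#' @export LungLabelMap
#' @exportClass LungLabelMap
LungLabelMap <- function(labels) {
  storage.mode(labels) <- "integer"
  new("LungLabelMap", labels = labels)
}

setClass("LungLabelMap", representation(labels = "array"))

setValidity("LungLabelMap", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L) msg <- c(msg, "labels must be a 3-D array")
  if (!all(object@labels %in% 0:2)) msg <- c(msg, "labels must be in {0, 1, 2}")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LungLabelMap", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LungLabelMap: %d x %d x %d; right %d vox, left %d vox\n",
              d[1], d[2], d[3], sum(object@labels == 1L), sum(object@labels == 2L)))
})

#' Six-region lung-thirds map
#'
#' Refines a [LungLabelMap-class] into upper/middle/lower thirds per lung:
#' 1..3 = right upper/middle/lower (RU, RM, RL), 4..6 = left (LU, LM, LL),
#' 0 = background. `bounds` records, per lung, the half-open slice interval
#' `[first, last+1)` of each third.
#'
#' @slot labels 3-D integer array with values in {0,...,6}.
#' @slot bounds named list with elements `right` and `left`, each a 3 x 2
#'   integer matrix of half-open slice intervals (rows RU/RM/RL or LU/LM/LL).
#' @export
#' @exportClass RegionMap
setClass("RegionMap", representation(labels = "array", bounds = "list"))

RegionMap <- function(labels, bounds) {
  storage.mode(labels) <- "integer"
  new("RegionMap", labels = labels, bounds = bounds)
}

setValidity("RegionMap", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L) msg <- c(msg, "labels must be a 3-D array")
  if (!all(object@labels %in% 0:6)) msg <- c(msg, "labels must be in {0..6}")
  if (!all(c("right", "left") %in% names(object@bounds)))
    msg <- c(msg, "bounds must contain 'right' and 'left'")
  if (length(msg)) msg else TRUE
})

#' Region codes of the six lung thirds
#' @return Character vector `c("RU","RM","RL","LU","LM","LL")` in label order 1..6.
#' @examples regionCodes()
#' @export
regionCodes <- function() c("RU", "RM", "RL", "LU", "LM", "LL")

setMethod("show", "RegionMap", function(object) {
  cnt <- tabulate(object@labels[object@labels > 0L], nbins = 6L)
  cat("RegionMap (voxels):", paste(regionCodes(), cnt, collapse = ", "), "\n")
})

#' Per-voxel parenchymal pattern map
#'
#' Labels 1..5 follow [patternClasses()]; 0 = outside the lung mask.
#' `qcSmallDisc` counts lung voxels whose feature disc held fewer than five
#' in-mask neighbours and were classified from a reduced disc.
#'
#' @slot labels 3-D integer array with values in {0,...,5}.
#' @slot classes character(5), the class order (fixed).
#' @slot qcSmallDisc integer(1).
#' @param labels,qcSmallDisc see slots.
#' @export ClassMap
#' @exportClass ClassMap
ClassMap <- function(labels, qcSmallDisc = 0L) {
  storage.mode(labels) <- "integer"
  new("ClassMap", labels = labels, classes = .CLASSES,
      qcSmallDisc = as.integer(qcSmallDisc))
}

setClass("ClassMap",
  representation(labels = "array", classes = "character", qcSmallDisc = "integer"))

setValidity("ClassMap", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L) msg <- c(msg, "labels must be a 3-D array")
  if (!all(object@labels %in% 0:5)) msg <- c(msg, "labels must be in {0..5}")
  if (!identical(object@classes, .CLASSES)) msg <- c(msg, "classes must be the canonical order")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClassMap", function(object) {
  cnt <- tabulate(object@labels[object@labels > 0L], nbins = 5L)
  cat("ClassMap (voxels):", paste(object@classes, cnt, collapse = ", "),
      "| small-disc QC:", object@qcSmallDisc, "\n")
})

## ---- EmphysemaIndices ------------------------------------------------------

#' CT-derived emphysema indices for one subject
#'
#' Measured CT lung volume, predicted total lung volume (when height and sex
#' are known), low-attenuation-area percentages, classifier-derived
#' emphysema percentages, and per-class volumes. Percentages carry the
#' denominator in their name: `...PctCtlv` is relative to the measured CT
#' lung volume, `...PctPlv` to the predicted volume.
#'
#' @slot ctLvMl measured CT lung volume (mL).
#' @slot pLvMl predicted total lung volume (mL), `NA` if not computable.
#' @slot laaPctCtlv,laaPctPlv low-attenuation area as % of CT_LV / P_LV.
#' @slot emphPctCtlv,emphPctPlv classifier emphysema volume as % of CT_LV / P_LV
#'   (`NA` without a class map / without P_LV).
#' @slot classVolumesMl named numeric(5), per-class volume in mL (all `NA`
#'   without a class map).
#' @slot goldGrade character(1), optional GOLD airflow-limitation grade.
#' @export
#' @exportClass EmphysemaIndices
setClass("EmphysemaIndices",
  representation(ctLvMl = "numeric", pLvMl = "numeric",
                 laaPctCtlv = "numeric", laaPctPlv = "numeric",
                 emphPctCtlv = "numeric", emphPctPlv = "numeric",
                 classVolumesMl = "numeric", goldGrade = "character"))

setValidity("EmphysemaIndices", function(object) {
  msg <- character()
  if (!is.na(object@laaPctCtlv) &&
      (object@laaPctCtlv < 0 || object@laaPctCtlv > 100))
    msg <- c(msg, "laaPctCtlv must lie in [0, 100]")
  cv <- object@classVolumesMl
  if (!identical(names(cv), .CLASSES))
    msg <- c(msg, "classVolumesMl must be named by the canonical classes")
  if (!any(is.na(cv)) && sum(cv) - object@ctLvMl > 0.01)
    msg <- c(msg, "class volumes cannot exceed the CT lung volume (+0.01 mL)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EmphysemaIndices", function(object) {
  cat(sprintf("EmphysemaIndices: CT_LV %.1f mL, P_LV %s mL\n", object@ctLvMl,
              ifelse(is.na(object@pLvMl), "NA", sprintf("%.1f", object@pLvMl))))
  cat(sprintf("  LAA  %%CT_LV %.2f | %%P_LV %s\n", object@laaPctCtlv,
              ifelse(is.na(object@laaPctPlv), "NA", sprintf("%.2f", object@laaPctPlv))))
  cat(sprintf("  Emph %%CT_LV %s | %%P_LV %s\n",
              ifelse(is.na(object@emphPctCtlv), "NA", sprintf("%.2f", object@emphPctCtlv)),
              ifelse(is.na(object@emphPctPlv), "NA", sprintf("%.2f", object@emphPctPlv))))
  if (!is.na(object@goldGrade)) cat("  GOLD grade:", object@goldGrade, "\n")
})

## ---- PatternClassifier -----------------------------------------------------

#' Feed-forward parenchymal pattern classifier
#'
#' A single-hidden-layer network mapping the five ROI density percentiles to
#' softmax posteriors over the five parenchymal classes. Features are
#' standardized with training-partition statistics only. The stored weights
#' are those of `bestEpoch`, the epoch minimizing validation cross-entropy.
#'
#' @slot W1,b1 hidden-layer weights (5 x H) and biases (H).
#' @slot W2,b2 output-layer weights (H x 5) and biases (5).
#' @slot center,scale training-set per-feature mean and SD.
#' @slot classes character(5), class order.
#' @slot history data.frame with columns `epoch`, `train`, `validation`,
#'   `test` (cross-entropy per epoch).
#' @slot bestEpoch integer(1).
#' @slot seed integer(1) used at initialization.
#' @export
#' @exportClass PatternClassifier
setClass("PatternClassifier",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
                 center = "numeric", scale = "numeric", classes = "character",
                 history = "data.frame", bestEpoch = "integer", seed = "integer"))

setValidity("PatternClassifier", function(object) {
  msg <- character()
  H <- ncol(object@W1)
  if (nrow(object@W1) != 5L) msg <- c(msg, "W1 must have 5 input rows")
  if (!identical(dim(object@W2), c(H, 5L))) msg <- c(msg, "W2 must be H x 5")
  if (length(object@b1) != H || length(object@b2) != 5L)
    msg <- c(msg, "bias lengths must match layer sizes")
  if (!identical(object@classes, .CLASSES)) msg <- c(msg, "classes must be canonical")
  if (nrow(object@history) > 0L &&
      object@history$validation[object@bestEpoch] >
        min(object@history$validation) + 1e-12)
    msg <- c(msg, "bestEpoch must minimize validation cross-entropy")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PatternClassifier", function(object) {
  cat(sprintf("PatternClassifier: 5 -> %d (tanh) -> 5 (softmax); %d epochs, best %d (val CE %.4f)\n",
              ncol(object@W1), nrow(object@history), object@bestEpoch,
              object@history$validation[object@bestEpoch]))
})

## ---- PhantomTruth ----------------------------------------------------------

#' Synthetic phantom with voxel-level ground truth
#'
#' The product of [generatePhantom()]: the simulated CT volume, its true
#' lung mask and class map, exact per-class voxel bookkeeping, and the exact
#' low-attenuation fraction at -950 HU.
#'
#' @slot volume a [CTVolume-class].
#' @slot lungMask a [LungLabelMap-class].
#' @slot classMap a [ClassMap-class] (ground truth, not a prediction).
#' @slot classCounts named numeric(5), exact voxel counts per class.
#' @slot classVolumesMl named numeric(5), exact volumes in mL.
#' @slot laaFraction numeric(1), exact fraction of lung voxels <= -950 HU.
#' @slot spec list, the generating specification (seed included).
#' @export
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(volume = "CTVolume", lungMask = "LungLabelMap",
                 classMap = "ClassMap", classCounts = "numeric",
                 classVolumesMl = "numeric", laaFraction = "numeric",
                 spec = "list"))

setMethod("show", "PhantomTruth", function(object) {
  cat("PhantomTruth (seed ", object@spec$seed, ")\n", sep = "")
  show(object@volume)
  cat("  true class volumes (mL):",
      paste(names(object@classVolumesMl),
            sprintf("%.0f", object@classVolumesMl), collapse = ", "), "\n")
  cat(sprintf("  true LAA fraction at -950 HU: %.4f\n", object@laaFraction))
})
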