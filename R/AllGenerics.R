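#' @include AllClasses.R
NULL

#' Accessors for emphyCT containers
#'
#' Slot access goes through these accessors: `voxels()` (HU array),
#' `pixelSpacing()` (in-plane mm), `sliceThickness()` (mm),
#' `voxelVolumeMl()` (volume of one voxel in mL), `patientMeta()`,
#' `labels()` (label array of a mask/region/class map), `regionBounds()`
#' (per-lung slice intervals of a [RegionMap-class]), `trainingHistory()`
#' and `bestEpoch()` (of a [PatternClassifier-class]), and
#' `indicesAsRow()` (one-row data.frame of an [EmphysemaIndices-class]).
#'
#' @param x an emphyCT object.
#' @return See the individual accessor description.
#' @name accessors
#' @examples
#' v <- CTVolume(array(-900, c(2, 2, 2)), c(0.7, 0.7), 5)
#' pixelSpacing(v); voxelVolumeMl(v)
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setMethod("voxels", "CTVolume", function(x) x@voxels)

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "CTVolume", function(x) x@pixelSpacing)

#' @rdname accessors
#' @export
setGeneric("sliceThickness", function(x) standardGeneric("sliceThickness"))
#' @rdname accessors
#' @export
setMethod("sliceThickness", "CTVolume", function(x) x@sliceThickness)

#' @rdname accessors
#' @export
setGeneric("voxelVolumeMl", function(x) standardGeneric("voxelVolumeMl"))
#' @rdname accessors
#' @export
setMethod("voxelVolumeMl", "CTVolume", function(x)
  x@pixelSpacing[1] * x@pixelSpacing[2] * x@sliceThickness / 1000)

#' @rdname accessors
#' @export
setGeneric("patientMeta", function(x) standardGeneric("patientMeta"))
#' @rdname accessors
#' @export
setMethod("patientMeta", "CTVolume", function(x) x@meta)

#' @rdname accessors
#' @export
setGeneric("patientMeta<-", function(x, value) standardGeneric("patientMeta<-"))
#' @rdname accessors
#' @export
setMethod("patientMeta<-", "CTVolume", function(x, value) {
  x@meta <- value; validObject(x); x
})

#' @rdname accessors
#' @export
setGeneric("labels")
#' @rdname accessors
#' @export
setMethod("labels", "LungLabelMap", function(object, ...) object@labels)
#' @rdname accessors
#' @export
setMethod("labels", "RegionMap", function(object, ...) object@labels)
#' @rdname accessors
#' @export
setMethod("labels", "ClassMap", function(object, ...) object@labels)

#' @rdname accessors
#' @export
setGeneric("regionBounds", function(x) standardGeneric("regionBounds"))
#' @rdname accessors
#' @export
setMethod("regionBounds", "RegionMap", function(x) x@bounds)

#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
#' @rdname accessors
#' @export
setMethod("trainingHistory", "PatternClassifier", function(x) x@history)

#' @rdname accessors
#' @export
setGeneric("bestEpoch", function(x) standardGeneric("bestEpoch"))
#' @rdname accessors
#' @export
setMethod("bestEpoch", "PatternClassifier", function(x) x@bestEpoch)

#' @rdname accessors
#' @export
setGeneric("indicesAsRow", function(x) standardGeneric("indicesAsRow"))
#' @rdname accessors
#' @export
setMethod("indicesAsRow", "EmphysemaIndices", function(x) {
  cv <- x@classVolumesMl
  data.frame(ct_lv_ml = x@ctLvMl, p_lv_ml = x@pLvMl,
             laa_pct_ctlv = x@laaPctCtlv, laa_pct_plv = x@laaPctPlv,
             emph_pct_ctlv = x@emphPctCtlv, emph_pct_plv = x@emphPctPlv,
             vol_emph_ml = cv[["Emph"]], vol_normal_ml = cv[["Normal"]],
             vol_ggo_ml = cv[["GGO"]], vol_cplo_ml = cv[["CP_LO"]],
             vol_consol_ml = cv[["Consolidation"]])
})
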