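#' @include AllClasses.R utils.R
NULL

## ---- minimal NRRD codec ----------------------------------------------------
## Raw and gzip encodings, 3-D, attached data, little-endian. Spacing is read
## from 'spacings' or from diagonal 'space directions'.

.nrrdTypes <- list(
  "uchar"  = list(what = "integer", size = 1L, signed = FALSE, name = "uchar"),
  "short"  = list(what = "integer", size = 2L, signed = TRUE,  name = "short"),
  "ushort" = list(what = "integer", size = 2L, signed = FALSE, name = "ushort"),
  "int"    = list(what = "integer", size = 4L, signed = TRUE,  name = "int"),
  "float"  = list(what = "double",  size = 4L, signed = TRUE,  name = "float"),
  "double" = list(what = "double",  size = 8L, signed = TRUE,  name = "double"))

.nrrdTypeAlias <- c("unsigned char" = "uchar", "uint8" = "uchar", "uint8_t" = "uchar",
                    "signed short" = "short", "short int" = "short",
                    "int16" = "short", "int16_t" = "short",
                    "unsigned short" = "ushort", "uint16" = "ushort",
                    "int32" = "int", "signed int" = "int",
                    "float32" = "float", "float64" = "double")

readNrrd <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  hdrEnd <- NULL
  for (i in seq_len(min(length(bytes) - 1L, 65536L))) {
    if (bytes[i] == as.raw(10L) && bytes[i + 1L] == as.raw(10L)) { hdrEnd <- i; break }
  }
  if (is.null(hdrEnd)) stopf("'%s': no NRRD header terminator found", path)
  hdr <- strsplit(rawToChar(bytes[seq_len(hdrEnd - 1L)]), "\n", fixed = TRUE)[[1]]
  hdr <- sub("\r$", "", hdr)
  if (!grepl("^NRRD000", hdr[1])) stopf("'%s' is not an NRRD file", path)
  fields <- list()
  for (line in hdr[-1]) {
    if (!nzchar(line) || startsWith(line, "#")) next
    m <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(m) == 3L) fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  typ <- tolower(fields[["type"]])
  if (typ %in% names(.nrrdTypeAlias)) typ <- .nrrdTypeAlias[[typ]]
  if (!typ %in% names(.nrrdTypes)) stopf("'%s': unsupported NRRD type '%s'", path, fields[["type"]])
  tinfo <- .nrrdTypes[[typ]]
  ndim <- as.integer(fields[["dimension"]])
  if (!identical(ndim, 3L)) stopf("'%s': only 3-D NRRD supported (dimension = %s)", path, ndim)
  sizes <- as.integer(strsplit(fields[["sizes"]], "[ \t]+")[[1]])
  spacing <- NULL
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "[ \t]+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3))
    spacing <- sqrt(colSums(m^2))
  }
  if (is.null(spacing) || length(spacing) != 3L || any(!is.finite(spacing)))
    stopf("'%s': NRRD spacing metadata ('spacings' or 'space directions') missing", path)
  if (any(spacing <= 0))
    stopf("'%s': non-positive spacing in NRRD header", path)
  enc <- tolower(fields[["encoding"]] %||% "raw")
  payload <- bytes[(hdrEnd + 2L):length(bytes)]
  if (enc %in% c("gzip", "gz")) payload <- memDecompress(payload, type = "gzip")
  else if (enc != "raw") stopf("'%s': unsupported NRRD encoding '%s'", path, enc)
  n <- prod(sizes)
  endian <- tolower(fields[["endian"]] %||% "little")
  vals <- readBin(payload, tinfo$what, n = n, size = tinfo$size,
                  signed = tinfo$signed, endian = endian)
  if (length(vals) != n) stopf("'%s': NRRD payload shorter than sizes promise", path)
  list(data = array(vals, dim = sizes), spacing = spacing)
}

writeNrrd <- function(data, spacing, path, gzip = FALSE) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L)
  isInt <- is.integer(data) || all(data == round(data))
  if (isInt && min(data) >= -32768 && max(data) <= 32767) {
    typ <- "short"; size <- 2L; vals <- as.integer(data)
  } else if (isInt) {
    typ <- "int"; size <- 4L; vals <- as.integer(data)
  } else {
    typ <- "double"; size <- 8L; vals <- as.double(data)
  }
  hdr <- c("NRRD0004",
           paste0("type: ", typ),
           "dimension: 3",
           paste0("sizes: ", paste(dim(data), collapse = " ")),
           paste0("spacings: ", paste(format(spacing, digits = 15), collapse = " ")),
           "endian: little",
           paste0("encoding: ", if (gzip) "gzip" else "raw"),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  payload <- writeBin(vals, raw(), size = size, endian = "little")
  if (gzip) payload <- memCompress(payload, type = "gzip")
  writeBin(payload, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- format dispatch -------------------------------------------------------

.volumeFormat <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
  else if (grepl("\\.(nrrd|nhdr)$", path, ignore.case = TRUE)) "nrrd"
  else stopf("'%s': unsupported volume format (expected .nii, .nii.gz or .nrrd)", path)
}

.readArraySpacing <- function(path) {
  fmt <- .volumeFormat(path)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    if (length(pd) < 3L || any(!is.finite(pd[1:3])))
      stopf("'%s': pixdim (voxel spacing) missing from NIfTI header", path)
    if (any(pd[1:3] <= 0))
      stopf("'%s': non-positive pixdim in NIfTI header", path)
    arr <- array(as.vector(img), dim = dim(img))
    list(data = arr, spacing = pd[1:3])
  } else {
    readNrrd(path)
  }
}

#' Read a CT volume from NIfTI or NRRD
#'
#' Voxel data are interpreted as Hounsfield units on a (row, col, slice)
#' grid with the slice index increasing cranio-to-caudal; in-plane spacing
#' and slice thickness are taken from the file header and must be present
#' and positive. Patient metadata can be merged from a JSON or CSV sidecar
#' with fields/columns `height_m`, `sex` and `id`.
#'
#' @param path NIfTI (`.nii`, `.nii.gz`) or NRRD (`.nrrd`) file.
#' @param sidecar optional path to a JSON or CSV metadata sidecar.
#' @return A [CTVolume-class].
#' @seealso [writeVolume()], [readLabelMap()]
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(CTVolume(array(-1000L, c(8, 8, 4)), c(1, 1), 5), f)
#' readVolume(f)
#' @export
readVolume <- function(path, sidecar = NULL) {
  .volumeFormat(path)                      # unsupported formats fail first
  if (!file.exists(path)) stopf("'%s': file not found", path)
  rs <- .readArraySpacing(path)
  if (length(dim(rs$data)) != 3L)
    stopf("'%s': expected a 3-D volume, got %d dimensions", path, length(dim(rs$data)))
  meta <- if (!is.null(sidecar)) readSidecarMeta(sidecar) else PatientMeta()
  CTVolume(rs$data, pixelSpacing = rs$spacing[1:2],
           sliceThickness = rs$spacing[3], meta = meta)
}

#' Read a label map from NIfTI or NRRD
#'
#' @param path file path.
#' @param kind `"lung"` for a 0/1/2 lung label map, `"class"` for a 0..5
#'   parenchymal class map. (Region maps are not reconstructed from file:
#'   their per-lung bounds are recomputed with [divideIntoThirds()].)
#' @return A [LungLabelMap-class] or [ClassMap-class].
#' @export
readLabelMap <- function(path, kind = c("lung", "class")) {
  kind <- match.arg(kind)
  rs <- .readArraySpacing(path)
  if (kind == "lung") LungLabelMap(rs$data) else ClassMap(rs$data)
}

readSidecarMeta <- function(path) {
  if (!file.exists(path)) stopf("sidecar '%s': file not found", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    j <- as.list(read.csv(path, stringsAsFactors = FALSE)[1, , drop = FALSE])
  } else stopf("sidecar '%s': expected .json or .csv", path)
  PatientMeta(heightM = as.numeric(j$height_m %||% NA),
              sex = as.character(j$sex %||% NA),
              id = as.character(j$id %||% ""))
}

#' Write a volume or label map to NIfTI or NRRD
#'
#' Integer data (HU volumes stored as integers, and all label maps) survive
#' a write/read cycle losslessly, including anisotropic spacing.
#'
#' @param x a [CTVolume-class], [LungLabelMap-class], [RegionMap-class] or
#'   [ClassMap-class].
#' @param path output path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @param geometry for label maps, an optional [CTVolume-class] supplying
#'   the voxel spacing to record (defaults to 1 mm isotropic).
#' @return `path`, invisibly.
#' @export
setGeneric("writeVolume", function(x, path, geometry = NULL) standardGeneric("writeVolume"))

.writeArray <- function(data, spacing, path) {
  fmt <- .volumeFormat(path)
  dir <- dirname(path)
  if (!dir.exists(dir)) stopf("cannot write '%s': directory does not exist", path)
  if (fmt == "nifti") {
    im <- RNifti::asNifti(data)
    RNifti::pixdim(im) <- spacing
    ok <- tryCatch({ RNifti::writeNifti(im, path); TRUE },
                   error = function(e) stopf("failed to write '%s': %s", path, conditionMessage(e)))
  } else {
    writeNrrd(data, spacing, path)
  }
  invisible(path)
}

#' @rdname writeVolume
#' @export
setMethod("writeVolume", "CTVolume", function(x, path, geometry = NULL) {
  vox <- x@voxels
  if (all(vox == round(vox))) storage.mode(vox) <- "integer"
  .writeArray(vox, c(x@pixelSpacing, x@sliceThickness), path)
})

.labelSpacing <- function(geometry) {
  if (is.null(geometry)) c(1, 1, 1)
  else c(geometry@pixelSpacing, geometry@sliceThickness)
}

#' @rdname writeVolume
#' @export
setMethod("writeVolume", "LungLabelMap", function(x, path, geometry = NULL)
  .writeArray(x@labels, .labelSpacing(geometry), path))

#' @rdname writeVolume
#' @export
setMethod("writeVolume", "RegionMap", function(x, path, geometry = NULL)
  .writeArray(x@labels, .labelSpacing(geometry), path))

#' @rdname writeVolume
#' @export
setMethod("writeVolume", "ClassMap", function(x, path, geometry = NULL)
  .writeArray(x@labels, .labelSpacing(geometry), path))

## ---- lung segmentation -----------------------------------------------------

#' Segment the lungs by attenuation threshold and connected components
#'
#' A simplified lung segmenter: voxels strictly below `airThreshold` are
#' air-like; connected components touching the in-plane image border are
#' discarded as outside air; the two largest remaining components become
#' the lungs, assigned right/left by centre of mass along the column
#' (left-right) axis; per-slice internal holes (vessels, dense lesions) are
#' filled. If only one interior component is found the lungs are assumed
#' fused and are split at the component's mid-sagittal plane, with a
#' warning. The large airways are not removed separately: hole filling
#' keeps any enclosed airway lumen inside the mask (a documented deviation
#' from fissure/airway-aware clinical segmenters).
#'
#' @param v a [CTVolume-class] containing a body surrounded by air.
#' @param airThreshold HU below which a voxel counts as air-like
#'   (default -400).
#' @param minComponentVoxels smallest interior component considered a lung
#'   candidate (default 50 voxels).
#' @param fillHoles fill per-slice enclosed holes in each lung (default TRUE).
#' @return A [LungLabelMap-class] (1 = right lung, 2 = left lung).
#' @export
segmentLungs <- function(v, airThreshold = -400, minComponentVoxels = 50,
                         fillHoles = TRUE) {
  stopifnot(is(v, "CTVolume"))
  vox <- v@voxels
  d <- dim(vox)
  comps <- labelComponents3d(vox < airThreshold)
  ncomp <- max(comps)
  if (ncomp == 0L)
    stopf("lung segmentation failed: no air-like voxels below %g HU", airThreshold)
  borderLabels <- unique(c(comps[1, , ], comps[d[1], , ],
                           comps[, 1, ], comps[, d[2], ]))
  borderLabels <- borderLabels[borderLabels > 0L]
  sizes <- tabulate(comps[comps > 0L], nbins = ncomp)
  interior <- setdiff(which(sizes >= minComponentVoxels), borderLabels)
  if (length(interior) == 0L)
    stopf("lung segmentation failed: no interior air component of >= %d voxels (very hyperinflated or lung-free volume)",
          minComponentVoxels)
  interior <- interior[order(sizes[interior], decreasing = TRUE)]
  colIndex <- slice.index(comps, 2L)
  out <- array(0L, d)
  if (length(interior) >= 2L) {
    two <- interior[1:2]
    com <- vapply(two, function(l) mean(colIndex[comps == l]), numeric(1))
    right <- two[which.min(com)]; left <- two[which.max(com)]
    out[comps == right] <- 1L
    out[comps == left] <- 2L
  } else {
    warnf("single fused lung field found; splitting at the mid-sagittal plane")
    sel <- comps == interior[1]
    splitCol <- mean(colIndex[sel])
    out[sel & colIndex <= splitCol] <- 1L
    out[sel & colIndex > splitCol] <- 2L
  }
  if (fillHoles) {
    for (lab in 1:2) {
      m <- array(as.numeric(out == lab), d)
      filled <- EBImage::fillHull(m) > 0
      out[filled & out == 0L] <- lab
    }
  }
  LungLabelMap(out)
}
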