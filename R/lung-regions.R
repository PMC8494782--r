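#' @include AllClasses.R utils.R
NULL

## Split n slices into three contiguous slab lengths, remainder going to the
## upper, then middle slab.
.thirdSizes <- function(n) {
  base <- n %/% 3L
  rem <- n %% 3L
  c(base + (rem >= 1L), base + (rem >= 2L), base)
}

#' Divide each lung into three cranio-caudal thirds
#'
#' For each lung independently, the axial slice extent occupied by that
#' lung is split into three contiguous slabs (upper, middle, lower in
#' increasing slice order). With `by = "extent"` (default) the slabs have
#' near-equal slice counts (difference at most one slice, remainder to the
#' upper then middle slab); with `by = "volume"` slab boundaries are placed
#' where the cumulative lung voxel count crosses one and two thirds.
#'
#' @param mask a [LungLabelMap-class]; each lung must span at least 3 slices.
#' @param by `"extent"` (equal slice counts) or `"volume"` (equal voxel
#'   counts).
#' @return A [RegionMap-class] with labels 1..6 = RU, RM, RL, LU, LM, LL.
#' @examples
#' lab <- array(0L, c(4, 4, 9)); lab[2:3, 2, ] <- 1L; lab[2:3, 3, ] <- 2L
#' regionBounds(divideIntoThirds(LungLabelMap(lab)))
#' @export
divideIntoThirds <- function(mask, by = c("extent", "volume")) {
  stopifnot(is(mask, "LungLabelMap"))
  by <- match.arg(by)
  lab <- mask@labels
  d <- dim(lab)
  out <- array(0L, d)
  bounds <- list()
  for (lung in 1:2) {
    side <- if (lung == 1L) "right" else "left"
    perSlice <- vapply(seq_len(d[3]), function(s) sum(lab[, , s] == lung), integer(1))
    present <- which(perSlice > 0L)
    if (length(present) == 0L)
      stopf("%s lung absent from the label map", side)
    first <- min(present); last <- max(present)
    n <- last - first + 1L
    if (n < 3L)
      stopf("%s lung spans only %d slice(s); at least 3 are needed to form thirds", side, n)
    if (by == "extent") {
      sizes <- .thirdSizes(n)
      cuts <- first + cumsum(sizes)        # half-open upper bounds
      starts <- c(first, cuts[1], cuts[2])
    } else {
      cum <- cumsum(perSlice[first:last])
      total <- cum[n]
      b1 <- which(cum >= total / 3)[1]
      b2 <- which(cum >= 2 * total / 3)[1]
      b1 <- min(max(b1, 1L), n - 2L)       # keep all three slabs non-empty
      b2 <- min(max(b2, b1 + 1L), n - 1L)
      starts <- first + c(0L, b1, b2)
      cuts <- c(starts[2], starts[3], last + 1L)
    }
    bmat <- cbind(first = starts, end = cuts)
    rownames(bmat) <- paste0(substr(toupper(side), 1, 1), c("U", "M", "L"))
    bounds[[side]] <- bmat
    for (k in 1:3) {
      sl <- seq.int(starts[k], cuts[k] - 1L)
      sel <- lab[, , sl, drop = FALSE] == lung
      block <- out[, , sl, drop = FALSE]
      block[sel] <- (lung - 1L) * 3L + k
      out[, , sl] <- block
    }
  }
  RegionMap(out, bounds)
}

#' Per-region volumes in millilitres
#'
#' Volume of each lung third: voxel count times in-plane pixel area times
#' slice thickness, converted from cubic millimetres to millilitres.
#'
#' @param regionMap a [RegionMap-class].
#' @param v the paired [CTVolume-class] (supplies the voxel geometry).
#' @return Named numeric of length 6 (RU, RM, RL, LU, LM, LL), in mL.
#' @export
regionVolumes <- function(regionMap, v) {
  stopifnot(is(regionMap, "RegionMap"), is(v, "CTVolume"))
  checkGrid(regionMap@labels, v@voxels, "region map")
  counts <- tabulate(regionMap@labels[regionMap@labels > 0L], nbins = 6L)
  setNames(counts * voxelVolumeMl(v), regionCodes())
}
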