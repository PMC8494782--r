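#' @include AllClasses.R
NULL

## 3-D connected components: EBImage::bwlabel labels each slice in 2-D;
## slice labels are merged across adjacent slices with union-find.
labelComponents3d <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  sliceLab <- EBImage::bwlabel(array(as.numeric(mask != 0), d))
  glab <- array(0L, d)
  offset <- 0L
  for (s in seq_len(d[3])) {
    sl <- sliceLab[, , s]
    m <- as.integer(max(sl))
    if (m > 0L) {
      sel <- sl > 0
      g <- glab[, , s]
      g[sel] <- as.integer(sl[sel]) + offset
      glab[, , s] <- g
      offset <- offset + m
    }
  }
  n <- offset
  if (n == 0L) return(glab)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (s in seq_len(d[3] - 1L)) {
    a <- glab[, , s]; b <- glab[, , s + 1L]
    sel <- a > 0L & b > 0L
    if (!any(sel)) next
    pairs <- unique(cbind(a[sel], b[sel]))
    for (k in seq_len(nrow(pairs))) {
      ra <- findRoot(pairs[k, 1]); rb <- findRoot(pairs[k, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  root <- vapply(seq_len(n), findRoot, integer(1))
  compact <- match(root, unique(root))
  nz <- glab > 0L
  glab[nz] <- compact[glab[nz]]
  glab
}

## Separable Gaussian smoothing of a 3-D field via the FFT; sigma in voxels
## per axis. Periodic boundaries, which is harmless for fields only read
## inside the lung masks well away from the grid border.
gaussianSmooth3d <- function(x, sigmaVox) {
  d <- dim(x)
  if (length(sigmaVox) == 1L) sigmaVox <- rep(sigmaVox, 3L)
  freqAxis <- function(n) {
    k <- c(seq(0L, floor(n / 2)), seq(-ceiling(n / 2) + 1L, -1L))
    k / n
  }
  att <- exp(-2 * pi^2 * (sigmaVox[1] * freqAxis(d[1]))^2)
  att2 <- exp(-2 * pi^2 * (sigmaVox[2] * freqAxis(d[2]))^2)
  att3 <- exp(-2 * pi^2 * (sigmaVox[3] * freqAxis(d[3]))^2)
  ker <- outer(outer(att, att2), att3)
  Re(fft(fft(x) * ker, inverse = TRUE)) / prod(d)
}

## In-plane disc offsets (row, col) within radiusMm of the centre pixel.
discOffsets <- function(radiusMm, pixelSpacing) {
  nr <- floor(radiusMm / pixelSpacing[1])
  nc <- floor(radiusMm / pixelSpacing[2])
  off <- expand.grid(dr = -nr:nr, dc = -nc:nc)
  dist <- sqrt((off$dr * pixelSpacing[1])^2 + (off$dc * pixelSpacing[2])^2)
  off[dist <= radiusMm + 1e-9, , drop = FALSE]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

sameGrid <- function(a, b) identical(dim(a), dim(b))

checkGrid <- function(a, b, what = "label map") {
  if (!sameGrid(a, b))
    stopf("grid mismatch: %s has dims %s but volume has %s", what,
          paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  invisible(TRUE)
}
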