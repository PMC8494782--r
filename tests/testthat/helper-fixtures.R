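# Shared fixtures and independent oracles, built in code at test time.

.fixtures <- new.env(parent = emptyenv())

# Full-size phantom at the generator's default study conditions; built once
# per test run and reused (it is deterministic for a fixed seed).
defaultPhantom <- function() {
  if (is.null(.fixtures$default))
    .fixtures$default <- generatePhantom(phantomSpec(seed = 42))
  .fixtures$default
}

# Small, fine-in-plane phantom (0.7 mm pixels) so a 4 mm ROI disc spans
# ~100 voxels, as on clinical-resolution CT sections.
finePhantom <- function(seed = 11) {
  key <- paste0("fine", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generatePhantom(phantomSpec(
      dim = c(128, 128, 24), spacing = c(0.7, 0.7, 5),
      bodySemiMm = c(42, 42), lungSemiMm = c(30, 17, 55),
      lungColOffsetMm = 19, hyperinflation = 0.05,
      heightM = 1.60, sex = "female", blobSigmaMm = 5, seed = seed))
  .fixtures[[key]]
}

# Coarse two-ellipsoid phantom with healthy lungs only (no dense lesions).
healthyPhantom <- function(seed = 21) {
  key <- paste0("healthy", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generatePhantom(phantomSpec(
      classFractions = c(Emph = 0, GGO = 0, CP_LO = 0, Consolidation = 0),
      seed = seed))
  .fixtures[[key]]
}

# Labelled features drawn from five non-overlapping bands: a perfectly
# separable classification problem.
separableFeatures <- function(nPerClass = 200, seed = 1) {
  withr::with_seed(seed, {
    centers <- c(Emph = -1000, Normal = -800, GGO = -600, CP_LO = -400,
                 Consolidation = -200)
    do.call(rbind, lapply(patternClasses(), function(cl) {
      base <- centers[[cl]] + runif(nPerClass, -40, 40)
      data.frame(label = cl, p2_5 = base - 8, p25 = base - 3, p50 = base,
                 p75 = base + 3, p97_5 = base + 8)
    }))
  })
}

# Brute-force disc oracle: enumerate every pixel of the slice and test its
# in-plane distance; independent of the package's offset arithmetic.
bruteDiscHU <- function(v, mask, center, radiusMm) {
  d <- dim(voxels(v)); sp <- pixelSpacing(v)
  hu <- numeric(0)
  for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
    dist <- sqrt(((r - center[1]) * sp[1])^2 + ((cc - center[2]) * sp[2])^2)
    if (dist <= radiusMm + 1e-9 && labels(mask)[r, cc, center[3]] > 0)
      hu <- c(hu, voxels(v)[r, cc, center[3]])
  }
  hu
}

diceOverlap <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
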