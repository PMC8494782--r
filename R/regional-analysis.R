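#' @include AllClasses.R lung-regions.R quantification.R
NULL

#' Regional emphysema profile over the six lung thirds
#'
#' For each lung third, computes the volume fraction of every parenchymal
#' class within that third, plus the third's emphysema volume expressed as
#' a percent of the predicted total lung volume (when height and sex are
#' known). A third counts as *affected* when its emphysema measure reaches
#' `thresholdPct` (inclusive: "at least 5 percent"). The affected-thirds
#' count is grouped as 0-2, 3-4 or 5-6 for cohort comparisons. The rule is
#' applied to the within-third emphysema fraction by default
#' (`measure = "region"`); `measure = "plv"` applies it to the per-third
#' emphysema volume as a percent of P_LV instead (both quantities are
#' always reported).
#'
#' @param classMap a [ClassMap-class].
#' @param regionMap a [RegionMap-class] on the same grid.
#' @param v the paired [CTVolume-class].
#' @param meta optional [PatientMeta-class] overriding the volume's own
#'   metadata for the P_LV-adjusted columns.
#' @param thresholdPct affected-third threshold in percent (default 5).
#' @param measure which per-third quantity the threshold applies to.
#' @return A list of class `RegionalProfile`: `regions` (data.frame, one
#'   row per third with `region`, `vol_ml`, `frac_emph`, `frac_normal`,
#'   `frac_ggo`, `frac_cplo`, `frac_consol`, `emph_pct_region`,
#'   `emph_pct_plv`), `affectedThirds`, `distributionGroup`,
#'   `thresholdPct`, `measure`.
#' @export
regionalProfile <- function(classMap, regionMap, v, meta = NULL,
                            thresholdPct = 5, measure = c("region", "plv")) {
  stopifnot(is(classMap, "ClassMap"), is(regionMap, "RegionMap"),
            is(v, "CTVolume"))
  measure <- match.arg(measure)
  checkGrid(classMap@labels, v@voxels, "class map")
  checkGrid(regionMap@labels, v@voxels, "region map")
  if (is.null(meta)) meta <- v@meta
  pLv <- suppressMessages(predictedLungVolume(meta))
  voxMl <- voxelVolumeMl(v)
  regs <- regionCodes()
  counts <- matrix(0, 6L, 5L, dimnames = list(regs, .CLASSES))
  for (r in 1:6) {
    sel <- regionMap@labels == r
    if (any(sel)) counts[r, ] <- tabulate(classMap@labels[sel], nbins = 5L)
  }
  tot <- rowSums(counts)
  frac <- counts / ifelse(tot > 0, tot, NA_real_)
  emphMl <- counts[, "Emph"] * voxMl
  df <- data.frame(region = regs, vol_ml = tot * voxMl,
                   frac_emph = frac[, "Emph"], frac_normal = frac[, "Normal"],
                   frac_ggo = frac[, "GGO"], frac_cplo = frac[, "CP_LO"],
                   frac_consol = frac[, "Consolidation"],
                   emph_pct_region = 100 * frac[, "Emph"],
                   emph_pct_plv = if (!is.na(pLv)) 100 * emphMl / pLv else NA_real_,
                   row.names = NULL)
  if (any(tot == 0))
    warnf("region(s) %s contain no lung voxels; excluded from the affected-thirds count",
          paste(regs[tot == 0], collapse = ", "))
  val <- if (measure == "region") df$emph_pct_region else df$emph_pct_plv
  if (measure == "plv" && all(is.na(val)))
    stopf("measure = 'plv' requires height and sex for the predicted lung volume")
  affected <- sum(val >= thresholdPct, na.rm = TRUE)
  group <- cut(affected, breaks = c(-0.5, 2.5, 4.5, 6.5),
               labels = c("0-2", "3-4", "5-6")) |> as.character()
  structure(list(regions = df, affectedThirds = affected,
                 distributionGroup = group, thresholdPct = thresholdPct,
                 measure = measure),
            class = "RegionalProfile")
}

#' Count affected thirds from per-third emphysema percentages
#'
#' The bare threshold rule, usable on hand-built vectors: how many of the
#' six per-third emphysema percentages are at or above the threshold.
#' Missing values (empty thirds) are excluded from the count.
#'
#' @param pctPerThird numeric vector of per-third emphysema percentages.
#' @param thresholdPct threshold in percent (default 5, inclusive).
#' @return Integer count.
#' @examples
#' affectedThirds(c(6, 4, 5, 2, 8, 1))  # 3
#' @export
affectedThirds <- function(pctPerThird, thresholdPct = 5) {
  sum(pctPerThird >= thresholdPct, na.rm = TRUE)
}

#' @export
print.RegionalProfile <- function(x, ...) {
  cat(sprintf("RegionalProfile: %d/6 thirds affected (>= %g%% by %s measure), group %s\n",
              x$affectedThirds, x$thresholdPct,
              ifelse(x$measure == "region", "within-third", "P_LV-adjusted"),
              x$distributionGroup))
  print(x$regions, digits = 4)
  invisible(x)
}

#' Summary glyph of a regional profile
#'
#' A machine-readable 2 x 3 summary in the naming convention of the
#' regional display: cells RU, RM, RL (right lung) and LU, LM, LL (left
#' lung), each carrying the class volume fractions of that third and its
#' dominant class. The conventional palette maps emphysema to red, GGO to
#' yellow, CP/LO to orange, and consolidation to gray.
#'
#' @param profile a `RegionalProfile` from [regionalProfile()].
#' @return A list of class `GlyphSummary` with one element per region cell
#'   (named `RU` .. `LL`), each a list `fractions` (named numeric(5)) and
#'   `dominant` (class name).
#' @export
glyphSummary <- function(profile) {
  stopifnot(inherits(profile, "RegionalProfile"))
  df <- profile$regions
  cells <- lapply(seq_len(nrow(df)), function(i) {
    fr <- setNames(as.numeric(df[i, c("frac_emph", "frac_normal", "frac_ggo",
                                      "frac_cplo", "frac_consol")]), .CLASSES)
    list(fractions = fr,
         dominant = if (all(is.na(fr))) NA_character_ else .CLASSES[which.max(fr)])
  })
  names(cells) <- df$region
  structure(cells, class = "GlyphSummary")
}

#' @export
print.GlyphSummary <- function(x, ...) {
  cat("GlyphSummary (dominant class per third):\n")
  dom <- vapply(x, function(c) c$dominant, character(1))
  m <- matrix(dom, nrow = 2L, byrow = TRUE,
              dimnames = list(c("R", "L"), c("U", "M", "L")))
  print(m, quote = FALSE)
  invisible(x)
}

#' Write a regional profile as CSV and a glyph as JSON
#'
#' The regional CSV has one row per third with columns `region`,
#' `frac_emph`, `frac_normal`, `frac_ggo`, `frac_cplo`, `frac_consol`,
#' `vol_ml`.
#'
#' @param profile a `RegionalProfile`.
#' @param path output `.csv` path (`writeRegionalCsv`) or `.json` path
#'   (`writeGlyphJson`).
#' @return `path`, invisibly.
#' @export
writeRegionalCsv <- function(profile, path) {
  stopifnot(inherits(profile, "RegionalProfile"))
  write.csv(profile$regions[, c("region", "frac_emph", "frac_normal",
                                "frac_ggo", "frac_cplo", "frac_consol",
                                "vol_ml")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRegionalCsv
#' @export
writeGlyphJson <- function(profile, path) {
  g <- if (inherits(profile, "GlyphSummary")) profile else glyphSummary(profile)
  jsonlite::write_json(lapply(g, function(cell)
    list(fractions = as.list(cell$fractions), dominant = cell$dominant)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
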